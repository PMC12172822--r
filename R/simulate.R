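#' Configuration for a synthetic resting-state cohort
#'
#' Bundles every parameter of the synthetic-data generator: cohort and scan
#' geometry, the planted community structure of the node time series, head
#' motion, nuisance contamination, and the planted symptom model. Defaults
#' emulate a small early-psychosis resting-state study: a 6-minute scan at
#' TR = 2 s (185 frames), 60 nodes carrying four planted communities (the
#' three default-mode subnetworks of 18/22/8 nodes plus 12 non-DMN nodes),
#' block correlations of 0.6 within and 0.1 between communities, mean
#' framewise displacement near 0.23 mm, and negative-symptom scores driven
#' by MPF-PM and MPF-AT connectivity.
#'
#' @param n_subjects Number of subjects. The default 69 is split 39/11/19
#'   into healthy controls (HC), clinical high-risk (CHR) and first-episode
#'   psychosis (FEP); other sizes are split proportionally.
#' @param n_nodes Number of nodes. Must match `planted_partition` if given.
#' @param n_frames Frames per scan (default 185).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param planted_partition Named character vector mapping node id to planted
#'   community label. `NULL` builds the default PM/AT/MPF/Other layout.
#' @param rho_within,rho_between Block correlations of the node series;
#'   must satisfy `0 <= rho_between < rho_within < 1`.
#' @param signal_mean,noise_sd Mean signal level and fluctuation SD in
#'   arbitrary units; the population temporal signal-to-noise ratio of every
#'   node is `signal_mean / noise_sd` before contamination.
#' @param ar_coef Optional AR(1) coefficient for temporal autocorrelation of
#'   the fluctuations (default 0: exchangeable frames).
#' @param confound_gain Amplitude of a shared WM/CSF confound added to every
#'   node (default 0).
#' @param motion_gain Amplitude of a motion artifact proportional to
#'   framewise displacement added to every node (default 0).
#' @param motion_step_sd Step SD of the motion random walk, in mm for
#'   translations; rotation steps use `motion_step_sd / 50` radians so both
#'   contribute equally to FD under the 50 mm sphere convention. The default
#'   0.035 yields mean FD near 0.23 mm once spikes are included.
#' @param spike_rate Per-frame probability of a motion spike.
#' @param spike_magnitude Spike displacement in mm (added to one translation).
#' @param beta_mpf_pm,beta_mpf_at,beta_fd Planted coefficients of the
#'   negative-symptom model on MPF-PM connectivity, MPF-AT connectivity and
#'   mean FD (score units per unit predictor). The defaults plant
#'   standardized effects near -0.5 and -0.6 on the two between-subnetwork
#'   predictors (MPF-AT the stronger, as in the motivating finding), sized
#'   so each is individually detectable at a 28-patient sample.
#' @param fd_positive_cor Target correlation between mean FD and the positive
#'   symptom score (default 0.39).
#' @param symptom_noise_sd SD of the Gaussian noise on the negative score.
#' @param seed Integer seed; with the same seed every generated artifact is
#'   bit-identical.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_subjects = 4, seed = 42)
#' table(cfg$planted_partition)
simulation_config <- function(n_subjects = 69,
                              n_nodes = 60,
                              n_frames = 185,
                              tr_seconds = 2,
                              planted_partition = NULL,
                              rho_within = 0.6,
                              rho_between = 0.1,
                              signal_mean = 100,
                              noise_sd = 1,
                              ar_coef = 0,
                              confound_gain = 0,
                              motion_gain = 0,
                              motion_step_sd = 0.035,
                              spike_rate = 0.02,
                              spike_magnitude = 1.5,
                              beta_mpf_pm = -70,
                              beta_mpf_at = -90,
                              beta_fd = 0,
                              fd_positive_cor = 0.39,
                              symptom_noise_sd = 4.0,
                              seed = 1) {
  stopifnot_scalar_number(n_subjects, "n_subjects", min = 1)
  stopifnot_scalar_number(n_nodes, "n_nodes", min = 2)
  stopifnot_scalar_number(n_frames, "n_frames", min = 2)
  stopifnot_scalar_number(tr_seconds, "tr_seconds", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(rho_between, "rho_between", min = 0, max = 1,
                          strict_max = TRUE)
  stopifnot_scalar_number(rho_within, "rho_within", min = 0, max = 1,
                          strict_max = TRUE)
  if (rho_within > 0 && rho_between >= rho_within) {
    abort("`rho_between` must be strictly smaller than `rho_within`.")
  }
  stopifnot_scalar_number(spike_rate, "spike_rate", min = 0, max = 1)
  stopifnot_scalar_number(spike_magnitude, "spike_magnitude", min = 0)
  stopifnot_scalar_number(motion_step_sd, "motion_step_sd", min = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(ar_coef, "ar_coef", min = 0, max = 1, strict_max = TRUE)
  stopifnot_scalar_number(symptom_noise_sd, "symptom_noise_sd", min = 0)
  stopifnot_scalar_number(seed, "seed")

  if (is.null(planted_partition)) {
    planted_partition <- default_planted_partition(n_nodes)
  }
  if (length(planted_partition) != n_nodes) {
    abort("`planted_partition` must assign a community to every node.")
  }
  if (is.null(names(planted_partition))) {
    names(planted_partition) <- sprintf("n%03d", seq_len(n_nodes))
  }

  cfg <- list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    n_frames = as.integer(n_frames), tr_seconds = tr_seconds,
    planted_partition = planted_partition,
    rho_within = rho_within, rho_between = rho_between,
    signal_mean = signal_mean, noise_sd = noise_sd, ar_coef = ar_coef,
    confound_gain = confound_gain, motion_gain = motion_gain,
    motion_step_sd = motion_step_sd, spike_rate = spike_rate,
    spike_magnitude = spike_magnitude,
    beta_mpf_pm = beta_mpf_pm, beta_mpf_at = beta_mpf_at, beta_fd = beta_fd,
    fd_positive_cor = fd_positive_cor, symptom_noise_sd = symptom_noise_sd,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' Default planted community layout
#'
#' Four communities: the three DMN subnetworks — posterior medial (PM),
#' anterior temporal (AT), medial prefrontal (MPF) — and a block of
#' non-DMN nodes, in proportions 18:22:8:12. At the default 60 nodes the
#' sizes are exactly 18/22/8/12.
#'
#' @param n_nodes Total node count (at least 8 so every block is non-empty).
#' @return Named character vector (node id -> community label).
#' @export
default_planted_partition <- function(n_nodes) {
  if (n_nodes < 8) {
    abort("The default layout needs at least 8 nodes (2 per community).")
  }
  frac <- c(PM = 18, AT = 22, MPF = 8, Other = 12) / 60
  sizes <- pmax(2L, round(frac * n_nodes))
  names(sizes) <- names(frac)
  # adjust the largest block so sizes sum to n_nodes
  sizes[which.max(sizes)] <- sizes[which.max(sizes)] + n_nodes - sum(sizes)
  labels <- rep(names(sizes), times = sizes)
  stats::setNames(labels, sprintf("n%03d", seq_len(n_nodes)))
}

#' Node table for a synthetic cohort
#'
#' Builds a node metadata table (id, MNI-like coordinates, sphere radius,
#' reference network label) consistent with the planted partition. The three
#' DMN subnetwork blocks are placed around canonical centroids (PM posterior
#' midline, AT inferior lateral temporal, MPF anterior medial) with seeded
#' jitter; all DMN nodes carry the reference label `"Default mode"`.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `node_id`, `x`, `y`, `z`, `radius`,
#'   `reference_label`, `planted_community`.
#' @export
synthetic_node_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  part <- config$planted_partition
  centroids <- list(
    PM    = c(0, -55, 30),
    AT    = c(45, -5, -25),
    MPF   = c(0, 48, -5),
    Other = c(-30, 10, 45)
  )
  with_seed(derive_seed(config$seed, 9L), {
    coords <- t(vapply(part, function(lab) {
      ctr <- centroids[[lab]]
      if (is.null(ctr)) ctr <- c(0, 0, 0)
      ctr + rnorm(3, 0, 8)
    }, numeric(3)))
  })
  tibble::tibble(
    node_id = names(part),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    radius = 5,
    reference_label = ifelse(part %in% c("PM", "AT", "MPF"),
                             "Default mode", as.character(part)),
    planted_community = as.character(part)
  )
}

#' Generate one subject's realignment-parameter trace
#'
#' A cumulative Gaussian random walk on the six rigid-body parameters
#' (3 translations in mm, 3 rotations in radians), with sporadic single-frame
#' spikes of `spike_magnitude` mm added to one translation axis. The spiked
#' frames are recorded in the `spike_frames` attribute as ground truth.
#'
#' @param config A [simulation_config()].
#' @param subject_index Integer subject index (RNG stream id).
#' @return A `n_frames` x 6 matrix of class `motion_trace` with columns
#'   `trans_x/y/z` (mm) and `rot_x/y/z` (radians), attributes `tr_seconds`
#'   and `spike_frames`.
#' @export
generate_motion_trace <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  t_frames <- config$n_frames
  if (t_frames < 2) abort("`n_frames` must be at least 2.")
  with_seed(derive_seed(config$seed, 1L, subject_index), {
    steps <- cbind(
      matrix(rnorm(3 * t_frames, 0, config$motion_step_sd), t_frames, 3),
      matrix(rnorm(3 * t_frames, 0, config$motion_step_sd / 50), t_frames, 3)
    )
    steps[1, ] <- 0 # reference frame at the origin
    params <- apply(steps, 2, cumsum)
    spike_frames <- integer(0)
    if (config$spike_rate > 0 && config$spike_magnitude > 0) {
      hit <- stats::runif(t_frames) < config$spike_rate
      hit[1] <- FALSE
      spike_frames <- which(hit)
      for (f in spike_frames) {
        axis <- sample.int(3, 1)
        params[f, axis] <- params[f, axis] + config$spike_magnitude
      }
    }
  })
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(params, class = c("motion_trace", "matrix"),
            tr_seconds = config$tr_seconds, spike_frames = spike_frames)
}

#' Generate one subject's WM/CSF surrogate confound series
#'
#' Two standardized AR(1) series standing in for the average white-matter and
#' cerebrospinal-fluid signals.
#'
#' @inheritParams generate_motion_trace
#' @return A `n_frames` x 2 matrix with columns `wm`, `csf`.
#' @export
generate_confounds <- function(config, subject_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  t_frames <- config$n_frames
  with_seed(derive_seed(config$seed, 2L, subject_index), {
    out <- vapply(1:2, function(j) {
      e <- rnorm(t_frames)
      x <- as.numeric(stats::filter(e, 0.3, method = "recursive"))
      x / sd(x)
    }, numeric(t_frames))
  })
  colnames(out) <- c("wm", "csf")
  out
}

# Block-constant correlation matrix from a planted partition.
planted_correlation <- function(partition, rho_within, rho_between) {
  n <- length(partition)
  same <- outer(partition, partition, "==")
  r <- matrix(rho_between, n, n)
  r[same] <- rho_within
  diag(r) <- 1
  dimnames(r) <- list(names(partition), names(partition))
  r
}

#' Generate one subject's node time series
#'
#' Frames are drawn from a multivariate normal whose correlation is
#' `rho_within` inside a planted community and `rho_between` across
#' communities, scaled to mean `signal_mean` and SD `noise_sd` (so the
#' population tSNR of every node is `signal_mean / noise_sd`). Optional
#' contamination adds a shared WM/CSF confound (`confound_gain`) and a
#' motion artifact proportional to framewise displacement (`motion_gain`).
#'
#' @inheritParams generate_motion_trace
#' @param motion Optional [generate_motion_trace()] output for the motion
#'   artifact (required when `motion_gain > 0`).
#' @param confounds Optional [generate_confounds()] output (required when
#'   `confound_gain > 0`).
#' @return A `n_frames` x `n_nodes` numeric matrix, columns named by node id.
#' @export
generate_node_series <- function(config, subject_index = 1L,
                                 motion = NULL, confounds = NULL) {
  stopifnot(inherits(config, "sim_config"))
  part <- config$planted_partition
  r <- planted_correlation(part, config$rho_within, config$rho_between)
  ch <- tryCatch(chol(r), error = function(e) {
    abort("The planted correlation matrix is not positive definite.")
  })
  t_frames <- config$n_frames
  with_seed(derive_seed(config$seed, 3L, subject_index), {
    z <- matrix(rnorm(t_frames * config$n_nodes), t_frames, config$n_nodes)
    if (config$ar_coef > 0) {
      z <- apply(z, 2, function(col) {
        x <- as.numeric(stats::filter(col, config$ar_coef, method = "recursive"))
        x * sqrt(1 - config$ar_coef^2) # restore unit variance
      })
    }
  })
  series <- config$signal_mean + config$noise_sd * (z %*% ch)
  colnames(series) <- names(part)
  if (config$confound_gain > 0) {
    if (is.null(confounds)) abort("`confounds` needed when `confound_gain` > 0.")
    shared <- rowMeans(confounds)
    series <- series + config$confound_gain * shared
  }
  if (config$motion_gain > 0) {
    if (is.null(motion)) abort("`motion` needed when `motion_gain` > 0.")
    fd <- compute_fd(motion)$fd
    series <- series + config$motion_gain * fd
  }
  series
}

#' Generate a full synthetic cohort
#'
#' Produces node series, motion traces, confounds, a node table and a subject
#' table (group labels HC/CHR/FEP, medication dummy for patients) plus a
#' ground-truth record. Symptom scores are *not* generated here: they depend
#' on connectivity profiles computed from the generated data by the real
#' pipeline, and are filled in by [generate_symptoms()].
#'
#' @param config A [simulation_config()].
#' @return An object of class `dmn_cohort`: a list with elements `series`
#'   (named list of frames x nodes matrices), `motion`, `confounds`,
#'   `nodes` (tibble), `subjects` (tibble), `truth` (list), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  ids <- sprintf("s%03d", seq_len(n))
  groups <- allocate_groups(n)
  with_seed(derive_seed(config$seed, 4L), {
    medicated <- ifelse(groups == "HC", NA,
                        stats::runif(n) < 0.47)
  })
  # emulate missing symptom interviews: the first two CHR subjects (if any)
  chr_idx <- which(groups == "CHR")
  missing_sympt <- head(chr_idx, min(2L, max(0L, length(chr_idx) - 1L)))
  has_symptoms <- groups != "HC"
  has_symptoms[missing_sympt] <- FALSE

  motion <- confounds <- series <- vector("list", n)
  names(motion) <- names(confounds) <- names(series) <- ids
  spike_frames <- vector("list", n)
  names(spike_frames) <- ids
  for (i in seq_len(n)) {
    motion[[i]] <- generate_motion_trace(config, i)
    confounds[[i]] <- generate_confounds(config, i)
    series[[i]] <- generate_node_series(config, i, motion[[i]], confounds[[i]])
    spike_frames[[i]] <- attr(motion[[i]], "spike_frames")
  }
  subjects <- tibble::tibble(
    subject_id = ids, group = groups, medicated = medicated,
    has_symptoms = has_symptoms,
    panss_positive = NA_real_, panss_negative = NA_real_,
    panss_general = NA_real_
  )
  structure(list(
    series = series, motion = motion, confounds = confounds,
    nodes = synthetic_node_table(config), subjects = subjects,
    truth = list(
      planted_partition = config$planted_partition,
      betas = c(mpf_pm = config$beta_mpf_pm, mpf_at = config$beta_mpf_at,
                fd = config$beta_fd),
      spike_frames = spike_frames
    ),
    config = config
  ), class = "dmn_cohort")
}

# Deterministic HC/CHR/FEP allocation in study proportions 39:11:19.
allocate_groups <- function(n) {
  if (n < 3) return(rep(c("HC", "FEP", "CHR"), length.out = n))
  n_fep <- max(1L, round(n * 19 / 69))
  n_chr <- max(1L, round(n * 11 / 69))
  n_hc <- n - n_fep - n_chr
  rep(c("HC", "CHR", "FEP"), times = c(n_hc, n_chr, n_fep))
}

#' Generate symptom scores from pipeline-derived connectivity profiles
#'
#' The negative score follows the planted linear model
#' `beta_mpf_pm * z(MPF,PM) + beta_mpf_at * z(MPF,AT) + beta_fd * meanFD`
#' plus Gaussian noise, recentred to a plausible PANSS negative-subscale
#' level. The positive score is generated with a tunable correlation
#' (`fd_positive_cor`) to mean FD; the general score is pure noise. Scores
#' are clipped to the instrument ranges (positive/negative 7-49, general
#' 16-112) and left continuous.
#'
#' @param config A [simulation_config()].
#' @param profiles Tibble with columns `subject_id`, `mpf_pm`, `mpf_at`
#'   (Fisher-z connectivity computed by the pipeline, e.g.
#'   [subnetwork_profiles()]).
#' @param mean_fd Tibble with columns `subject_id`, `mean_fd` (mm), or a
#'   named numeric vector.
#' @return Tibble `subject_id`, `panss_positive`, `panss_negative`,
#'   `panss_general`.
#' @export
generate_symptoms <- function(config, profiles, mean_fd) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("subject_id", "mpf_pm", "mpf_at") %in% names(profiles))) {
    abort("`profiles` must have columns subject_id, mpf_pm, mpf_at.")
  }
  if (is.numeric(mean_fd)) {
    mean_fd <- tibble::tibble(subject_id = names(mean_fd), mean_fd = unname(mean_fd))
  }
  d <- dplyr::inner_join(profiles, mean_fd, by = "subject_id")
  if (nrow(d) != nrow(profiles) || nrow(d) != length(unique(d$subject_id))) {
    abort("`profiles` and `mean_fd` subjects do not align one-to-one.")
  }
  n <- nrow(d)
  det <- config$beta_mpf_pm * d$mpf_pm + config$beta_mpf_at * d$mpf_at +
    config$beta_fd * d$mean_fd
  with_seed(derive_seed(config$seed, 5L), {
    eps_neg <- rnorm(n, 0, config$symptom_noise_sd)
    eps_pos <- rnorm(n)
    eps_gen <- rnorm(n)
  })
  negative <- 15.7 + (det - mean(det)) + eps_neg
  rho <- config$fd_positive_cor
  fd_std <- if (sd(d$mean_fd) > 0) {
    as.numeric(scale(d$mean_fd))
  } else {
    rep(0, n)
  }
  positive <- 11.6 + 3.2 * (rho * fd_std + sqrt(1 - rho^2) * eps_pos)
  general <- 29.2 + 6.6 * eps_gen
  tibble::tibble(
    subject_id = d$subject_id,
    panss_positive = pmin(pmax(positive, 7), 49),
    panss_negative = pmin(pmax(negative, 7), 49),
    panss_general = pmin(pmax(general, 16), 112)
  )
}

#' Write a cohort to plain-text fixtures
#'
#' Writes one node-series TSV and one 6-column whitespace motion text per
#' subject, a confound TSV, the node and subject tables, the ground-truth
#' record (JSON) and a manifest with MD5 checksums.
#'
#' @param cohort A [generate_cohort()] result.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the manifest tibble (`file`, `md5`).
#' @export
write_fixture_set <- function(cohort, directory) {
  stopifnot(inherits(cohort, "dmn_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) abort("Cannot create output directory.")
  files <- character(0)
  wr <- function(rel) {
    path <- file.path(directory, rel)
    files <<- c(files, rel)
    path
  }
  # numeric matrices are written with %.17g so doubles round-trip exactly
  write_matrix_tsv <- function(m, path) {
    body <- apply(m, 1, function(row) {
      paste(sprintf("%.17g", row), collapse = "\t")
    })
    writeLines(c(paste(colnames(m), collapse = "\t"), body), path)
  }
  for (id in names(cohort$series)) {
    write_matrix_tsv(cohort$series[[id]], wr(sprintf("series_%s.tsv", id)))
    m <- cohort$motion[[id]]
    lines <- apply(unclass(m), 1, function(row) {
      paste(sprintf("%.17g", row), collapse = " ")
    })
    writeLines(lines, wr(sprintf("motion_%s.txt", id)))
    write_matrix_tsv(cohort$confounds[[id]],
                     wr(sprintf("confounds_%s.tsv", id)))
  }
  readr::write_tsv(cohort$nodes, wr("nodes.tsv"), progress = FALSE)
  readr::write_tsv(cohort$subjects, wr("subjects.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(planted_partition = as.list(cohort$truth$planted_partition),
         betas = as.list(cohort$truth$betas),
         spike_frames = cohort$truth$spike_frames),
    wr("truth.json"), auto_unbox = TRUE, digits = NA
  )
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(directory, files)))
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       dataframe = "rows")
  invisible(manifest)
}

#' Read a node-series TSV (frames x nodes, node ids as header)
#' @param path File path.
#' @return Numeric matrix frames x nodes.
#' @export
read_node_series <- function(path) {
  # base parser: correctly-rounded doubles, so %.17g text round-trips exactly
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  m <- as.matrix(d)
  rownames(m) <- NULL
  m
}

#' Read a 6-column whitespace realignment-parameter file
#'
#' Columns are 3 translations (mm) then 3 rotations (radians), one row per
#' frame — the common realignment-parameter dialect.
#'
#' @param path File path.
#' @param tr_seconds Repetition time attached to the trace.
#' @return A `motion_trace` matrix.
#' @export
read_motion_trace <- function(path, tr_seconds = 2) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) abort("Motion file must have exactly 6 columns.")
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  rownames(m) <- NULL
  structure(m, class = c("motion_trace", "matrix"), tr_seconds = tr_seconds)
}

#' Read a fixture directory written by [write_fixture_set()]
#' @param directory Directory containing the fixtures.
#' @return A `dmn_cohort` list (without `config`).
#' @export
read_fixture_set <- function(directory) {
  subjects <- readr::read_tsv(file.path(directory, "subjects.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  nodes <- readr::read_tsv(file.path(directory, "nodes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  truth <- jsonlite::read_json(file.path(directory, "truth.json"))
  ids <- subjects$subject_id
  series <- lapply(ids, function(id) {
    read_node_series(file.path(directory, sprintf("series_%s.tsv", id)))
  })
  motion <- lapply(ids, function(id) {
    read_motion_trace(file.path(directory, sprintf("motion_%s.txt", id)))
  })
  confounds <- lapply(ids, function(id) {
    read_node_series(file.path(directory, sprintf("confounds_%s.tsv", id)))
  })
  names(series) <- names(motion) <- names(confounds) <- ids
  structure(list(series = series, motion = motion, confounds = confounds,
                 nodes = nodes, subjects = subjects,
                 truth = list(
                   planted_partition = unlist(truth$planted_partition),
                   betas = unlist(truth$betas),
                   spike_frames = lapply(truth$spike_frames, unlist)
                 )),
            class = "dmn_cohort")
}
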