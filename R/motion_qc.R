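#' Framewise displacement from realignment parameters
#'
#' Power-style scalar head-motion summary: for each frame the sum of absolute
#' backward differences of the six rigid-body parameters, with rotations
#' converted from radians to millimetres of arc on a sphere of radius
#' `sphere_radius_mm` (the conventional 50 mm). The first frame is 0 by
#' convention.
#'
#' @param motion A frames x 6 matrix (3 translations mm, 3 rotations rad),
#'   e.g. a `motion_trace`.
#' @param sphere_radius_mm Rotation-to-translation conversion radius.
#' @return Tibble with columns `frame` and `fd` (mm).
#' @export
#' @examples
#' m <- matrix(0, 4, 6)
#' m[2, 1] <- 0.1; m[2, 5] <- 0.002
#' compute_fd(m)$fd[2] # 0.1 + 50 * 0.002 = 0.2
compute_fd <- function(motion, sphere_radius_mm = 50) {
  m <- unclass(motion)
  if (!is.matrix(m) || ncol(m) != 6) {
    abort("`motion` must be a frames x 6 matrix.")
  }
  if (nrow(m) < 2) abort("FD needs at least 2 frames.")
  if (anyNA(m) || !all(is.finite(m))) {
    abort("`motion` contains non-finite parameters.")
  }
  d <- abs(diff(m))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            sphere_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  tibble::tibble(frame = seq_len(nrow(m)), fd = fd)
}

#' Flag high-motion frames for scrubbing
#'
#' Frames with FD strictly above the threshold ("more than 0.5 mm") are
#' flagged as outliers; each gets one spike (scrubbing) regressor
#' downstream.
#'
#' @param fd Tibble from [compute_fd()] (columns `frame`, `fd`).
#' @param threshold_mm Scrub threshold in mm (default 0.5).
#' @return The input tibble with a logical `outlier` column and attribute
#'   `threshold_mm`.
#' @export
flag_outliers <- function(fd, threshold_mm = 0.5) {
  stopifnot(is.data.frame(fd), all(c("frame", "fd") %in% names(fd)))
  out <- dplyr::mutate(fd, outlier = .data$fd > threshold_mm)
  attr(out, "threshold_mm") <- threshold_mm
  out
}

#' Spike (scrubbing) regressor matrix
#'
#' One indicator column per flagged frame: 1 at that frame, 0 elsewhere.
#'
#' @param flags Output of [flag_outliers()].
#' @return A frames x n_outliers 0/1 matrix (0 columns when no outliers),
#'   columns named `spike_<frame>`.
#' @export
spike_matrix <- function(flags) {
  frames <- flags$frame[flags$outlier]
  n <- nrow(flags)
  s <- matrix(0, n, length(frames))
  if (length(frames)) {
    s[cbind(frames, seq_along(frames))] <- 1
    colnames(s) <- sprintf("spike_%d", frames)
  }
  s
}

#' Per-subject motion exclusion decision
#'
#' A subject is excluded iff the maximum absolute translation relative to
#' the reference (first) frame exceeds `abs_threshold_mm` in any axis, or
#' the fraction of frames with FD above `threshold_mm` exceeds
#' `max_outlier_frac`. Both comparisons are strict ("more than"), so e.g.
#' 31/185 outliers (16.8%) is retained and 32/185 (17.3%) is excluded.
#'
#' @param motion A frames x 6 motion matrix.
#' @param fd Optional precomputed [compute_fd()] tibble.
#' @param threshold_mm FD scrub threshold (default 0.5 mm).
#' @param max_outlier_frac Maximum tolerated outlier fraction (default 0.17).
#' @param abs_threshold_mm Maximum tolerated absolute translation
#'   (default 3 mm). Rotations are not included in the absolute-motion rule.
#' @return One-row tibble: `mean_fd`, `max_abs_mm`, `n_outliers`,
#'   `outlier_frac`, `excluded`, `reason`.
#' @export
exclusion_decision <- function(motion, fd = NULL, threshold_mm = 0.5,
                               max_outlier_frac = 0.17, abs_threshold_mm = 3) {
  m <- unclass(motion)
  if (is.null(fd)) fd <- compute_fd(m)
  flags <- flag_outliers(fd, threshold_mm)
  n_out <- sum(flags$outlier)
  frac <- n_out / nrow(flags)
  rel <- sweep(m[, 1:3, drop = FALSE], 2, m[1, 1:3])
  max_abs <- max(abs(rel))
  abs_bad <- max_abs > abs_threshold_mm
  frac_bad <- frac > max_outlier_frac
  reason <- if (abs_bad && frac_bad) {
    "absolute motion; outlier fraction"
  } else if (abs_bad) {
    "absolute motion"
  } else if (frac_bad) {
    "outlier fraction"
  } else {
    NA_character_
  }
  tibble::tibble(
    mean_fd = mean(fd$fd), max_abs_mm = max_abs,
    n_outliers = n_out, outlier_frac = frac,
    excluded = abs_bad || frac_bad, reason = reason
  )
}

#' Motion QC report for a whole cohort
#'
#' @param cohort A `dmn_cohort` (or any list with a `motion` element of
#'   per-subject motion matrices).
#' @inheritParams exclusion_decision
#' @return Tibble with one row per subject (`subject_id` first).
#' @export
qc_report <- function(cohort, threshold_mm = 0.5, max_outlier_frac = 0.17,
                      abs_threshold_mm = 3) {
  motion <- if (is.list(cohort) && !is.null(cohort$motion)) cohort$motion else cohort
  purrr::imap_dfr(motion, function(m, id) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = id),
      exclusion_decision(m, threshold_mm = threshold_mm,
                         max_outlier_frac = max_outlier_frac,
                         abs_threshold_mm = abs_threshold_mm)
    )
  })
}

#' Discrete cosine high-pass basis
#'
#' The K lowest-frequency discrete-cosine basis vectors (excluding the
#' constant term, which is carried by the design intercept), with
#' `K = floor(2 * T * TR * cutoff_hz)`. Regressing these out removes
#' fluctuations slower than the cutoff.
#'
#' @param n_frames Number of frames T.
#' @param tr_seconds Repetition time (s).
#' @param cutoff_hz High-pass cutoff frequency (default 0.01 Hz); 0 disables
#'   the basis (K = 0).
#' @return A T x K matrix (K may be 0), columns named `dct_<k>`.
#' @export
#' @examples
#' ncol(dct_basis(185, 2, 0.01)) # floor(2 * 370 * 0.01) = 7
dct_basis <- function(n_frames, tr_seconds, cutoff_hz = 0.01) {
  k_max <- floor(2 * n_frames * tr_seconds * cutoff_hz)
  t_idx <- seq_len(n_frames) - 1
  b <- vapply(seq_len(k_max), function(k) {
    sqrt(2 / n_frames) * cos(pi * (2 * t_idx + 1) * k / (2 * n_frames))
  }, numeric(n_frames))
  b <- matrix(b, nrow = n_frames)
  if (k_max > 0) colnames(b) <- sprintf("dct_%d", seq_len(k_max))
  b
}

#' Assemble the nuisance regression design
#'
#' Column order: intercept, the six realignment parameters, mean WM, mean
#' CSF, one spike column per flagged frame, then the DCT high-pass basis.
#' Degenerate (constant or duplicate) columns other than the intercept are
#' dropped with a warning so the design has full column rank.
#'
#' @param motion Frames x 6 motion matrix.
#' @param wm,csf Numeric confound series (same frame count).
#' @param spikes Spike matrix from [spike_matrix()] (may have 0 columns) or
#'   `NULL`.
#' @param highpass_hz High-pass cutoff (default 0.01 Hz; 0 disables).
#' @param tr_seconds Repetition time in seconds.
#' @return A frames x p design matrix with a `roles` attribute naming each
#'   column's role.
#' @export
build_design <- function(motion, wm, csf, spikes = NULL,
                         highpass_hz = 0.01, tr_seconds = 2) {
  m <- unclass(motion)
  t_frames <- nrow(m)
  lens <- c(length(wm), length(csf), if (!is.null(spikes)) nrow(spikes))
  if (any(lens != t_frames)) {
    abort("Motion, confounds and spikes must share the same frame count.")
  }
  if (is.null(spikes)) spikes <- matrix(0, t_frames, 0)
  dct <- dct_basis(t_frames, tr_seconds, highpass_hz)
  x <- cbind(intercept = 1, m, wm = wm, csf = csf, spikes, dct)
  roles <- c("intercept", rep("motion", 6), "wm", "csf",
             rep("spike", ncol(spikes)), rep("dct", ncol(dct)))
  # prune rank-deficient columns (keep the earliest of any dependent set)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    keep <- sort(qr_x$pivot[seq_len(qr_x$rank)])
    warn(sprintf("Dropping %d rank-deficient design column(s).",
                 ncol(x) - length(keep)))
    x <- x[, keep, drop = FALSE]
    roles <- roles[keep]
  }
  attr(x, "roles") <- roles
  x
}

#' Regress nuisance signals out of node series
#'
#' Ordinary least-squares residuals of each node's time series against the
#' nuisance design. Residuals are orthogonal to every design column; in
#' particular, frames carrying a spike regressor have residual exactly 0 for
#' every node, which removes scrubbed frames' influence without deleting
#' them.
#'
#' @param series Frames x nodes numeric matrix.
#' @param design Design matrix from [build_design()].
#' @return Residual frames x nodes matrix (same dimnames as `series`).
#' @export
regress_nuisance <- function(series, design) {
  y <- as_series_matrix(series)
  if (nrow(y) != nrow(design)) {
    abort("`series` and `design` must have the same number of frames.")
  }
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    abort("Singular nuisance design: prune dependent columns (see build_design()).")
  }
  res <- qr.resid(qr_x, y)
  dimnames(res) <- dimnames(y)
  res
}

#' Temporal signal-to-noise ratio per node
#'
#' Temporal mean divided by temporal SD of each node's series, computed on
#' the extracted series *before* nuisance regression. Constant series get an
#' infinite-tSNR sentinel (they are never excluded by a "below 50" rule).
#'
#' @param series Frames x nodes numeric matrix.
#' @return Tibble with columns `node_id` and `tsnr`.
#' @export
compute_tsnr <- function(series) {
  y <- as_series_matrix(series)
  if (nrow(y) < 2) abort("tSNR needs at least 2 frames.")
  mu <- colMeans(y)
  sdev <- apply(y, 2, sd)
  tsnr <- ifelse(sdev == 0, Inf, mu / sdev)
  ids <- colnames(y)
  if (is.null(ids)) ids <- sprintf("n%03d", seq_along(tsnr))
  tibble::tibble(node_id = ids, tsnr = unname(tsnr))
}

#' Motion QC + nuisance regression for a whole cohort
#'
#' Runs the full denoising stage on every subject: FD, outlier flagging,
#' exclusion decisions, design assembly and nuisance regression. Excluded
#' subjects are dropped from the residual series.
#'
#' @param cohort A `dmn_cohort`.
#' @inheritParams exclusion_decision
#' @param highpass_hz High-pass cutoff for the DCT basis.
#' @param drop_excluded Drop subjects failing QC from the output (default
#'   `TRUE`).
#' @return List with `qc` (QC report tibble), `residuals` (named list of
#'   residual series matrices), `tsnr` (long tibble subject x node, computed
#'   before regression).
#' @export
denoise_cohort <- function(cohort, threshold_mm = 0.5, max_outlier_frac = 0.17,
                           abs_threshold_mm = 3, highpass_hz = 0.01,
                           drop_excluded = TRUE) {
  stopifnot(is.list(cohort), !is.null(cohort$series), !is.null(cohort$motion))
  qc <- qc_report(cohort, threshold_mm, max_outlier_frac, abs_threshold_mm)
  ids <- names(cohort$series)
  keep <- if (drop_excluded) qc$subject_id[!qc$excluded] else ids
  tsnr <- purrr::imap_dfr(cohort$series, function(s, id) {
    dplyr::mutate(compute_tsnr(s), subject_id = id, .before = 1)
  })
  residuals <- lapply(keep, function(id) {
    m <- cohort$motion[[id]]
    fd <- compute_fd(m)
    spikes <- spike_matrix(flag_outliers(fd, threshold_mm))
    conf <- cohort$confounds[[id]]
    design <- build_design(m, conf[, "wm"], conf[, "csf"], spikes,
                           highpass_hz = highpass_hz,
                           tr_seconds = attr(m, "tr_seconds") %||% 2)
    regress_nuisance(cohort$series[[id]], design)
  })
  names(residuals) <- keep
  list(qc = qc, residuals = residuals, tsnr = tsnr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
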