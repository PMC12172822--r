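#' Fisher z-transform of a correlation
#'
#' `z = atanh(r)`, the variance-stabilizing transform used before averaging
#' and testing connectivity values.
#'
#' @param r Correlation value(s) with `|r| < 1`.
#' @return The transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("`r` must satisfy |r| < 1.")
  }
  atanh(r)
}

#' Within/between-subnetwork Fisher-z connectivity profile
#'
#' Computes one subject's six-value profile: mean Fisher-z connectivity
#' within PM, within AT, within MPF, and between MPF-PM, PM-AT, MPF-AT.
#' Within-block means run over unique unordered node pairs (self-pairs
#' excluded); between-block means over all cross pairs. By default each
#' correlation is z-transformed before averaging (`"z_first"`); the
#' alternative `"r_first"` averages r then transforms.
#'
#' @param matrix Connectivity matrix covering (at least) the partition's
#'   nodes.
#' @param partition Tibble with `node_id` and `subnetwork`
#'   (PM / AT / MPF), e.g. `membership` from [subcluster_dmn()].
#' @param mode `"z_first"` (default) or `"r_first"`.
#' @return One-row tibble with columns `within_pm`, `within_at`,
#'   `within_mpf`, `mpf_pm`, `pm_at`, `mpf_at`.
#' @export
subnetwork_profile <- function(matrix, partition,
                               mode = c("z_first", "r_first")) {
  mode <- match.arg(mode)
  part <- partition[!is.na(partition$subnetwork) &
                      partition$subnetwork %in% c("PM", "AT", "MPF"), ]
  missing <- setdiff(part$node_id, rownames(matrix))
  if (length(missing)) {
    abort(paste0("Matrix is missing node(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  blocks <- split(part$node_id, part$subnetwork)
  for (b in c("PM", "AT", "MPF")) {
    if (is.null(blocks[[b]]) || !length(blocks[[b]])) {
      abort(sprintf("Subnetwork %s is empty.", b))
    }
  }
  within <- function(ids) {
    if (length(ids) < 2) {
      abort("A within-subnetwork mean needs at least 2 nodes.")
    }
    sub <- matrix[ids, ids, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    block_mean(vals, mode)
  }
  between <- function(ids_a, ids_b) {
    block_mean(as.vector(matrix[ids_a, ids_b, drop = FALSE]), mode)
  }
  tibble::tibble(
    within_pm = within(blocks$PM),
    within_at = within(blocks$AT),
    within_mpf = within(blocks$MPF),
    mpf_pm = between(blocks$MPF, blocks$PM),
    pm_at = between(blocks$PM, blocks$AT),
    mpf_at = between(blocks$MPF, blocks$AT)
  )
}

block_mean <- function(r, mode) {
  if (mode == "z_first") mean(fisher_z(r)) else fisher_z(mean(r))
}

#' Connectivity profiles for a cohort
#'
#' @param matrices Named list of per-subject connectivity matrices.
#' @param partition As in [subnetwork_profile()].
#' @inheritParams subnetwork_profile
#' @return Tibble with `subject_id` and the six profile columns.
#' @export
subnetwork_profiles <- function(matrices, partition, mode = "z_first") {
  purrr::imap_dfr(matrices, function(m, id) {
    dplyr::bind_cols(tibble::tibble(subject_id = id),
                     subnetwork_profile(m, partition, mode))
  })
}

#' Pooled-variance two-sample t-test from raw values
#'
#' Student's t with pooled variance and `df = n1 + n2 - 2`, two-tailed;
#' the statistic is `(mean(a) - mean(b)) / se`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return One-row tibble: `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`,
#'   `n_b`, `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("Each group needs >= 2 values.")
  res <- t_from_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
  dplyr::bind_cols(
    tibble::tibble(mean_a = mean(a), sd_a = sd(a), n_a = length(a),
                   mean_b = mean(b), sd_b = sd(b), n_b = length(b)),
    res
  )
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Identical to [two_sample_t()] when the summaries derive from the same raw
#' data; useful for checking statistics reported from group means and SDs.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
#' @examples
#' t_from_summary(47.00, 10.87, 9, 34.68, 11.92, 19) # t ~ 2.62, df 26
t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) abort("Each group needs n >= 2.")
  if (sd_a < 0 || sd_b < 0 || (sd_a == 0 && sd_b == 0)) {
    abort("Group SDs must be non-negative and not both zero.")
  }
  df <- n_a + n_b - 2
  pooled_var <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  se <- sqrt(pooled_var * (1 / n_a + 1 / n_b))
  t_stat <- (mean_a - mean_b) / se
  tibble::tibble(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}

#' Pearson chi-square test on a 2x2 count table
#'
#' Pearson's chi-square without continuity correction by default (a Yates
#' correction is available via `correct = TRUE`), df = 1.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
chi_square_counts <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2) || any(counts < 0)) {
    abort("`counts` must be a 2x2 matrix of non-negative counts.")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("Chi-square is undefined with a zero marginal.")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter), p = res$p.value)
}

#' Compare connectivity profiles between two groups
#'
#' Runs a pooled-variance two-sample t-test per profile measure, producing
#' a per-measure report (group means, SDs, t, df, p) in the standard
#' within-first ordering (PM, AT, MPF, MPF x PM, PM x AT, MPF x AT). No
#' multiple-testing correction is applied by default; `adjust = "bonferroni"`
#' adds an adjusted p column.
#'
#' @param profiles Tibble from [subnetwork_profiles()].
#' @param groups Tibble with `subject_id` and `group`.
#' @param group_a,group_b The two group labels to compare; `group_b` may be
#'   a vector (e.g. both patient subgroups).
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return Tibble with one row per measure.
#' @export
compare_profiles <- function(profiles, groups, group_a, group_b,
                             adjust = "none") {
  d <- dplyr::inner_join(profiles, groups, by = "subject_id")
  measures <- c("within_pm", "within_at", "within_mpf",
                "mpf_pm", "pm_at", "mpf_at")
  measures <- intersect(measures, names(d))
  out <- purrr::map_dfr(measures, function(mname) {
    a <- d[[mname]][d$group %in% group_a]
    b <- d[[mname]][d$group %in% group_b]
    dplyr::bind_cols(tibble::tibble(measure = mname), two_sample_t(a, b))
  })
  if (adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  }
  out
}
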