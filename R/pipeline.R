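#' Run the full subnetwork-connectivity pipeline on a cohort
#'
#' Convenience wrapper chaining the pipeline stages: motion QC and nuisance
#' regression ([denoise_cohort()]), tSNR node filtering
#' ([filter_nodes_by_tsnr()]), per-subject connectivity matrices
#' ([pearson_matrix()]), whole-brain consensus parcellation
#' ([consensus_partition()]) at `gamma_whole`, DMN identification
#' ([identify_dmn()]), DMN subclustering at `gamma_dmn`
#' ([subcluster_dmn()]), and per-subject within/between-subnetwork
#' Fisher-z profiles ([subnetwork_profiles()]).
#'
#' @param cohort A `dmn_cohort` (e.g. [generate_cohort()] output, or a
#'   fixture set read back with [read_fixture_set()]).
#' @param gamma_whole Resolution for the whole-brain parcellation
#'   (default 1.25).
#' @param gamma_dmn Resolution for the DMN subclustering (default 1.00).
#' @param iterations Louvain ensemble size (default 1000).
#' @param stability_threshold Consensus stability cutoff (default 0.40).
#' @param seed Integer seed for all randomized stages.
#' @param restarts Random restarts per Louvain run.
#' @param dmn_label Reference label naming default-mode nodes.
#' @param dmn_mode [identify_dmn()] mode: `"largest"` (one detected
#'   community) or `"union"` (all communities dominated by the reference
#'   DMN label; appropriate when the whole-brain resolution already splits
#'   the DMN into its subnetworks).
#' @param highpass_hz DCT high-pass cutoff (default 0.01 Hz).
#' @return List with `qc`, `node_filter`, `matrices` (retained-node
#'   per-subject connectivity), `whole_brain` (partition ensemble),
#'   `dmn_ids`, `dmn` (a `dmn_partition`), `profiles`, `mean_fd` (tibble).
#' @export
run_dmn_pipeline <- function(cohort, gamma_whole = 1.25, gamma_dmn = 1.00,
                             iterations = 1000, stability_threshold = 0.40,
                             seed = 1, restarts = 20,
                             dmn_label = "Default mode",
                             dmn_mode = "largest", highpass_hz = 0.01) {
  den <- denoise_cohort(cohort, highpass_hz = highpass_hz)
  filt <- filter_nodes_by_tsnr(den$tsnr, cohort$nodes)
  keep_nodes <- filt$node_id[filt$retained]
  matrices <- lapply(den$residuals, function(s) {
    pearson_matrix(s[, keep_nodes, drop = FALSE])
  })
  avg <- group_average(matrices)
  whole <- consensus_partition(avg, gamma = gamma_whole,
                               iterations = iterations,
                               stability_threshold = stability_threshold,
                               seed = seed, restarts = restarts)
  dmn_ids <- identify_dmn(whole, cohort$nodes, dmn_label = dmn_label,
                          mode = dmn_mode)
  dmn <- subcluster_dmn(matrices, dmn_ids, cohort$nodes, gamma = gamma_dmn,
                        iterations = iterations,
                        stability_threshold = stability_threshold,
                        seed = seed + 1, restarts = restarts)
  profiles <- subnetwork_profiles(matrices, dmn$membership)
  mean_fd <- den$qc[, c("subject_id", "mean_fd")]
  list(qc = den$qc, node_filter = filt, matrices = matrices,
       whole_brain = whole, dmn_ids = dmn_ids, dmn = dmn,
       profiles = profiles, mean_fd = mean_fd)
}

#' Predict a symptom score from connectivity profiles
#'
#' The prediction stage: joins connectivity profiles with the subject
#' table, keeps patients with symptom data, enters the six profile
#' measures plus mean FD into [bootstrap_vip()], and refits the selected
#' predictors by OLS with optional dummy co-predictors
#' ([ols_refit()], [r2_change()]).
#'
#' @param profiles Tibble from [subnetwork_profiles()].
#' @param subjects Subject table with `subject_id`, `group`, symptom
#'   columns, and optionally `medicated`.
#' @param mean_fd Tibble `subject_id`, `mean_fd`.
#' @param outcome Name of the response column (default `"panss_negative"`).
#' @param alpha,B,threshold,seed Passed to [bootstrap_vip()].
#' @param medication_dummy Add `medicated` as an OLS co-predictor and test
#'   its R-squared change (default `TRUE` when the column exists).
#' @return List with `vip` (`vip_result`), `model` (`ols_refit` over the
#'   selected predictors, or `NULL` when none selected), `medication`
#'   (r2_change tibble or `NULL`), `data` (the analysis tibble).
#' @export
predict_symptoms <- function(profiles, subjects, mean_fd,
                             outcome = "panss_negative", alpha = 0.5,
                             B = 5000, threshold = 0.70, seed = 1,
                             medication_dummy = TRUE) {
  d <- profiles |>
    dplyr::inner_join(subjects, by = "subject_id") |>
    dplyr::inner_join(mean_fd, by = "subject_id")
  if (!outcome %in% names(d)) abort(sprintf("No column `%s`.", outcome))
  d <- d[!is.na(d[[outcome]]), ]
  predictors <- c("within_pm", "within_at", "within_mpf",
                  "mpf_pm", "pm_at", "mpf_at", "mean_fd")
  x <- as.matrix(d[, predictors])
  y <- d[[outcome]]
  vip <- bootstrap_vip(x, y, alpha = alpha, B = B, threshold = threshold,
                       seed = seed)
  model <- NULL
  medication <- NULL
  if (length(vip$selected)) {
    co <- NULL
    if (medication_dummy && "medicated" %in% names(d) &&
        !anyNA(d$medicated)) {
      co <- data.frame(medicated = as.numeric(d$medicated))
    }
    model <- ols_refit(x[, vip$selected, drop = FALSE], y)
    if (!is.null(co)) {
      medication <- r2_change(model, co$medicated, "medicated")
    }
  }
  list(vip = vip, model = model, medication = medication, data = d)
}
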