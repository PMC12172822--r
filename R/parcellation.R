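#' Filter nodes by temporal signal-to-noise ratio and reference label
#'
#' Drops nodes whose across-subject mean tSNR is below `mean_min`, whose
#' minimum across subjects is below `subject_min`, or whose reference label
#' is `"uncertain"`. Both tSNR rules are strict "below" comparisons, so a
#' mean of exactly 50 is kept.
#'
#' @param tsnr Long tibble with columns `subject_id`, `node_id`, `tsnr`
#'   (e.g. from [denoise_cohort()]).
#' @param node_table Tibble with `node_id` and `reference_label`.
#' @param mean_min Minimum across-subject mean tSNR (default 50).
#' @param subject_min Minimum per-subject tSNR (default 30).
#' @return Tibble `node_id`, `mean_tsnr`, `min_tsnr`, `reference_label`,
#'   `retained`, `reason`.
#' @export
filter_nodes_by_tsnr <- function(tsnr, node_table, mean_min = 50,
                                 subject_min = 30) {
  stopifnot(all(c("subject_id", "node_id", "tsnr") %in% names(tsnr)))
  summ <- tsnr |>
    dplyr::group_by(.data$node_id) |>
    dplyr::summarise(mean_tsnr = mean(.data$tsnr),
                     min_tsnr = min(.data$tsnr), .groups = "drop") |>
    dplyr::left_join(dplyr::select(node_table, "node_id", "reference_label"),
                     by = "node_id")
  summ |>
    dplyr::mutate(
      low_mean = .data$mean_tsnr < mean_min,
      low_min = .data$min_tsnr < subject_min,
      uncertain = !is.na(.data$reference_label) &
        tolower(.data$reference_label) == "uncertain",
      retained = !.data$low_mean & !.data$low_min & !.data$uncertain,
      reason = dplyr::case_when(
        uncertain ~ "uncertain label",
        low_mean & low_min ~ "mean and minimum tSNR",
        low_mean ~ "mean tSNR",
        low_min ~ "minimum tSNR",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("node_id", "mean_tsnr", "min_tsnr", "reference_label",
                  "retained", "reason")
}

#' Pearson connectivity matrix of a node-series matrix
#'
#' @param series Frames x nodes numeric matrix (residual series after
#'   nuisance regression).
#' @return Symmetric nodes x nodes correlation matrix with unit diagonal,
#'   dimnames from the series columns.
#' @export
pearson_matrix <- function(series) {
  y <- as_series_matrix(series)
  if (nrow(y) < 3) abort("Connectivity needs at least 3 frames.")
  sds <- apply(y, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(y)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    abort(paste0("Zero-variance node(s): ", paste(bad, collapse = ", ")))
  }
  r <- cor(y)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Group-average connectivity matrix
#'
#' Element-wise mean of per-subject correlation matrices. The default
#' averages raw r values; `mode = "z"` Fisher-transforms, averages, and
#' back-transforms.
#'
#' @param matrices List of per-subject correlation matrices over identical
#'   node sets.
#' @param mode `"r"` (default) or `"z"`.
#' @return The averaged matrix.
#' @export
group_average <- function(matrices, mode = c("r", "z")) {
  mode <- match.arg(mode)
  stopifnot(is.list(matrices), length(matrices) >= 1)
  ref <- dimnames(matrices[[1]])
  dims_ok <- vapply(matrices, function(m) {
    identical(dim(m), dim(matrices[[1]])) && identical(dimnames(m), ref)
  }, logical(1))
  if (!all(dims_ok)) abort("All matrices must share the same node set.")
  if (mode == "r") {
    avg <- Reduce(`+`, matrices) / length(matrices)
  } else {
    zs <- lapply(matrices, function(m) {
      z <- atanh(pmin(pmax(m, -0.999999), 0.999999))
      diag(z) <- 0
      z
    })
    avg <- tanh(Reduce(`+`, zs) / length(matrices))
    diag(avg) <- 1
  }
  avg
}

#' Identify the default-mode community in a consensus partition
#'
#' Returns the node ids of the consensus community containing the largest
#' number of nodes whose reference label is the default-mode label. Ties are
#' broken deterministically: larger community first, then lowest community
#' index. With `mode = "union"`, all communities whose plurality reference
#' label is the default-mode label are returned together — appropriate when
#' the resolution has already split the DMN into its subnetworks.
#'
#' @param ensemble A [consensus_partition()] result (removed nodes are
#'   ignored).
#' @param node_table Tibble with `node_id` and `reference_label`.
#' @param dmn_label The default-mode reference label
#'   (default `"Default mode"`).
#' @param mode `"largest"` (default) or `"union"`.
#' @return Character vector of DMN node ids.
#' @export
identify_dmn <- function(ensemble, node_table, dmn_label = "Default mode",
                         mode = c("largest", "union")) {
  mode <- match.arg(mode)
  cons <- ensemble$consensus[!ensemble$consensus$removed, ]
  labs <- node_table$reference_label[match(cons$node_id, node_table$node_id)]
  if (!any(labs == dmn_label, na.rm = TRUE)) {
    abort(sprintf("No node carries the reference label \"%s\".", dmn_label))
  }
  is_dmn <- !is.na(labs) & labs == dmn_label
  per_comm <- tibble::tibble(community = cons$community, is_dmn = is_dmn) |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(n_dmn = sum(.data$is_dmn), size = dplyr::n(),
                     .groups = "drop")
  if (mode == "largest") {
    per_comm <- per_comm[order(-per_comm$n_dmn, -per_comm$size,
                               per_comm$community), ]
    chosen <- per_comm$community[1]
    cons$node_id[cons$community == chosen]
  } else {
    chosen <- per_comm$community[per_comm$n_dmn > per_comm$size / 2]
    if (!length(chosen)) {
      chosen <- per_comm$community[which.max(per_comm$n_dmn)]
    }
    cons$node_id[cons$community %in% chosen]
  }
}

# Assign PM/AT/MPF names to three communities from their centroid
# coordinates: most posterior mean y -> PM, then most inferior mean z -> AT,
# the remaining (anterior-medial) -> MPF. Cosmetic names; membership is the
# tested object.
label_subnetworks <- function(communities, node_table) {
  k <- length(unique(communities$community))
  if (k != 3) {
    return(dplyr::mutate(communities,
                         subnetwork = paste0("C", .data$community)))
  }
  cents <- communities |>
    dplyr::left_join(node_table, by = "node_id") |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(my = mean(.data$y), mz = mean(.data$z), .groups = "drop")
  name <- rep(NA_character_, nrow(cents))
  pm <- which.min(cents$my)
  name[pm] <- "PM"
  rest <- setdiff(seq_len(3), pm)
  at <- rest[which.min(cents$mz[rest])]
  name[at] <- "AT"
  name[setdiff(rest, at)] <- "MPF"
  map <- stats::setNames(name, cents$community)
  dplyr::mutate(communities,
                subnetwork = unname(map[as.character(.data$community)]))
}

#' Subcluster the DMN into its subnetworks
#'
#' Restricts every subject's connectivity matrix to the DMN node set,
#' group-averages, and runs consensus community detection at `gamma`
#' (default 1.00). When exactly three communities emerge they are named
#' PM / AT / MPF by a centroid-coordinate heuristic (most posterior mean
#' y = PM, most inferior remaining = AT, remainder = MPF); any other
#' community count is reported with generic names, never forced to three.
#'
#' @param matrices List of per-subject full connectivity matrices.
#' @param dmn_ids Character vector of DMN node ids.
#' @param node_table Node table with `node_id`, `x`, `y`, `z`.
#' @param gamma Resolution for the DMN-level clustering (default 1.00).
#' @param iterations,stability_threshold,seed,restarts Passed to
#'   [consensus_partition()].
#' @param average_mode Group-averaging mode, `"r"` or `"z"`.
#' @return Object of class `dmn_partition`: list with `membership` (tibble
#'   `node_id`, `community`, `subnetwork`, `stability`, `removed`),
#'   `n_communities`, `ensemble`, `matrix` (the averaged DMN matrix).
#' @export
subcluster_dmn <- function(matrices, dmn_ids, node_table, gamma = 1.00,
                           iterations = 1000, stability_threshold = 0.40,
                           seed = 1, restarts = 20, average_mode = "r") {
  if (length(dmn_ids) < 3) abort("Need at least 3 DMN nodes to subcluster.")
  sub <- lapply(matrices, function(m) m[dmn_ids, dmn_ids, drop = FALSE])
  avg <- group_average(sub, mode = average_mode)
  ens <- consensus_partition(avg, gamma = gamma, iterations = iterations,
                             stability_threshold = stability_threshold,
                             seed = seed, restarts = restarts)
  kept <- ens$consensus[!ens$consensus$removed,
                        c("node_id", "community", "stability")]
  membership <- label_subnetworks(kept, node_table)
  membership <- dplyr::bind_rows(
    membership,
    dplyr::mutate(
      ens$consensus[ens$consensus$removed,
                    c("node_id", "community", "stability")],
      subnetwork = NA_character_
    )
  )
  membership$removed <- membership$node_id %in%
    ens$consensus$node_id[ens$consensus$removed]
  structure(list(
    membership = membership,
    n_communities = length(unique(kept$community)),
    ensemble = ens,
    matrix = avg
  ), class = "dmn_partition")
}

#' @export
print.dmn_partition <- function(x, ...) {
  cat(sprintf("DMN partition: %d nodes, %d communit%s\n",
              nrow(x$membership), x$n_communities,
              if (x$n_communities == 1) "y" else "ies"))
  print(table(x$membership$subnetwork, useNA = "ifany"))
  invisible(x)
}
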