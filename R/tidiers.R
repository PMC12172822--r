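#' Tidy a bootstrap VIP result
#'
#' @param x A [bootstrap_vip()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `vip`, `selected`.
#' @export
tidy.vip_result <- function(x, ...) {
  tibble::tibble(
    term = names(x$vip),
    vip = unname(x$vip),
    selected = names(x$vip) %in% x$selected
  ) |>
    dplyr::arrange(dplyr::desc(.data$vip))
}

#' One-row summary of a bootstrap VIP result
#' @inheritParams tidy.vip_result
#' @return Tibble with `alpha`, `B`, `threshold`, `n_selected`,
#'   `n_redraws`.
#' @export
glance.vip_result <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, B = x$B, threshold = x$threshold,
                 n_selected = length(x$selected), n_redraws = x$n_redraws)
}

#' Tidy an OLS refit
#'
#' @param x An [ols_refit()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (raw coefficient), `beta_std`
#'   (standardized coefficient), `std_error`, `statistic`, `p_value`.
#' @export
tidy.ols_refit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  terms <- rownames(sm)[-1]
  tibble::tibble(
    term = terms,
    estimate = sm[-1, "Estimate"],
    beta_std = unname(x$beta_std[terms]),
    std_error = sm[-1, "Std. Error"],
    statistic = sm[-1, "t value"],
    p_value = sm[-1, "Pr(>|t|)"]
  )
}

#' One-row summary of an OLS refit
#' @inheritParams tidy.ols_refit
#' @return Tibble with `r_squared`, `adj_r_squared`, `n`, `p`.
#' @export
glance.ols_refit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 n = x$n, p = x$p)
}

#' Tidy a consensus partition ensemble
#'
#' @param x A [consensus_partition()] result.
#' @param ... Unused.
#' @return The consensus tibble (`node_id`, `community`, `stability`,
#'   `removed`).
#' @export
tidy.partition_ensemble <- function(x, ...) x$consensus

#' One-row summary of a consensus partition ensemble
#' @inheritParams tidy.partition_ensemble
#' @return Tibble with `gamma`, `iterations`, `n_communities`,
#'   `n_removed`, `q_max`, `q_mean`.
#' @export
glance.partition_ensemble <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, iterations = length(x$q_values),
    n_communities = length(unique(x$consensus$community)),
    n_removed = sum(x$consensus$removed),
    q_max = max(x$q_values), q_mean = mean(x$q_values)
  )
}
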