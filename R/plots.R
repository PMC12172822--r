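#' VIP bar plot with the selection threshold
#'
#' Bar chart of per-predictor variable inclusion probabilities with a
#' horizontal line at the selection threshold.
#'
#' @param object A [bootstrap_vip()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vip_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$term, -.data$vip),
    y = .data$vip, fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey65"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "Variable inclusion probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Node-stability plot for a consensus partition
#'
#' @param object A [consensus_partition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partition_ensemble <- function(object, ...) {
  d <- object$consensus
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$node_id, .data$stability),
    y = .data$stability,
    colour = factor(.data$community), shape = .data$removed
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$stability_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "node", y = "stability",
                  colour = "community", shape = "removed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Framewise-displacement trace plot
#'
#' FD over frames with the scrub threshold and flagged frames highlighted.
#'
#' @param fd Tibble from [compute_fd()].
#' @param threshold_mm Scrub threshold (default 0.5 mm).
#' @return A ggplot object.
#' @export
plot_fd <- function(fd, threshold_mm = 0.5) {
  d <- flag_outliers(fd, threshold_mm)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frame, y = .data$fd)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = d[d$outlier, ], colour = "#b2182b") +
    ggplot2::geom_hline(yintercept = threshold_mm, linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "framewise displacement (mm)") +
    ggplot2::theme_minimal()
}
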