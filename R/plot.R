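#' Scalp plot of an ERD-ratio topography
#'
#' Schematic top-view scalp map of the per-channel ERD ratio, one facet per
#' band. Ratios below 1 (blue) mark channels showing event-related
#' desynchronization.
#'
#' @param object An [erd_ratio_map()].
#' @param label_channels Label every electrode (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.erd_ratio_map <- function(object, label_channels = TRUE, ...) {
  long <- tidy.erd_ratio_map(object)
  pos <- montage_positions(object$channel)
  df <- dplyr::left_join(long, pos, by = "channel")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$ratio),
                        shape = 21, size = 6, colour = "grey30") +
    ggplot2::scale_fill_gradient2(
      midpoint = 1, low = "#2166ac", mid = "white", high = "#b2182b",
      name = "ERD ratio"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$band)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
  if (label_channels) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$channel),
                                size = 1.8)
  }
  p
}

#' Strategy accuracy comparison plot
#'
#' Per-subject accuracies of the three channel-selection strategies with
#' subject trajectories, the visual counterpart of the repeated-measures
#' comparison.
#'
#' @param table An [as_accuracy_table()] (e.g. [published_accuracies()]).
#' @return A ggplot object.
#' @export
plot_strategy_accuracy <- function(table) {
  table <- as_accuracy_table(table)
  long <- tidyr::pivot_longer(
    as_tibble(table)[c("subject", "group", strategy_cols)],
    dplyr::all_of(strategy_cols),
    names_to = "strategy", values_to = "accuracy"
  )
  long$strategy <- factor(long$strategy, levels = strategy_cols,
                          labels = c("SM1-4", "SM1-5", "ERD"))
  ggplot2::ggplot(long, ggplot2::aes(.data$strategy, .data$accuracy)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject),
                       colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4) +
    ggplot2::labs(x = "channel-selection strategy", y = "accuracy (%)",
                  colour = "topography group") +
    ggplot2::theme_minimal()
}
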