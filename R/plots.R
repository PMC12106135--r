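# ggplot2 figures for the result tables.

#' Bar chart of size-binned agreement
#'
#' Mirrors the standard inter-observer figure: one bar per lesion-size bin
#' and metric, with standard-deviation error bars.
#'
#' @param binned Output of [size_binned_agreement()].
#' @param metrics Metrics to display.
#' @return A ggplot object.
#' @export
plot_agreement <- function(binned, metrics = c("dice", "iou", "sensitivity")) {
  d <- dplyr::filter(binned, .data$metric %in% metrics)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mean,
                                  fill = .data$bin)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "lesion size (positive pixels)", y = "mean ± sd") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Training loss curve
#'
#' @param log Per-epoch loss tibble from [train()].
#' @return A ggplot object.
#' @export
plot_training <- function(log) {
  ggplot2::ggplot(log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
}

#' Per-unit metric distributions
#'
#' @param per_unit Tibble from [metrics_report()].
#' @param metrics Metric columns to display.
#' @return A ggplot object.
#' @export
plot_metrics <- function(per_unit,
                         metrics = c("dice", "iou", "sensitivity", "vs")) {
  long <- tidyr::pivot_longer(
    dplyr::select(per_unit, dplyr::any_of(metrics)),
    dplyr::everything(), names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.friedman_test <- function(object, ...) {
  d <- tidy.friedman_test(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$model,
                                                     .data$mean_rank),
                                  y = .data$mean_rank)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean rank (lower is better)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nemenyi_posthoc <- function(object, ...) {
  d <- tidy.nemenyi_posthoc(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model1, y = .data$model2,
                                  fill = .data$significant)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rank_diff)),
                       size = 3) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Nemenyi pairwise rank differences (CD = %.2f)",
                                  object$critical_difference)) +
    ggplot2::theme_minimal()
}
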