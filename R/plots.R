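# ggplot2 visualisations of the result types.

#' Plot a Grad-CAM heatmap
#'
#' Line plus colour-strip view of per-position importance; the central
#' dinucleotide is marked with a dashed line.
#'
#' @param object A `splice_heatmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.splice_heatmap <- function(object, ...) {
  df <- tidy(object)
  W <- nrow(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$score), size = 0.8) +
    ggplot2::scale_colour_viridis_c(option = "viridis", limits = c(0, 1)) +
    ggplot2::geom_vline(xintercept = W / 2 + 0.5, linetype = "dashed",
                        colour = "red3") +
    ggplot2::labs(x = "window position (nt)", y = "importance",
                  colour = "score",
                  title = sprintf("Grad-CAM, class %d (n = %d)",
                                  object$target_class, object$n_averaged)) +
    ggplot2::theme_minimal()
}

#' Plot training curves
#' @param object A trained `splice_cnn`.
#' @param ... Unused.
#' @return A ggplot faceted by metric (loss / accuracy).
#' @export
autoplot.splice_cnn <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the five metrics of a report
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot bar chart (percent scale).
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       vjust = -0.4, size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 105)) +
    ggplot2::labs(x = NULL, y = "percent", title = object$dataset_name) +
    ggplot2::theme_minimal()
}

#' Plot an identity distribution
#' @param object An `identity_distribution`.
#' @param ... Unused.
#' @return A ggplot bar chart over the ten identity bins.
#' @export
autoplot.identity_distribution <- function(object, ...) {
  df <- tidy(object)
  df$bin <- sprintf("%d-%d", df$lower, df$upper)
  df$bin <- factor(df$bin, levels = df$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange3") +
    ggplot2::labs(x = "mean pairwise identity (%)", y = "sequences (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
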