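# broom-style tidiers for fitted objects and reports.

#' Tidy a metrics report into a metric/value tibble
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble with columns `metric` and `value` (percentages).
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(metric = names(x$metrics), value = unlist(x$metrics, use.names = FALSE))
}

#' One-row summary of a metrics report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(dataset = x$dataset_name, site_type = x$site_type,
         accuracy = x$metrics$accuracy, precision = x$metrics$precision,
         sensitivity = x$metrics$sensitivity,
         specificity = x$metrics$specificity, f1 = x$metrics$f1)
}

#' Per-epoch training history of a model
#' @param x A trained `splice_cnn`.
#' @param ... Unused.
#' @return Long tibble with `epoch`, `metric`, `set`, `value`.
#' @export
tidy.splice_cnn <- function(x, ...) {
  if (is.null(x$history)) abort("model has no training history")
  x$history |>
    tidyr::pivot_longer(-"epoch", names_to = "key", values_to = "value") |>
    mutate(set = ifelse(startsWith(.data$key, "val_"), "validation", "train"),
           metric = sub("^val_", "", .data$key)) |>
    select("epoch", "metric", "set", "value")
}

#' One-row model summary
#' @param x A `splice_cnn`.
#' @param ... Unused.
#' @export
glance.splice_cnn <- function(x, ...) {
  last <- if (is.null(x$history)) NULL else x$history[nrow(x$history), ]
  tibble(site_type = x$site_type, input_length = x$config$input_length,
         n_params = x$n_params, trained = x$trained,
         epochs = if (is.null(last)) NA_integer_ else last$epoch,
         final_loss = if (is.null(last)) NA_real_ else last$loss,
         final_val_accuracy = if (is.null(last)) NA_real_ else last$val_accuracy)
}

#' Tidy a heatmap into a position/score tibble
#' @param x A `splice_heatmap`.
#' @param ... Unused.
#' @export
tidy.splice_heatmap <- function(x, ...) {
  tibble(position = seq_along(x$scores), score = x$scores,
         target_class = x$target_class)
}

#' Tidy an identity distribution into its bins
#' @param x An `identity_distribution`.
#' @param ... Unused.
#' @export
tidy.identity_distribution <- function(x, ...) {
  x$bins
}
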