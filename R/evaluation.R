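# Evaluation: confusion counts, the five performance metrics (as
# percentages), benchmark evaluation and unweighted aggregation across
# benchmarks.

#' Tally a 2x2 confusion table
#'
#' Class 1 is "splice site". True positives are sites predicted as sites,
#' true negatives are non-sites predicted as non-sites.
#'
#' @param predicted,truth Equal-length integer vectors of 0/1 labels.
#' @return An object of class `confusion_counts`: list with `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) abort("label vectors must have equal length")
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    abort("labels must be 0 or 1")
  structure(list(TP = sum(predicted == 1 & truth == 1),
                 FP = sum(predicted == 1 & truth == 0),
                 TN = sum(predicted == 0 & truth == 0),
                 FN = sum(predicted == 0 & truth == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 * p * s / (p + s)`, on the percentage scale.
#'
#' @param precision,sensitivity Percentages.
#' @return F1 as a percentage.
#' @export
f1_score <- function(precision, sensitivity) {
  2 * precision * sensitivity / (precision + sensitivity)
}

#' Compute the five performance metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and the F1 score, all reported as
#' percentages and stored unrounded. Ratios with a zero denominator are
#' reported as `NaN` with a warning rather than silently as zero, so they can
#' be excluded from averages deliberately.
#'
#' @param counts A [confusion_counts()] object (or list with TP/FP/TN/FN).
#' @param dataset_name,site_type Optional metadata recorded in the report.
#' @return An object of class `metrics_report`.
#' @export
compute_metrics <- function(counts, dataset_name = NA_character_,
                            site_type = NA_character_) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n < 1) abort("at least one evaluated example is required")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s is undefined (zero denominator); reported as NaN", what))
      return(NaN)
    }
    100 * num / den
  }
  acc <- 100 * (counts$TP + counts$TN) / n
  prec <- ratio(counts$TP, counts$TP + counts$FP, "precision")
  sens <- ratio(counts$TP, counts$TP + counts$FN, "sensitivity")
  spec <- ratio(counts$TN, counts$TN + counts$FP, "specificity")
  f1 <- f1_score(prec, sens)
  metrics_report(accuracy = acc, precision = prec, sensitivity = sens,
                 specificity = spec, f1 = f1, counts = counts,
                 dataset_name = dataset_name, site_type = site_type)
}

#' Construct a metrics report directly
#'
#' Useful for entering published per-benchmark metric tables so they can be
#' aggregated with [aggregate_reports()].
#'
#' @param accuracy,precision,sensitivity,specificity,f1 Percentages.
#' @param counts Optional [confusion_counts()].
#' @param dataset_name,site_type Optional metadata.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(accuracy = NaN, precision = NaN, sensitivity = NaN,
                           specificity = NaN, f1 = NaN, counts = NULL,
                           dataset_name = NA_character_,
                           site_type = NA_character_) {
  structure(list(metrics = list(accuracy = accuracy, precision = precision,
                                sensitivity = sensitivity,
                                specificity = specificity, f1 = f1),
                 counts = counts, dataset_name = dataset_name,
                 site_type = site_type),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report%s%s>\n",
              if (is.na(x$dataset_name)) "" else paste0(" ", x$dataset_name),
              if (is.na(x$site_type)) "" else paste0(" (", x$site_type, ")")))
  m <- x$metrics
  cat(sprintf("  accuracy %.2f%%  precision %.2f%%  sensitivity %.2f%%  specificity %.2f%%  F1 %.2f%%\n",
              m$accuracy, m$precision, m$sensitivity, m$specificity, m$f1))
  invisible(x)
}

#' Evaluate a model on a labelled benchmark
#'
#' Runs predict -> classify -> confusion counts -> metrics on a set of
#' labelled windows.
#'
#' @param model A trained `splice_cnn`.
#' @param benchmark A tibble with `window` and `label` columns (e.g. from
#'   [read_benchmark_fasta()] or [split_train_test()]).
#' @param threshold Classification threshold.
#' @param adapt Adapt benchmark window lengths to the model input length.
#' @param dataset_name Name recorded in the report.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, benchmark, threshold = 0.5, adapt = TRUE,
                           dataset_name = NA_character_) {
  if (nrow(benchmark) == 0) abort("benchmark is empty")
  probs <- predict_proba(model, benchmark, adapt = adapt)
  pred <- classify(probs, threshold)
  compute_metrics(confusion_counts(pred, benchmark$label),
                  dataset_name = dataset_name, site_type = model$site_type)
}

#' Average metric reports across benchmarks
#'
#' Unweighted arithmetic mean of each metric across the supplied reports
#' (the convention used for multi-benchmark summary rows). Reports must share
#' a site type. By default the stored unrounded values are averaged; set
#' `rounded = TRUE` to average values rounded to 2 decimals first, matching
#' published tables whose averages were taken over displayed values.
#'
#' @param reports A list of `metrics_report` objects.
#' @param rounded Average 2-decimal-rounded values instead of raw ones.
#' @return A `metrics_report` holding the averages.
#' @export
aggregate_reports <- function(reports, rounded = FALSE) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  if (length(reports) < 1) abort("at least one report is required")
  sites <- unique(vapply(reports, function(r) r$site_type, character(1)))
  if (length(sites) > 1) abort("cannot aggregate reports with mixed site types")
  vals <- sapply(reports, function(r) unlist(r$metrics))
  if (rounded) vals <- round(vals, 2)
  means <- rowMeans(vals)
  metrics_report(accuracy = means[["accuracy"]], precision = means[["precision"]],
                 sensitivity = means[["sensitivity"]],
                 specificity = means[["specificity"]], f1 = means[["f1"]],
                 dataset_name = "average", site_type = sites)
}

#' Write metric reports to TSV (one row per benchmark plus an average row)
#'
#' @param reports A list of `metrics_report` objects (same site type).
#' @param path Output TSV file.
#' @param json_path Optional JSON sidecar with the same content.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(reports, path, json_path = NULL) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  rows <- purrr::map_dfr(c(reports, list(aggregate_reports(reports))), glance)
  rows <- mutate(rows, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(rows, json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
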