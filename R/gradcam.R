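# Grad-CAM interpretability: per-position importance of an input window for
# a chosen class, read off the last convolutional block.

normalize_heatmap <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= .Machine$double.eps) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# raw conv-resolution maps (one row per window) -> W-length normalized maps
upsample_maps <- function(maps, W) {
  Lc <- ncol(maps)
  xin <- seq(1, W, length.out = Lc)
  t(apply(maps, 1, function(m) approx(xin, m, xout = seq_len(W))$y))
}

new_heatmap <- function(scores, target_class, site_type, n_averaged) {
  structure(list(scores = scores, target_class = as.integer(target_class),
                 site_type = site_type, n_averaged = as.integer(n_averaged)),
            class = "splice_heatmap")
}

#' @export
print.splice_heatmap <- function(x, ...) {
  cat(sprintf("<splice_heatmap> class %d%s, %d position(s), averaged over %d window(s); peak at %d\n",
              x$target_class,
              if (is.na(x$site_type)) "" else paste0(" (", x$site_type, ")"),
              length(x$scores), x$n_averaged, which.max(x$scores)))
  invisible(x)
}

check_gradcam_layer <- function(model, layer) {
  if (!is_scalar_int(layer) || layer < 1 || layer > length(model$kernels))
    abort(sprintf("`layer` must be a convolution block index in 1..%d",
                  length(model$kernels)))
  as.integer(layer)
}

#' Grad-CAM heatmap for a single window
#'
#' Computes the gradient of the pre-softmax score of `target_class` with
#' respect to the post-ReLU activation map of a chosen convolutional layer,
#' spatially averages the gradient per channel to obtain channel weights,
#' forms the weighted channel sum, clips negative values to zero, linearly
#' interpolates from the convolutional resolution back to the window length
#' and min-max normalises to `[0, 1]`. A flat map (all activations
#' identical) degenerates to all zeros.
#'
#' The default layer is the first convolution block: its 7-nt receptive
#' field and unit stride give nucleotide-scale localisation of the planted
#' motifs. Deeper blocks (`layer = 2` or `3`) give more abstract but
#' spatially blurrier maps, since each position there summarises a 40-nt
#' receptive field reached through max-pooling, so peaks can land tens of
#' nucleotides away from the feature that caused them.
#'
#' @param model A trained `splice_cnn`.
#' @param window A single window string of the model's input length.
#' @param target_class 0 (non-SS) or 1 (SS).
#' @param layer Convolution block whose activations are interrogated
#'   (1-based; default 1).
#' @return An object of class `splice_heatmap` with `scores` (length W,
#'   values in `[0, 1]`), `target_class`, `site_type`, `n_averaged`.
#' @export
gradcam_heatmap <- function(model, window, target_class = 1L, layer = 1L) {
  stopifnot(inherits(model, "splice_cnn"))
  if (!isTRUE(model$trained)) abort("Grad-CAM requires a trained model")
  if (!target_class %in% c(0, 1)) abort("`target_class` must be 0 or 1")
  layer <- check_gradcam_layer(model, layer)
  batch <- as_encoded_batch(window)
  if (batch$width != model$config$input_length)
    abort("window length does not match model input length")
  maps <- cnn_gradcam_cpp(model$weights, batch_cube(batch),
                          as.integer(target_class), layer, 0L)
  up <- upsample_maps(maps, model$config$input_length)
  new_heatmap(normalize_heatmap(up[1, ]), target_class, model$site_type, 1L)
}

#' Class-averaged Grad-CAM heatmap
#'
#' Samples up to `n` windows of the requested class without replacement,
#' computes each window's min-max-normalised Grad-CAM map and averages them
#' position-wise. The mean of per-window `[0, 1]` maps is reported as is
#' (its values lie in `[0, 1]` but its extremes need not be 0 and 1):
#' re-stretching the mean would amplify residual ripple in a flat map to
#' full scale and destroy the contrast between peaked (splice-site) and
#' flat (non-site) class maps that these averages are meant to expose. Set
#' `renormalize = TRUE` to force the `[0, 1]` stretch.
#'
#' @param model A trained `splice_cnn`.
#' @param examples A tibble with `window` and `label` columns.
#' @param target_class The class whose examples are averaged (0 or 1).
#' @param n Maximum number of windows to average (default 10,000).
#' @param seed Seed for the subsample.
#' @param layer Convolution block to interrogate (see [gradcam_heatmap()]).
#' @param renormalize Min-max stretch the averaged map to `[0, 1]`.
#' @return A `splice_heatmap` with `n_averaged` set to the number actually
#'   used.
#' @export
average_heatmaps <- function(model, examples, target_class = 1L, n = 10000L,
                             seed = 1L, layer = 1L, renormalize = FALSE) {
  stopifnot(inherits(model, "splice_cnn"))
  if (!isTRUE(model$trained)) abort("Grad-CAM requires a trained model")
  layer <- check_gradcam_layer(model, layer)
  pool <- filter(examples, .data$label == target_class)
  if (nrow(pool) == 0) abort("no examples of the requested class")
  k <- min(n, nrow(pool))
  pool <- withr::with_seed(seed, pool[sample.int(nrow(pool), k), , drop = FALSE])
  batch <- as_encoded_batch(pool)
  if (batch$width != model$config$input_length)
    abort("window length does not match model input length")
  maps <- cnn_gradcam_cpp(model$weights, batch_cube(batch),
                          as.integer(target_class), layer, 0L)
  up <- upsample_maps(maps, model$config$input_length)
  norm <- t(apply(up, 1, normalize_heatmap))
  avg <- colMeans(norm)
  if (renormalize) avg <- normalize_heatmap(avg)
  new_heatmap(avg, target_class, model$site_type, k)
}
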