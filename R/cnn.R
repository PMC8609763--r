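# The convolutional classifier: configuration, construction, training,
# prediction. One independent model is trained per splice-site type.

#' Architecture hyperparameters of the splice-site CNN
#'
#' The default stack is three unpadded 1-D convolution blocks of 16, 32 and
#' 64 filters with kernel sizes 7, 6 and 6 (stride 1), each followed by
#' dropout (rate 0.2) and max-pooling of size 2 with stride 2, then a flatten
#' stage, a 100-unit ReLU dense layer and a 2-class softmax output. At the
#' default input length of 200 nt the spatial trace is
#' 200 -> 194 -> 97 -> 92 -> 46 -> 41 -> 20 and the model has 144,222
#' trainable parameters.
#'
#' @param input_length Window length W in nt (even).
#' @param conv_filters Integer vector of filters per convolution block.
#' @param conv_kernel_sizes Kernel sizes, same length as `conv_filters`.
#' @param conv_stride Convolution stride (only 1 is supported).
#' @param pool_size,pool_stride Max-pooling geometry (only 2/2 supported).
#' @param dropout_rate Dropout rate in `[0, 1)` applied after each
#'   convolution.
#' @param dense_units Width of the fully connected hidden layer.
#' @param n_classes Number of output classes.
#' @param seed Seed for weight initialisation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_length = 200L,
                         conv_filters = c(16L, 32L, 64L),
                         conv_kernel_sizes = c(7L, 6L, 6L),
                         conv_stride = 1L,
                         pool_size = 2L, pool_stride = 2L,
                         dropout_rate = 0.2,
                         dense_units = 100L,
                         n_classes = 2L,
                         seed = 1L) {
  if (length(conv_filters) != length(conv_kernel_sizes))
    abort("`conv_filters` and `conv_kernel_sizes` must have the same length")
  if (conv_stride != 1L || pool_size != 2L || pool_stride != 2L)
    abort("only conv_stride = 1 and 2/2 pooling are supported")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    abort("`dropout_rate` must be in [0, 1)")
  if (!is_scalar_int(input_length) || input_length < 4)
    abort("`input_length` must be an integer >= 4")
  structure(list(input_length = as.integer(input_length),
                 conv_filters = as.integer(conv_filters),
                 conv_kernel_sizes = as.integer(conv_kernel_sizes),
                 conv_stride = 1L, pool_size = 2L, pool_stride = 2L,
                 dropout_rate = as.double(dropout_rate),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "model_config")
}

# spatial sizes through the stack; NULL when any stage collapses below 1
shape_trace <- function(input_length, kernels) {
  L <- input_length
  trace <- integer(0)
  for (k in kernels) {
    L <- L - k + 1
    if (L < 1) return(NULL)
    trace <- c(trace, L)
    L <- L %/% 2
    if (L < 1) return(NULL)
    trace <- c(trace, L)
  }
  trace
}

count_params <- function(weights) {
  sum(vapply(weights$conv_W, length, double(1))) +
    sum(vapply(weights$conv_b, length, double(1))) +
    length(weights$W1) + length(weights$b1) +
    length(weights$W2) + length(weights$b2)
}

#' Build an (untrained) splice-site CNN
#'
#' Instantiates seeded initial weights for the stack described by `config`.
#' When the input length is too short for the full stack (e.g. 20-nt
#' windows), the last convolution block is dropped with a warning and a
#' reduced stack is built; if even that does not fit, a dimension error is
#' raised.
#'
#' @param config A [model_config()].
#' @param site_type `"donor"`, `"acceptor"` or `NA`.
#' @return An object of class `splice_cnn` with elements `config`,
#'   `site_type`, `weights`, `history` (`NULL` until trained), `trained`,
#'   `n_params` and `reduced`.
#' @export
build_model <- function(config = model_config(), site_type = NA_character_) {
  filters <- config$conv_filters
  kernels <- config$conv_kernel_sizes
  reduced <- FALSE
  if (is.null(shape_trace(config$input_length, kernels))) {
    if (length(kernels) > 1) {
      filters <- filters[-length(filters)]
      kernels <- kernels[-length(kernels)]
      reduced <- TRUE
    }
    if (is.null(shape_trace(config$input_length, kernels)))
      abort(sprintf("input length %d is too short for the convolution stack",
                    config$input_length))
    warn(sprintf(
      "input length %d cannot traverse the full stack; dropping the last convolution block",
      config$input_length))
  }
  weights <- cnn_init_cpp(config$input_length, filters, kernels, 4L,
                          config$dense_units, config$n_classes, config$seed)
  structure(list(config = config, site_type = site_type, weights = weights,
                 history = NULL, trained = FALSE,
                 n_params = count_params(weights), reduced = reduced,
                 filters = filters, kernels = kernels),
            class = "splice_cnn")
}

#' @export
print.splice_cnn <- function(x, ...) {
  cat(sprintf("<splice_cnn%s> W=%d, conv %s (kernels %s), dense %d, %s, %d parameters\n",
              if (is.na(x$site_type)) "" else paste0(" ", x$site_type),
              x$config$input_length,
              paste(x$filters, collapse = "/"),
              paste(x$kernels, collapse = "/"),
              x$config$dense_units,
              if (x$trained) "trained" else "untrained",
              x$n_params))
  invisible(x)
}

#' Training hyperparameters
#'
#' Defaults follow the reference protocol: cross-entropy loss on the 2-class
#' softmax, the Adamax optimiser at learning rate 1e-5, 400 epochs with
#' batches of 32, and a stratified 15\% validation split carved out of the
#' training data to monitor learning.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adamax step size.
#' @param validation_fraction Fraction of the training data held out for
#'   per-epoch validation, in (0, 1).
#' @param seed Seed for the validation split, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 400L, batch_size = 32L, learning_rate = 1e-5,
                         validation_fraction = 0.15, seed = 1L) {
  if (!is_scalar_int(epochs) || epochs < 1) abort("`epochs` must be a positive integer")
  if (!is.numeric(validation_fraction) || validation_fraction <= 0 ||
      validation_fraction >= 1)
    abort("`validation_fraction` must be in (0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = as.double(learning_rate),
                 validation_fraction = as.double(validation_fraction),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a splice-site CNN
#'
#' Splits off a stratified validation set, then optimises the cross-entropy
#' loss with Adamax over shuffled mini-batches. Per-epoch training and
#' validation loss/accuracy are recorded in the model's `history`. With fixed
#' seeds the result is fully deterministic.
#'
#' @param model A [build_model()] object.
#' @param data An `encoded_batch`, or a tibble with `window` and `label`
#'   columns (encoded internally).
#' @param config A [train_config()].
#' @return The trained `splice_cnn`.
#' @export
train_cnn <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "splice_cnn"), inherits(config, "train_config"))
  batch <- as_encoded_batch(data)
  if (batch$width != model$config$input_length)
    abort(sprintf("window length %d does not match model input length %d",
                  batch$width, model$config$input_length))
  if (length(unique(batch$labels)) < 2)
    abort("training data must contain both classes")
  cube <- batch_cube(batch)
  y <- batch$labels
  val_idx <- withr::with_seed(config$seed, {
    unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, max(1L, floor(config$validation_fraction * length(idx))))
    }), use.names = FALSE)
  })
  tr_idx <- setdiff(seq_along(y), val_idx)
  fit <- cnn_train_cpp(model$weights,
                       cube[, , tr_idx, drop = FALSE], y[tr_idx],
                       cube[, , val_idx, drop = FALSE], y[val_idx],
                       config$epochs, config$batch_size, config$learning_rate,
                       model$config$dropout_rate, config$seed)
  model$weights <- fit$weights
  model$history <- tibble(epoch = seq_len(config$epochs),
                          loss = fit$history[, 1],
                          accuracy = fit$history[, 2],
                          val_loss = fit$history[, 3],
                          val_accuracy = fit$history[, 4])
  model$trained <- TRUE
  model$train_config <- config
  model
}

#' Predict class probabilities
#'
#' Dropout is disabled at inference, so repeated prediction on the same
#' input is bit-stable. Each returned row sums to 1.
#'
#' @param model A trained (or untrained) `splice_cnn`.
#' @param newdata Character vector of windows, tibble with a `window` column,
#'   or an `encoded_batch`.
#' @param adapt If `TRUE`, windows whose length differs from the model input
#'   length are adapted with [adapt_length()] (centre-crop or N-padding);
#'   otherwise a length mismatch is an error.
#' @return A tibble with columns `p_non_ss` and `p_ss`, one row per window
#'   in input order.
#' @export
predict_proba <- function(model, newdata, adapt = FALSE) {
  stopifnot(inherits(model, "splice_cnn"))
  if (!inherits(newdata, "encoded_batch") && adapt) {
    w <- as_windows(newdata)
    newdata <- adapt_length(w, model$config$input_length)
  }
  batch <- as_encoded_batch(newdata)
  if (batch$width != model$config$input_length)
    abort(sprintf("window length %d does not match model input length %d (use adapt = TRUE)",
                  batch$width, model$config$input_length))
  probs <- cnn_predict_cpp(model$weights, batch_cube(batch))
  tibble(p_non_ss = probs[, 1], p_ss = probs[, 2])
}

#' @export
predict.splice_cnn <- function(object, newdata, type = c("prob", "class"),
                               threshold = 0.5, adapt = FALSE, ...) {
  type <- match.arg(type)
  probs <- predict_proba(object, newdata, adapt = adapt)
  if (type == "prob") probs else classify(probs, threshold)
}

#' Turn probabilities into 0/1 labels
#'
#' A window is called a splice site when `P(SS)` strictly exceeds the
#' threshold; a tie at the threshold is conservatively called non-SS.
#'
#' @param probabilities A tibble/matrix of probability rows (second column =
#'   `P(SS)`), or a numeric vector of `P(SS)`.
#' @param threshold Decision threshold.
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  p_ss <- if (is.data.frame(probabilities)) probabilities$p_ss
          else if (is.matrix(probabilities)) probabilities[, 2]
          else probabilities
  as.integer(p_ss > threshold)
}

#' Adapt window length to a model's input length
#'
#' Longer windows are symmetrically centre-cropped (preserving the central
#' dinucleotide at `L/2`, `L/2 + 1`); shorter windows are padded with `N` on
#' both sides, which one-hot encodes to all-zero channels.
#'
#' @param windows Character vector of windows (all the same, even, length).
#' @param length Target even length.
#' @return Character vector of adapted windows.
#' @export
adapt_length <- function(windows, length) {
  L <- unique(nchar(windows))
  if (base::length(L) != 1) abort("all windows must have the same length")
  if (L %% 2 != 0 || length %% 2 != 0) abort("window lengths must be even")
  if (length == L) return(windows)
  if (length < L) return(trim_window_chr(windows, length))
  pad <- strrep("N", (length - L) / 2)
  paste0(pad, windows, pad)
}
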