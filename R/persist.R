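# Model persistence: a saved-model directory holding config.json, a
# full-precision weights.json and training_history.tsv. Loading reconstructs
# bit-identical predictions.

#' Save a model to a directory
#'
#' Writes `config.json` (architecture, site type, parameter count),
#' `weights.json` (all weight matrices at full numeric precision) and, when
#' the model has been trained, `training_history.tsv`.
#'
#' @param model A `splice_cnn`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "splice_cnn"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(config = unclass(model$config), site_type = model$site_type,
               trained = model$trained, n_params = model$n_params,
               reduced = model$reduced, filters = model$filters,
               kernels = model$kernels,
               train_config = if (!is.null(model$train_config)) unclass(model$train_config))
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  w <- model$weights
  ser <- list(conv_W = lapply(w$conv_W, function(m) list(dim = dim(m), x = as.vector(m))),
              conv_b = lapply(w$conv_b, as.vector),
              W1 = list(dim = dim(w$W1), x = as.vector(w$W1)),
              b1 = as.vector(w$b1),
              W2 = list(dim = dim(w$W2), x = as.vector(w$W2)),
              b2 = as.vector(w$b2),
              kernels = w$kernels)
  # I(17) = 17 significant digits, enough for an exact double round trip
  jsonlite::write_json(ser, file.path(dir, "weights.json"), digits = I(17))
  if (!is.null(model$history))
    write.table(model$history, file.path(dir, "training_history.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a model saved with [save_model()]
#' @param dir The saved-model directory.
#' @return A `splice_cnn`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  ser <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  remat <- function(s) matrix(s$x, nrow = s$dim[1], ncol = s$dim[2])
  conv_W <- if (is.data.frame(ser$conv_W)) {
    lapply(seq_len(nrow(ser$conv_W)), function(i)
      matrix(ser$conv_W$x[[i]], nrow = ser$conv_W$dim[[i]][1]))
  } else {
    lapply(ser$conv_W, remat)
  }
  conv_b <- lapply(ser$conv_b, function(b) matrix(unlist(b), nrow = 1))
  weights <- list(conv_W = conv_W, conv_b = conv_b,
                  W1 = remat(ser$W1), b1 = matrix(unlist(ser$b1), nrow = 1),
                  W2 = remat(ser$W2), b2 = matrix(unlist(ser$b2), nrow = 1),
                  kernels = as.integer(unlist(ser$kernels)))
  cfg <- meta$config
  config <- model_config(input_length = cfg$input_length,
                         conv_filters = cfg$conv_filters,
                         conv_kernel_sizes = cfg$conv_kernel_sizes,
                         dropout_rate = cfg$dropout_rate,
                         dense_units = cfg$dense_units,
                         n_classes = cfg$n_classes, seed = cfg$seed)
  hist_path <- file.path(dir, "training_history.tsv")
  history <- if (file.exists(hist_path))
    as_tibble(read.table(hist_path, header = TRUE, sep = "\t")) else NULL
  structure(list(config = config,
                 site_type = meta$site_type %||% NA_character_,
                 weights = weights, history = history,
                 trained = isTRUE(meta$trained),
                 n_params = count_params(weights),
                 reduced = isTRUE(meta$reduced),
                 filters = as.integer(unlist(meta$filters)),
                 kernels = as.integer(unlist(meta$kernels))),
            class = "splice_cnn")
}
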