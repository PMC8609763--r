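# One-hot encoding of DNA windows into the S x H x W x C tensor consumed by
# the classifier (H = 1, C = 4 channels in A, C, G, T order; N -> all zeros).

onehot_rows <- rbind(diag(4), 0)
rownames(onehot_rows) <- c("A", "C", "G", "T", "N")
colnames(onehot_rows) <- c("A", "C", "G", "T")

char_indices <- function(window) {
  chars <- strsplit(toupper(window), "")[[1]]
  idx <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort(sprintf("invalid character '%s' at position %d (expected A/C/G/T/N)",
                  chars[bad], bad))
  }
  idx
}

#' One-hot encode a DNA window
#'
#' `A -> (1,0,0,0)`, `C -> (0,1,0,0)`, `G -> (0,0,1,0)`, `T -> (0,0,0,1)`;
#' the undetermined base `N` maps to the all-zero vector. Lower-case input is
#' accepted and upper-cased.
#'
#' @param window A single DNA string over `A/C/G/T/N` (case-insensitive).
#' @return A `W x 4` numeric matrix with columns `A`, `C`, `G`, `T`.
#' @export
encode_one_hot <- function(window) {
  if (!is.character(window) || length(window) != 1)
    abort("`window` must be a single string")
  onehot_rows[char_indices(window), , drop = FALSE]
}

#' Decode a one-hot matrix back to a DNA string
#'
#' The inverse of [encode_one_hot()]; all-zero rows decode to `N`. Rows that
#' are neither valid one-hot nor all-zero (two ones, fractional values) are
#' an error.
#'
#' @param m A `W x 4` numeric matrix.
#' @return A DNA string of length `W`.
#' @export
decode_one_hot <- function(m) {
  if (!is.matrix(m) || ncol(m) != 4) abort("expected a W x 4 matrix")
  if (!all(m %in% c(0, 1))) abort("matrix entries must be 0 or 1")
  rs <- rowSums(m)
  if (any(!rs %in% c(0, 1))) abort("each row must be one-hot or all-zero")
  bases <- c("A", "C", "G", "T")
  out <- rep("N", nrow(m))
  hot <- rs == 1
  out[hot] <- bases[max.col(m[hot, , drop = FALSE])]
  paste(out, collapse = "")
}

# windows -> arma-ready cube array, dim (W, 4, S)
encode_windows_cube <- function(windows) {
  W <- nchar(windows[1])
  S <- length(windows)
  idx <- vapply(windows, char_indices, integer(W), USE.NAMES = FALSE)
  idx <- matrix(idx, nrow = W)                 # columns are windows
  cube <- array(0, c(W, 4L, S))
  for (b in 1:4) {
    sel <- which(idx == b, arr.ind = TRUE)
    if (nrow(sel) > 0)
      cube[cbind(sel[, 1], b, sel[, 2])] <- 1
  }
  cube
}

#' Encode a batch of windows
#'
#' Stacks one-hot encodings of equal-length windows into an array of shape
#' `S x 1 x W x 4` (samples, height, width, channels), preserving order, and
#' carries the 0/1 labels alongside.
#'
#' @param windows Character vector of equal-length windows (non-empty), or a
#'   tibble with `window` (and optionally `label`) columns.
#' @param labels Integer vector of 0/1 labels, same length as `windows`.
#' @return An object of class `encoded_batch`: list with `data` (the
#'   `S x 1 x W x 4` array), `labels` and `width`.
#' @export
encode_batch <- function(windows, labels = NULL) {
  if (is.data.frame(windows)) {
    if (is.null(labels) && "label" %in% names(windows)) labels <- windows$label
    windows <- as_windows(windows)
  }
  if (length(windows) == 0) abort("cannot encode an empty batch")
  if (length(unique(nchar(windows))) != 1) abort("windows must have equal length")
  if (is.null(labels)) labels <- rep(0L, length(windows))
  if (length(labels) != length(windows)) abort("`labels` must match `windows` in length")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  cube <- encode_windows_cube(windows)
  W <- dim(cube)[1]
  S <- dim(cube)[3]
  data <- array(aperm(cube, c(3, 1, 2)), dim = c(S, 1L, W, 4L))
  structure(list(data = data, labels = as.integer(labels), width = W),
            class = "encoded_batch")
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat(sprintf("<encoded_batch> %d windows x 1 x %d x 4 (%d positive)\n",
              dim(x$data)[1], x$width, sum(x$labels)))
  invisible(x)
}

# encoded_batch -> cube (W, 4, S) for the C++ engine
batch_cube <- function(batch) {
  d <- batch$data
  S <- dim(d)[1]; W <- dim(d)[3]
  aperm(array(d, c(S, W, 4L)), c(2, 3, 1))
}

# accept tibble / character / encoded_batch uniformly
as_encoded_batch <- function(x) {
  if (inherits(x, "encoded_batch")) return(x)
  encode_batch(x)
}
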