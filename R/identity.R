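# Dataset QC: pairwise identity statistics and position frequency matrices.

#' Ungapped pairwise percent identity
#'
#' Positional comparison of equal-length sequences:
#' `(#matching positions / length) * 100`. Vectorised over pairs.
#'
#' @param a,b Character vectors of equal-length DNA strings (recycled).
#' @return Numeric vector of percent identities.
#' @export
percent_identity <- function(a, b) {
  if (any(nchar(a) != nchar(b)))
    abort("`a` and `b` must have equal lengths (ungapped comparison)")
  mapply(function(x, y) {
    cx <- strsplit(x, "")[[1]]
    cy <- strsplit(y, "")[[1]]
    100 * sum(cx == cy) / length(cx)
  }, a, b, USE.NAMES = FALSE)
}

#' Distribution of mean pairwise identities
#'
#' For each sequence, computes its mean percent identity against all the
#' others, then bins the per-sequence means into ten 10\%-wide bins
#' (`[0,10), ..., [90,100]`; the upper edge is inclusive only for 100). The
#' pairwise identity matrix is computed with one-hot cross-products, so the
#' cost is linear in sequence length.
#'
#' @param sequences Character vector (>= 2 equal-length sequences) or a
#'   tibble of examples with a `window` column.
#' @return An object of class `identity_distribution`: a list with `bins`
#'   (tibble `lower`, `upper`, `fraction`), `n_sequences` and
#'   `mean_of_means`.
#' @export
identity_distribution <- function(sequences) {
  s <- as_windows(sequences)
  if (length(s) < 2) abort("at least 2 sequences are required")
  L <- unique(nchar(s))
  if (length(L) != 1) abort("sequences must have equal length")
  chars <- matrix(unlist(strsplit(s, "")), nrow = length(s), byrow = TRUE)
  sim <- matrix(0, length(s), length(s))
  for (b in c("A", "C", "G", "T", "N")) {
    ind <- (chars == b) * 1
    sim <- sim + tcrossprod(ind)
  }
  pid <- 100 * sim / L
  means <- (rowSums(pid) - 100) / (length(s) - 1)
  idx <- pmin(floor(means / 10), 9) + 1     # 100% falls in the [90,100] bin
  fractions <- tabulate(idx, nbins = 10) / length(s)
  structure(list(
    bins = tibble(lower = seq(0, 90, 10), upper = seq(10, 100, 10),
                  fraction = fractions),
    n_sequences = length(s),
    mean_of_means = mean(means)
  ), class = "identity_distribution")
}

#' @export
print.identity_distribution <- function(x, ...) {
  cat(sprintf("<identity_distribution> %d sequences, mean of means %.2f%%\n",
              x$n_sequences, x$mean_of_means))
  for (i in seq_len(10)) {
    cat(sprintf("  [%3d-%3d%%) %6.2f%%\n", x$bins$lower[i], x$bins$upper[i],
                100 * x$bins$fraction[i]))
  }
  invisible(x)
}

#' Per-position nucleotide counts
#'
#' Counts A/C/G/T occurrences per window position (the numeric counterpart of
#' a sequence logo). Column sums equal the number of windows when no window
#' contains `N`.
#'
#' @inheritParams identity_distribution
#' @param examples Character vector of equal-length windows or a tibble with
#'   a `window` column; must be non-empty.
#' @return A 4 x L integer matrix with rows `A`, `C`, `G`, `T`.
#' @export
position_frequency_matrix <- function(examples) {
  w <- as_windows(examples)
  if (length(w) == 0) abort("no windows supplied")
  if (length(unique(nchar(w))) != 1) abort("windows must have equal length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(w))
  out <- matrix(0L, 4, nchar(w[1]), dimnames = list(c("A", "C", "G", "T"), NULL))
  common <- intersect(rownames(cm), rownames(out))
  out[common, ] <- cm[common, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}
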