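# Sliding-window scan of a genomic sequence: per-position splice-site
# probabilities, the building block of the `predict` command.

#' Scan a sequence for putative splice sites
#'
#' Slides the model window along the sequence and reports, for every valid
#' centre position, the probability that the central dinucleotide is a splice
#' site of the model's type. Positions whose window would run past the
#' sequence ends are skipped.
#'
#' @param model A trained `splice_cnn`.
#' @param sequence A single DNA string (forward strand; reverse-complement
#'   the input to scan the other strand).
#' @param step Step between consecutive centres, in nt.
#' @param threshold Calls with `p_ss > threshold` are flagged in the `call`
#'   column.
#' @return A tibble with `center` (1-based first base of the central
#'   dinucleotide), `dinucleotide`, `p_ss` and `call`.
#' @export
scan_sequence <- function(model, sequence, step = 1L, threshold = 0.5) {
  stopifnot(inherits(model, "splice_cnn"))
  if (!is.character(sequence) || length(sequence) != 1)
    abort("`sequence` must be a single string")
  W <- model$config$input_length
  flank <- W %/% 2L
  len <- nchar(sequence)
  if (len < W) abort(sprintf("sequence shorter than the model window (%d nt)", W))
  centers <- seq.int(flank, len - flank, by = step)
  windows <- substring(sequence, centers - flank + 1L, centers + flank)
  probs <- predict_proba(model, windows)
  tibble(center = centers,
         dinucleotide = substring(sequence, centers, centers + 1L),
         p_ss = probs$p_ss,
         call = probs$p_ss > threshold)
}
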