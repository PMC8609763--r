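# Internal helpers shared across modules.

# Derive a reproducible 31-bit sub-seed from a master seed and an index.
# Keeps every derived seed in [0, 2^31): R's set.seed() takes 32-bit integers.
derive_seed <- function(seed, index) {
  a <- (as.double(seed) %% 2147483647) * 48271 %% 2147483647
  as.integer((a + as.double(index) * 1000003) %% 2147483647)
}

# i.i.d. background bases at a given GC fraction
sample_bases <- function(n, gc = 0.5) {
  if (n <= 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Sample one base per draw from a per-position consensus model: the consensus
# base with probability `strength`, otherwise uniform over the other three.
sample_consensus <- function(consensus, strength) {
  vapply(consensus, function(b) {
    if (stats::runif(1) < strength) b else sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
}

is_scalar_int <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x)

check_range_pair <- function(x, name, min_lo = 1) {
  if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || any(x != round(x)))
    abort(sprintf("`%s` must be an integer pair (min, max)", name))
  if (x[1] > x[2]) abort(sprintf("`%s` must satisfy min <= max", name))
  if (x[1] < min_lo) abort(sprintf("`%s` minimum must be >= %d", name, min_lo))
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  as.double(x)
}

# extract a character vector of windows from the various user-facing shapes
as_windows <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    if (!"window" %in% names(x)) abort("data frame input needs a `window` column")
    return(x$window)
  }
  abort("expected a character vector of windows or a data frame with a `window` column")
}
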