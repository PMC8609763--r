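# Dataset construction: positive window extraction, negative sampling in
# three categories (false-positive dinucleotides, exonic and intronic
# background), deduplication, composition strategies and train/test splits.

site_regex <- c(donor = "GT", acceptor = "AG")

window_has_n <- function(w) stringr::str_detect(w, "N")

central_dinucleotide <- function(window) {
  L <- nchar(window)
  substr(window, L / 2, L / 2 + 1)
}

#' Extract positive splice-site windows from annotated genes
#'
#' For every interior exon boundary of the requested type, a window of length
#' `2 * flank` is cut out of the genomic sequence so that the boundary
#' dinucleotide (the first two intron bases for donors, the last two for
#' acceptors) sits at positions `L/2` and `L/2 + 1` of the window. Windows
#' that would run past the sequence ends, or that contain an `N`, are
#' discarded. Genes with malformed exon maps are skipped with a warning.
#'
#' @param genes A gene tibble ([simulate_genes()], [read_gene_set()]).
#' @param site_type `"donor"` or `"acceptor"`.
#' @param flank Half window length in nt (window length is `2 * flank`).
#'
#' @return A tibble of examples with columns `window`, `label` (all 1),
#'   `site_type`, `origin` (`"true_site"`), `canonical`, `gene_id`,
#'   `center_pos` (1-based coordinate of the first base of the central
#'   dinucleotide).
#' @export
extract_positive_windows <- function(genes, site_type = c("donor", "acceptor"),
                                     flank = 300) {
  site_type <- match.arg(site_type)
  if (!is_scalar_int(flank) || flank < 1) abort("`flank` must be a positive integer")
  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    bad <- check_exon_map(g$exons[[1]], nchar(g$sequence))
    if (!is.null(bad)) {
      warn(sprintf("skipping gene %s: %s", g$gene_id, bad))
      return(NULL)
    }
    introns <- gene_introns(g$exons[[1]])
    introns <- introns[introns$end >= introns$start + 1, , drop = FALSE]
    if (nrow(introns) == 0) return(NULL)
    centers <- if (site_type == "donor") introns$donor_center else introns$acceptor_center
    start <- centers - flank + 1L
    end <- centers + flank
    keep <- start >= 1 & end <= nchar(g$sequence)
    if (!any(keep)) return(NULL)
    w <- substring(g$sequence, start[keep], end[keep])
    is_canon <- central_dinucleotide(w) == site_regex[[site_type]]
    tibble(window = w, label = 1L, site_type = site_type,
           origin = "true_site", canonical = is_canon,
           gene_id = g$gene_id, center_pos = centers[keep])
  })
  if (nrow(out) == 0) {
    return(tibble(window = character(0), label = integer(0), site_type = character(0),
                  origin = character(0), canonical = logical(0),
                  gene_id = character(0), center_pos = integer(0)))
  }
  out |> filter(!window_has_n(.data$window))
}

# symmetric crop of a window string keeping the central dinucleotide centred
trim_window_chr <- function(w, length) {
  L_old <- nchar(w)
  start <- L_old / 2 - length / 2 + 1
  substr(w, start, start + length - 1)
}

#' Trim windows to a shorter, even length
#'
#' Symmetric crop keeping the central dinucleotide at positions `L/2` and
#' `L/2 + 1` of the trimmed window (e.g. a 600-nt window with its site at
#' 301--302 becomes a 200-nt window with the site at 101--102).
#'
#' @param examples A tibble of examples, or a character vector of windows.
#' @param length Target (even) window length, at most the current length.
#' @return The same shape as `examples` with trimmed windows.
#' @export
trim_windows <- function(examples, length) {
  w <- as_windows(examples)
  L <- unique(nchar(w))
  if (length(L) != 1) abort("all windows must have the same length")
  if (length %% 2 != 0 || L %% 2 != 0) abort("window lengths must be even")
  if (length > L) abort(sprintf("target length %d exceeds window length %d", length, L))
  trimmed <- trim_window_chr(w, length)
  if (is.character(examples)) return(trimmed)
  mutate(examples, window = trimmed)
}

# enumerate candidate negative centers for one gene
candidate_centers <- function(gene, site_type, category, flank) {
  seqlen <- nchar(gene$sequence)
  introns <- gene_introns(gene$exons[[1]])
  annotated <- c(introns$donor_center, introns$acceptor_center)
  cand <- switch(category,
    fp_dinucleotide = {
      hits <- stringr::str_locate_all(gene$sequence, site_regex[[site_type]])[[1]]
      pos <- hits[, 1]
      setdiff(pos, if (site_type == "donor") introns$donor_center else introns$acceptor_center)
    },
    exon_bg = {
      ex <- gene$exons[[1]]
      pos <- unlist(purrr::map2(ex$start, ex$end, function(s, e) if (e > s) s:(e - 1L) else integer(0)))
      setdiff(pos, annotated)
    },
    intron_bg = {
      pos <- unlist(purrr::map2(introns$start, introns$end,
                                function(s, e) if (e > s) s:(e - 1L) else integer(0)))
      setdiff(pos, annotated)
    })
  cand <- cand[cand - flank + 1 >= 1 & cand + flank <= seqlen]
  as.integer(cand)
}

#' Sample negative (non-splice-site) windows
#'
#' Three categories are supported, mirroring the composition strategies of the
#' benchmark datasets: `"fp_dinucleotide"` centres windows on GT (donor model)
#' or AG (acceptor model) occurrences that are not annotated splice sites;
#' `"exon_bg"` and `"intron_bg"` centre windows on arbitrary dinucleotides
#' lying wholly inside an exon or intron (no constraint on their identity)
#' that are not annotated sites. Sampling is without replacement on
#' `(gene_id, center)` coordinates; windows containing `N` or running past
#' sequence ends are excluded up front.
#'
#' @inheritParams extract_positive_windows
#' @param category One of `"fp_dinucleotide"`, `"exon_bg"`, `"intron_bg"`.
#' @param n Number of windows to draw (>= 0).
#' @param exclude Optional tibble with columns `gene_id`, `center_pos` of
#'   centres that must not be drawn (e.g. the positive sites).
#' @param seed Integer seed for the draw.
#'
#' @return A tibble of examples (`label` 0, `origin` = `category`).
#' @export
sample_negatives <- function(genes, site_type = c("donor", "acceptor"),
                             category = c("fp_dinucleotide", "exon_bg", "intron_bg"),
                             n, exclude = NULL, flank = 300, seed = 1L) {
  site_type <- match.arg(site_type)
  category <- match.arg(category)
  if (!is_scalar_int(n) || n < 0) abort("`n` must be a non-negative integer")
  if (n == 0) {
    return(tibble(window = character(0), label = integer(0), site_type = character(0),
                  origin = character(0), canonical = logical(0),
                  gene_id = character(0), center_pos = integer(0)))
  }
  cand <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!is.null(check_exon_map(g$exons[[1]], nchar(g$sequence)))) return(NULL)
    tibble(gene_id = g$gene_id,
           center_pos = candidate_centers(g, site_type, category, flank))
  })
  if (!is.null(exclude) && nrow(cand) > 0)
    cand <- anti_join(cand, exclude[c("gene_id", "center_pos")],
                      by = c("gene_id", "center_pos"))
  # drop centres whose window contains an undetermined base
  if (nrow(cand) > 0) {
    seqs <- setNames(genes$sequence, genes$gene_id)
    w <- unname(substring(seqs[cand$gene_id], cand$center_pos - flank + 1,
                          cand$center_pos + flank))
    ok <- !window_has_n(w)
    cand <- cand[ok, , drop = FALSE]
    w <- w[ok]
  } else {
    w <- character(0)
  }
  if (nrow(cand) < n) {
    abort(sprintf(
      "requested %d %s negatives but only %d candidate centres are available (deficit %d)",
      n, category, nrow(cand), n - nrow(cand)))
  }
  pick <- withr::with_seed(seed, sample.int(nrow(cand), n))
  w <- w[pick]
  is_canon <- central_dinucleotide(w) == site_regex[[site_type]]
  tibble(window = w, label = 0L, site_type = site_type, origin = category,
         canonical = is_canon,
         gene_id = cand$gene_id[pick], center_pos = cand$center_pos[pick])
}

#' Remove duplicate windows, keeping first occurrences
#'
#' Duplicates are detected on the window string alone; the first occurrence in
#' input order survives.
#'
#' @param examples A tibble of examples.
#' @return The deduplicated tibble.
#' @export
dedup_windows <- function(examples) {
  distinct(examples, .data$window, .keep_all = TRUE)
}

spec_presets <- tibble(
  name = c("AS_0", "AS_1", "AS_2", "AS_10", "GS_0", "GS_1", "GS_2", "GS_10"),
  quality = rep(c("all", "confirmed_only"), each = 4),
  ratio = rep(c(1L, 1L, 2L, 10L), 2),
  negative_mix = rep(c("fp_only", "heterogeneous", "fp_only", "fp_only"), 2)
)

#' Describe a dataset composition strategy
#'
#' The eight named presets combine data quality (`AS_*` uses all genes,
#' `GS_*` only confirmed ones), the positive:negative ratio (1:1, 1:2, 1:10)
#' and the negative mix (`AS_0`/`GS_0`, `AS_2`/`GS_2` and `AS_10`/`GS_10` use
#' false-positive dinucleotides only; `AS_1`/`GS_1` mix exonic, intronic and
#' false-positive negatives in near-equal thirds). Custom specs set the
#' fields directly.
#'
#' @param name One of the presets above, or `"custom"`.
#' @param quality `"confirmed_only"` or `"all"`.
#' @param ratio Integer negatives-per-positive ratio.
#' @param negative_mix `"fp_only"` or `"heterogeneous"`.
#' @param window_length Even window length (one of the studied lengths
#'   20, 80, 140, 200, 400, 600, or any even value >= 4).
#' @param replicate Replicate index (1--10); each replicate draws an
#'   independent negative set from the same positives.
#' @param seed Base seed; the negative draw is seeded from `seed` and
#'   `replicate` jointly.
#'
#' @return An object of class `dataset_spec`.
#' @export
dataset_spec <- function(name = "custom",
                         quality = c("confirmed_only", "all"),
                         ratio = 1L,
                         negative_mix = c("heterogeneous", "fp_only"),
                         window_length = 200L,
                         replicate = 1L, seed = 1L) {
  if (name %in% spec_presets$name) {
    row <- spec_presets[spec_presets$name == name, ]
    quality <- row$quality
    ratio <- row$ratio
    negative_mix <- row$negative_mix
  } else {
    quality <- match.arg(quality)
    negative_mix <- match.arg(negative_mix)
  }
  if (!is_scalar_int(ratio) || ratio < 1) abort("`ratio` must be a positive integer")
  if (!is_scalar_int(window_length) || window_length < 4 || window_length %% 2 != 0)
    abort("`window_length` must be an even integer >= 4")
  if (!is_scalar_int(replicate) || replicate < 1) abort("`replicate` must be a positive integer")
  structure(list(name = name, quality = quality, ratio = as.integer(ratio),
                 negative_mix = negative_mix,
                 window_length = as.integer(window_length),
                 replicate = as.integer(replicate), seed = as.integer(seed)),
            class = "dataset_spec")
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf("<dataset_spec %s> quality=%s ratio=1:%d mix=%s W=%d replicate=%d seed=%d\n",
              x$name, x$quality, x$ratio, x$negative_mix, x$window_length,
              x$replicate, x$seed))
  invisible(x)
}

# Partition of n heterogeneous negatives into intron/exon/FP counts. Each of
# the intron and exon categories gets floor(n/3), rounded down to a multiple
# of 50 when n itself is a multiple of 50; the remainder goes to the FP
# category (11,000 -> 3650/3650/3700; 12,000 -> 4000/4000/4000; for n not
# divisible by 3 the spare examples land on FP).
neg_mix_counts <- function(n) {
  base <- n %/% 3L
  if (n %% 50L == 0L) base <- (base %/% 50L) * 50L
  c(intron_bg = base, exon_bg = base, fp_dinucleotide = n - 2L * base)
}

#' Assemble a dataset under a composition strategy
#'
#' Runs the construction pipeline for one site type: filter genes by quality
#' tier, extract and deduplicate positive windows, draw the negative
#' categories prescribed by the spec (with the positive centres excluded from
#' false-positive sampling), deduplicate negatives within themselves and
#' against the positives, and enforce the exact positive:negative ratio
#' (negatives lost to deduplication are re-drawn up to a retry cap, after
#' which the larger side is downsampled). The replicate index seeds an
#' independent negative draw so replicates share positives but not negatives.
#'
#' @inheritParams extract_positive_windows
#' @param spec A [dataset_spec()].
#' @param positives Optional pre-extracted positive examples (e.g. windows
#'   extracted at +/- 300 nt to be trimmed down); when `NULL` positives are
#'   extracted at `spec$window_length / 2` directly.
#'
#' @return A tibble of examples (positives then negatives) of class
#'   `splice_dataset`, with the spec and site type stored in attributes
#'   `"spec"` and `"site_type"`.
#' @export
assemble_dataset <- function(genes, spec, site_type = c("donor", "acceptor"),
                             positives = NULL) {
  stopifnot(inherits(spec, "dataset_spec"))
  site_type <- match.arg(site_type)
  flank <- spec$window_length %/% 2L
  if (spec$quality == "confirmed_only") genes <- filter(genes, .data$quality == "confirmed")
  if (is.null(positives)) {
    positives <- extract_positive_windows(genes, site_type, flank = flank)
  } else if (unique(nchar(positives$window)) != spec$window_length) {
    positives <- trim_windows(positives, spec$window_length)
  }
  positives <- dedup_windows(positives)
  if (nrow(positives) == 0) abort("no positive windows could be extracted")

  draw_seed <- derive_seed(spec$seed, spec$replicate)
  n_neg_target <- spec$ratio * nrow(positives)
  counts <- if (spec$negative_mix == "heterogeneous") {
    neg_mix_counts(n_neg_target)
  } else {
    c(fp_dinucleotide = n_neg_target)
  }
  exclusion <- positives[c("gene_id", "center_pos")]
  negatives <- purrr::imap_dfr(counts, function(k, cat) {
    if (k == 0) return(NULL)
    sample_negatives(genes, site_type, cat, n = k, exclude = exclusion,
                     flank = flank, seed = derive_seed(draw_seed, match(cat, names(counts))))
  })

  for (retry in seq_len(5)) {
    negatives <- dedup_windows(negatives)
    negatives <- negatives[!negatives$window %in% positives$window, , drop = FALSE]
    deficit <- n_neg_target - nrow(negatives)
    if (deficit <= 0) break
    extra <- tryCatch(
      sample_negatives(genes, site_type, "fp_dinucleotide", n = deficit,
                       exclude = bind_rows(exclusion,
                                           negatives[c("gene_id", "center_pos")]),
                       flank = flank, seed = derive_seed(draw_seed, 100L + retry)),
      error = function(e) NULL)
    if (is.null(extra)) break
    negatives <- bind_rows(negatives, extra)
  }
  if (nrow(negatives) < n_neg_target) {
    # dedup exhausted the sampling space: downsample positives to keep the
    # ratio exact
    n_pos <- nrow(negatives) %/% spec$ratio
    if (n_pos < 1) abort("insufficient sampling space for the requested negative set")
    positives <- positives[seq_len(n_pos), , drop = FALSE]
    n_neg_target <- spec$ratio * n_pos
  }
  negatives <- negatives[seq_len(n_neg_target), , drop = FALSE]
  out <- bind_rows(positives, negatives)
  attr(out, "spec") <- spec
  attr(out, "site_type") <- site_type
  class(out) <- c("splice_dataset", class(out))
  out
}

#' Stratified train/test split
#'
#' Shuffles each label stratum and assigns `train_fraction` of it (rounded to
#' the nearest integer) to the training partition, so both partitions
#' preserve the positive:negative ratio to within one example per class.
#'
#' @param dataset A tibble of examples with a `label` column.
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed for the shuffle.
#' @return The dataset with an added `partition` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, seed = 1L) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must be in (0, 1)")
  tab <- table(dataset$label)
  if (length(tab) < 2 || any(tab < 5))
    abort("each class needs at least 5 examples to split")
  withr::with_seed(seed, {
    parts <- lapply(split(seq_len(nrow(dataset)), dataset$label), function(idx) {
      idx <- sample(idx)
      n_train <- floor(train_fraction * length(idx) + 0.5)
      list(train = idx[seq_len(n_train)], test = idx[-seq_len(n_train)])
    })
  })
  partition <- character(nrow(dataset))
  for (p in parts) {
    partition[p$train] <- "train"
    partition[p$test] <- "test"
  }
  dataset$partition <- partition
  dataset
}
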