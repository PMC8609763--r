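#' Parameters for the synthetic gene generator
#'
#' Bundles and validates the knobs of the multi-exon gene simulator. The
#' simulator plants the sequence signals a splice-site classifier is expected
#' to learn: a donor consensus `aG|GTAAGT` spanning the last two exonic and
#' first six intronic bases, and an acceptor region made of a branchpoint-like
#' pentamer (`CTRAC`, ending 20--40 nt upstream of the intron end), a
#' polypyrimidine tract and a terminal `N(C/T)AG`. Boundary dinucleotides are
#' canonical GT/AG except for a tunable fraction of non-canonical sites
#' (GC donors; AC acceptors, paired with an AT donor when both flags fire in
#' the same intron), defaulting to the 2.2\% / 1.3\% rates observed across
#' eukaryotes.
#'
#' @param n_exons_range Integer pair, minimum and maximum number of exons per
#'   gene (both at least 2, so every gene has at least one intron).
#' @param exon_len_range Integer pair, exon length range in nt.
#' @param intron_len_range Integer pair, intron length range in nt. The
#'   minimum must be at least 60 nt so that the donor motif, branchpoint,
#'   polypyrimidine tract and acceptor motif never overlap.
#' @param gc_background GC fraction of the i.i.d. background sequence.
#' @param p_noncanonical_donor Probability that an intron gets a GC donor.
#' @param p_noncanonical_acceptor Probability that an intron gets an AC
#'   acceptor.
#' @param ppt_len_range Integer pair, polypyrimidine tract length in nt
#'   (maximum 15, so the tract never reaches the branchpoint window).
#' @param motif_strength Per-position probability of emitting the consensus
#'   base at the informative (non-boundary) motif positions; the remaining
#'   mass is uniform over the other three bases.
#' @param seed Integer seed used when a gene is generated directly from the
#'   params object.
#'
#' @return An object of class `gene_params`.
#' @export
gene_params <- function(n_exons_range = c(3L, 8L),
                        exon_len_range = c(80L, 320L),
                        intron_len_range = c(70L, 350L),
                        gc_background = 0.5,
                        p_noncanonical_donor = 0.022,
                        p_noncanonical_acceptor = 0.013,
                        ppt_len_range = c(8L, 15L),
                        motif_strength = 0.85,
                        seed = 1L) {
  p <- list(
    n_exons_range = check_range_pair(n_exons_range, "n_exons_range", min_lo = 2),
    exon_len_range = check_range_pair(exon_len_range, "exon_len_range"),
    intron_len_range = check_range_pair(intron_len_range, "intron_len_range"),
    gc_background = check_prob(gc_background, "gc_background"),
    p_noncanonical_donor = check_prob(p_noncanonical_donor, "p_noncanonical_donor"),
    p_noncanonical_acceptor = check_prob(p_noncanonical_acceptor, "p_noncanonical_acceptor"),
    ppt_len_range = check_range_pair(ppt_len_range, "ppt_len_range"),
    motif_strength = check_prob(motif_strength, "motif_strength"),
    seed = as.integer(seed)
  )
  # branchpoint pentamer ends 20-40 nt upstream of the intron end; the intron
  # must fit donor head (6) + pentamer at its furthest offset + acceptor tail
  if (p$intron_len_range[1] < 60)
    abort("`intron_len_range` minimum must be >= 60 nt to accommodate the planted signals")
  if (p$ppt_len_range[2] > 15)
    abort("`ppt_len_range` maximum must be <= 15 nt so the tract stays clear of the branchpoint window")
  structure(p, class = "gene_params")
}

#' @export
print.gene_params <- function(x, ...) {
  cat("<gene_params>\n")
  cat(sprintf("  exons %d-%d of %d-%d nt, introns %d-%d nt, GC %.2f\n",
              x$n_exons_range[1], x$n_exons_range[2],
              x$exon_len_range[1], x$exon_len_range[2],
              x$intron_len_range[1], x$intron_len_range[2], x$gc_background))
  cat(sprintf("  non-canonical donor %.3f / acceptor %.3f, motif strength %.2f\n",
              x$p_noncanonical_donor, x$p_noncanonical_acceptor, x$motif_strength))
  invisible(x)
}

# assemble one intron of length m with planted signals; returns list(seq, d, a)
# where d/a are the boundary dinucleotides actually planted
plant_intron <- function(m, params) {
  ms <- params$motif_strength
  s <- sample_bases(m, params$gc_background)
  nc_d <- stats::runif(1) < params$p_noncanonical_donor
  nc_a <- stats::runif(1) < params$p_noncanonical_acceptor
  if (nc_d && nc_a) { d <- c("A", "T"); a <- c("A", "C") }
  else if (nc_d)    { d <- c("G", "C"); a <- c("A", "G") }
  else if (nc_a)    { d <- c("G", "T"); a <- c("A", "C") }
  else              { d <- c("G", "T"); a <- c("A", "G") }
  # donor: boundary dinucleotide exact, +3..+6 consensus AAGT
  s[1:2] <- d
  s[3:6] <- sample_consensus(c("A", "A", "G", "T"), ms)
  # branchpoint CTRAC, last base 20-40 nt upstream of the intron end
  off <- sample(20:40, 1)
  bp <- c("C", "T", sample(c("A", "G"), 1), "A", "C")
  s[(m - off - 4):(m - off)] <- bp
  # polypyrimidine tract immediately upstream of the terminal N(C/T)AG
  plen <- sample(params$ppt_len_range[1]:params$ppt_len_range[2], 1)
  ppt <- ifelse(stats::runif(plen) < 0.9,
                sample(c("C", "T"), plen, replace = TRUE),
                sample(c("A", "G"), plen, replace = TRUE))
  s[(m - 3 - plen):(m - 4)] <- ppt
  # N (background), pyrimidine (C favoured), then the boundary dinucleotide
  if (stats::runif(1) < ms)
    s[m - 2] <- sample(c("C", "T"), 1, prob = c(2, 1))
  s[(m - 1):m] <- a
  list(seq = s, donor = paste(d, collapse = ""), acceptor = paste(a, collapse = ""))
}

#' Generate one synthetic multi-exon gene
#'
#' Draws exon/intron counts and lengths uniformly from the ranges in `params`,
#' fills the gene with i.i.d. background at the requested GC content and
#' overwrites each intron with the planted donor/branchpoint/PPT/acceptor
#' signals (see [gene_params()]). The two exonic bases flanking each boundary
#' are also drawn from the consensus (`aG` upstream of donors, `Gt`-like
#' downstream of acceptors).
#'
#' @param params A [gene_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @param gene_id Identifier for the gene.
#'
#' @return A one-row tibble with columns `gene_id`, `sequence`, `exons`
#'   (list column of tibbles with `start`/`end`, 1-based inclusive),
#'   `quality` (`"confirmed"`) and `seed`.
#' @export
generate_gene <- function(params = gene_params(), seed = params$seed,
                          gene_id = "gene_1") {
  stopifnot(inherits(params, "gene_params"))
  withr::with_seed(seed, {
    ms <- params$motif_strength
    ne <- sample(params$n_exons_range[1]:params$n_exons_range[2], 1)
    elens <- sample(params$exon_len_range[1]:params$exon_len_range[2], ne, replace = TRUE)
    ilens <- sample(params$intron_len_range[1]:params$intron_len_range[2], ne - 1, replace = TRUE)
    parts <- vector("list", 2 * ne - 1)
    for (i in seq_len(ne)) parts[[2 * i - 1]] <- sample_bases(elens[i], params$gc_background)
    for (j in seq_len(ne - 1)) {
      intron <- plant_intron(ilens[j], params)
      parts[[2 * j]] <- intron$seq
      # exonic flanks of the consensus motifs
      up <- parts[[2 * j - 1]]
      up[(length(up) - 1):length(up)] <- sample_consensus(c("A", "G"), ms)
      parts[[2 * j - 1]] <- up
      dn <- parts[[2 * j + 1]]
      dn[1] <- if (stats::runif(1) < ms) sample(c("G", "A"), 1) else sample(c("C", "T"), 1)
      dn[2] <- sample_consensus("T", ms)
      parts[[2 * j + 1]] <- dn
    }
    lens <- vapply(parts, length, integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    exon_idx <- seq(1, 2 * ne - 1, by = 2)
    exons <- tibble(start = starts[exon_idx], end = ends[exon_idx])
    tibble(gene_id = gene_id,
           sequence = paste(unlist(parts), collapse = ""),
           exons = list(exons),
           quality = "confirmed",
           seed = as.integer(seed))
  })
}

# corrupt one exon boundary by 1-15 nt, mimicking a gene-prediction error
corrupt_gene <- function(gene, seed) {
  withr::with_seed(seed, {
    ex <- gene$exons[[1]]
    ne <- nrow(ex)
    # interior boundaries: ends of exons 1..ne-1 (donor side) and starts of
    # exons 2..ne (acceptor side)
    k <- sample(2 * (ne - 1), 1)
    shift <- sample(c(-15:-1, 1:15), 1)
    if (k <= ne - 1) {
      i <- k
      new_end <- ex$end[i] + shift
      new_end <- max(ex$start[i] + 1, min(new_end, ex$start[i + 1] - 2))
      ex$end[i] <- new_end
    } else {
      i <- k - (ne - 1) + 1L
      new_start <- ex$start[i] + shift
      new_start <- max(ex$end[i - 1] + 2, min(new_start, ex$end[i] - 1))
      ex$start[i] <- new_start
    }
    gene$exons <- list(ex)
    gene$quality <- "unconfirmed"
    gene
  })
}

#' Generate a reproducible set of synthetic genes
#'
#' Per-gene seeds are derived from the master seed with a fixed hash, so the
#' output is byte-identical for a given `seed` and the set can be regenerated
#' gene by gene. Optionally a fraction of genes is degraded to `"unconfirmed"`
#' quality by shifting one exon boundary by 1--15 nt, which corrupts the true
#' splice sites the way an erroneous gene prediction would.
#'
#' @param n_genes Number of genes (>= 0).
#' @param params A [gene_params()] object.
#' @param seed Master integer seed.
#' @param p_unconfirmed Fraction of genes whose annotation is corrupted.
#' @param dir If non-`NULL`, directory where `genes.fasta`, `exons.gff3` and
#'   `exons.tsv` are written.
#'
#' @return A tibble of genes (see [generate_gene()]), invisibly carrying the
#'   file paths written (attribute `"files"`) when `dir` is given.
#' @export
simulate_genes <- function(n_genes, params = gene_params(), seed = 1L,
                           p_unconfirmed = 0, dir = NULL) {
  if (!is_scalar_int(n_genes) || n_genes < 0) abort("`n_genes` must be a non-negative integer")
  check_prob(p_unconfirmed, "p_unconfirmed")
  if (n_genes == 0) {
    return(tibble(gene_id = character(0), sequence = character(0),
                  exons = list(), quality = character(0), seed = integer(0)))
  }
  genes <- purrr::map_dfr(seq_len(n_genes), function(i) {
    gseed <- derive_seed(seed, i)
    g <- generate_gene(params, seed = gseed, gene_id = sprintf("gene_%04d", i))
    flip <- withr::with_seed(derive_seed(gseed, 1L), stats::runif(1) < p_unconfirmed)
    if (flip) g <- corrupt_gene(g, derive_seed(gseed, 2L))
    g
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(fasta = file.path(dir, "genes.fasta"),
               gff3 = file.path(dir, "exons.gff3"),
               tsv = file.path(dir, "exons.tsv"))
    write_gene_fasta(genes, files["fasta"])
    write_exon_map(genes, files["gff3"], format = "gff3")
    write_exon_map(genes, files["tsv"], format = "tsv")
    attr(genes, "files") <- files
  }
  genes
}

# intron intervals (1-based inclusive) of one gene's exon map, with the
# donor/acceptor window centers used throughout the package
gene_introns <- function(exons) {
  if (nrow(exons) < 2) {
    return(tibble(start = integer(0), end = integer(0),
                  donor_center = integer(0), acceptor_center = integer(0)))
  }
  ex <- dplyr::arrange(exons, .data$start)
  tibble(start = ex$end[-nrow(ex)] + 1L,
         end = ex$start[-1] - 1L) |>
    mutate(donor_center = .data$start, acceptor_center = .data$end - 1L)
}

# validate an exon map; returns NULL if fine, else a message
check_exon_map <- function(exons, seq_len) {
  if (nrow(exons) == 0) return("empty exon map")
  ex <- dplyr::arrange(exons, .data$start)
  if (any(ex$start > ex$end)) return("exon with start > end")
  if (any(ex$start < 1) || any(ex$end > seq_len)) return("exon outside sequence")
  if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) return("overlapping exons")
  NULL
}
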