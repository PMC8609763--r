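# File interfaces: FASTA for sequences, GFF3/TSV for exon maps, TSV/FASTA for
# dataset manifests and labelled benchmarks.

#' Write gene sequences to FASTA
#'
#' Headers carry the quality tier and the per-gene seed, e.g.
#' `>gene_0001 quality=confirmed seed=12345`. Sequences are wrapped at 60
#' columns.
#'
#' @param genes A gene tibble from [simulate_genes()] or [read_gene_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_fasta <- function(genes, path) {
  headers <- sprintf("%s quality=%s seed=%d", genes$gene_id, genes$quality,
                     genes$seed %||% rep(0L, nrow(genes)))
  x <- Biostrings::DNAStringSet(setNames(genes$sequence, headers))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Write an exon map as GFF3 or 3-column TSV
#'
#' GFF3 output holds one `exon` feature per exon, 1-based inclusive, forward
#' strand; the TSV flavour has columns `gene_id`, `start`, `end`.
#'
#' @inheritParams write_gene_fasta
#' @param format `"gff3"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_exon_map <- function(genes, path, format = c("gff3", "tsv")) {
  format <- match.arg(format)
  flat <- genes |>
    select("gene_id", "exons") |>
    tidyr::unnest("exons")
  if (format == "tsv") {
    write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = flat$gene_id,
      ranges = IRanges::IRanges(start = flat$start, end = flat$end),
      strand = "+", type = "exon")
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Read genes from FASTA plus an exon map
#'
#' The exon map may be GFF3 (features of type `exon`) or the 3-column TSV
#' written by [write_exon_map()]; the format is sniffed from the first line.
#' Quality tiers and seeds are recovered from FASTA headers when present
#' (`quality=... seed=...`), defaulting to `"confirmed"`.
#'
#' @param fasta Path to the FASTA file.
#' @param exon_map Path to the exon map (GFF3 or TSV).
#' @return A gene tibble as produced by [simulate_genes()].
#' @export
read_gene_set <- function(fasta, exon_map) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  qual <- ifelse(grepl("quality=unconfirmed", headers), "unconfirmed", "confirmed")
  seed <- suppressWarnings(as.integer(sub(".*seed=(\\d+).*", "\\1", headers)))
  seed[is.na(seed)] <- 0L
  first <- readLines(exon_map, n = 1)
  if (grepl("^##gff", first) || grepl("gff3?$", exon_map)) {
    gr <- rtracklayer::import(exon_map, format = "GFF3")
    gr <- gr[as.character(gr$type) == "exon"]
    flat <- tibble(gene_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  } else {
    flat <- as_tibble(read.table(exon_map, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
  }
  exon_list <- lapply(ids, function(id) {
    flat |> filter(.data$gene_id == id) |> select("start", "end") |> arrange(.data$start)
  })
  tibble(gene_id = ids, sequence = unname(as.character(seqs)),
         exons = exon_list, quality = qual, seed = seed)
}

#' Write a dataset manifest as TSV
#'
#' One row per example with columns `window`, `label`, `site_type`, `origin`,
#' `canonical`, `gene_id`, `center_pos` (and `partition` if present).
#'
#' @param examples A tibble of examples (e.g. from [assemble_dataset()]).
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(examples, path) {
  cols <- intersect(c("window", "label", "site_type", "origin", "canonical",
                      "gene_id", "center_pos", "partition"), names(examples))
  write.table(examples[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest written by [write_dataset_tsv()]
#' @param path TSV file.
#' @return A tibble of examples.
#' @export
read_dataset_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
}

#' Write examples as a labelled FASTA
#'
#' Headers are structured as
#' `>id label=<0|1> site=<donor|acceptor> origin=<...> gene=<...> pos=<...>`.
#'
#' @inheritParams write_dataset_tsv
#' @export
write_dataset_fasta <- function(examples, path) {
  headers <- sprintf("ex_%06d label=%d site=%s origin=%s gene=%s pos=%d",
                     seq_len(nrow(examples)), examples$label, examples$site_type,
                     examples$origin, examples$gene_id, examples$center_pos)
  x <- Biostrings::DNAStringSet(setNames(examples$window, headers))
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a labelled benchmark FASTA
#'
#' Expects headers carrying `label=0|1` and optionally `site=donor|acceptor`,
#' the layout written by [write_dataset_fasta()].
#'
#' @param path FASTA file.
#' @return A tibble with columns `id`, `window`, `label`, `site_type`.
#' @export
read_benchmark_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  headers <- names(x)
  lab <- suppressWarnings(as.integer(sub(".*label=([01]).*", "\\1", headers)))
  if (anyNA(lab)) abort("benchmark FASTA headers must carry `label=0` or `label=1`")
  site <- ifelse(grepl("site=acceptor", headers), "acceptor",
                 ifelse(grepl("site=donor", headers), "donor", NA_character_))
  tibble(id = sub("\\s.*$", "", headers), window = as.character(x),
         label = lab, site_type = site)
}
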