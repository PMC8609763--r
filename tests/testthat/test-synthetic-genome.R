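# The gene simulator: structural contracts, planted-signal statistics and
# file round trips.

test_that("generated genes respect structural contracts", {
  p <- gene_params(n_exons_range = c(2, 2), p_noncanonical_donor = 0,
                   p_noncanonical_acceptor = 0)
  g <- generate_gene(p, seed = 7)
  ex <- g$exons[[1]]
  expect_equal(nrow(ex), 2)
  expect_true(all(ex$start <= ex$end))
  expect_true(all(ex$end <= nchar(g$sequence)))
  expect_true(ex$start[2] > ex$end[1] + 1)          # one real intron

  genes <- simulate_genes(25, gene_params(p_noncanonical_donor = 0,
                                          p_noncanonical_acceptor = 0),
                          seed = 3)
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    expect_true(all(diff(ex$start) > 0))
    introns <- tibble::tibble(start = ex$end[-nrow(ex)] + 1,
                              end = ex$start[-1] - 1)
    s <- genes$sequence[i]
    expect_true(all(substring(s, introns$start, introns$start + 1) == "GT"))
    expect_true(all(substring(s, introns$end - 1, introns$end) == "AG"))
  }
})

test_that("the gene set generator is deterministic and seed-sensitive", {
  a <- simulate_genes(8, seed = 99)
  b <- simulate_genes(8, seed = 99)
  c <- simulate_genes(8, seed = 100)
  expect_identical(a, b)
  expect_false(identical(a$sequence, c$sequence))
  expect_identical(simulate_genes(0, seed = 1)$gene_id, character(0))
})

test_that("non-canonical boundary rates fall inside exact binomial bands", {
  genes <- simulate_genes(300, seed = 12345)
  boundaries <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    s <- genes$sequence[i]
    tibble::tibble(
      donor = substring(s, ex$end[-nrow(ex)] + 1, ex$end[-nrow(ex)] + 2),
      acceptor = substring(s, ex$start[-1] - 2, ex$start[-1] - 1))
  })
  n <- nrow(boundaries)
  expect_gt(n, 1000)
  k_donor <- sum(boundaries$donor != "GT")
  k_acceptor <- sum(boundaries$acceptor != "AG")
  # exact binomial 99% central interval at the configured rates
  expect_true(k_donor >= qbinom(0.005, n, 0.022) &&
              k_donor <= qbinom(0.995, n, 0.022))
  expect_true(k_acceptor >= qbinom(0.005, n, 0.013) &&
              k_acceptor <= qbinom(0.995, n, 0.013))
})

test_that("site counts equal intron counts for every gene", {
  genes <- simulate_genes(50, seed = 31)
  expected_introns <- sum(vapply(genes$exons, nrow, integer(1)) - 1L)
  don <- extract_positive_windows(genes, "donor", flank = 10)
  acc <- extract_positive_windows(genes, "acceptor", flank = 10)
  # flank 10 never reaches past gene ends (first/last exons are >= 80 nt)
  expect_equal(nrow(don), expected_introns)
  expect_equal(nrow(acc), expected_introns)
  for (i in seq_len(nrow(genes))) {
    ni <- nrow(genes$exons[[i]]) - 1L
    expect_equal(sum(don$gene_id == genes$gene_id[i]), ni)
    expect_equal(sum(acc$gene_id == genes$gene_id[i]), ni)
  }
})

test_that("donor positions +3..+6 are enriched for the planted consensus", {
  genes <- simulate_genes(200, seed = 77)
  flanks <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    start <- ex$end[-nrow(ex)] + 1
    tibble::tibble(motif = substring(genes$sequence[i], start + 2, start + 5))
  })
  expect_gt(nrow(flanks), 800)
  consensus <- c("A", "A", "G", "T")
  for (j in 1:4) {
    counts <- table(factor(substring(flanks$motif, j, j),
                           levels = c("A", "C", "G", "T")))
    chi <- chisq.test(counts, p = rep(0.25, 4))
    expect_lt(chi$p.value, 0.01)
    expect_equal(names(which.max(counts)), consensus[j])
  }
})

test_that("FASTA + exon maps round-trip and are byte-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- simulate_genes(5, seed = 8, p_unconfirmed = 0.4, dir = d1)
  simulate_genes(5, seed = 8, p_unconfirmed = 0.4, dir = d2)
  for (f in c("genes.fasta", "exons.gff3", "exons.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  back_gff <- read_gene_set(file.path(d1, "genes.fasta"),
                            file.path(d1, "exons.gff3"))
  back_tsv <- read_gene_set(file.path(d1, "genes.fasta"),
                            file.path(d1, "exons.tsv"))
  expect_equal(back_gff$sequence, g1$sequence)
  expect_equal(back_gff$quality, g1$quality)
  for (i in seq_len(nrow(g1))) {
    expect_equal(as.data.frame(back_gff$exons[[i]]), as.data.frame(g1$exons[[i]]))
    expect_equal(as.data.frame(back_tsv$exons[[i]]), as.data.frame(g1$exons[[i]]))
  }
})

test_that("unconfirmed genes carry a corrupted exon boundary", {
  clean <- simulate_genes(10, seed = 55, p_unconfirmed = 0)
  noisy <- simulate_genes(10, seed = 55, p_unconfirmed = 1)
  expect_true(all(noisy$quality == "unconfirmed"))
  expect_identical(clean$sequence, noisy$sequence)   # only annotation changes
  for (i in seq_len(10)) {
    expect_false(identical(as.data.frame(clean$exons[[i]]),
                           as.data.frame(noisy$exons[[i]])))
    expect_null(splicecnn:::check_exon_map(noisy$exons[[i]],
                                           nchar(noisy$sequence[i])))
  }
})

test_that("parameter validation rejects impossible constraints", {
  expect_error(gene_params(n_exons_range = c(1, 3)), ">= 2")
  expect_error(gene_params(intron_len_range = c(40, 100)), "60")
  expect_error(gene_params(p_noncanonical_donor = 1.5), "probability")
  expect_error(gene_params(ppt_len_range = c(8, 30)), "branchpoint")
})
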