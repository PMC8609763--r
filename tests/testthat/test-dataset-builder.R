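# Dataset construction: window extraction, trimming, negative sampling,
# deduplication, composition strategies, splits and QC statistics.

test_that("positive windows are cut around intron boundaries as specified", {
  g <- toy_gene()
  don <- extract_positive_windows(g, "donor", flank = 4)
  expect_equal(nrow(don), 1)
  expect_equal(don$window, "CGAGTAAG")
  expect_equal(substr(don$window, 4, 5), "GT")
  expect_equal(don$center_pos, 11L)
  expect_true(don$canonical)

  acc <- extract_positive_windows(g, "acceptor", flank = 4)
  expect_equal(acc$window, "TCTAGCCT")
  expect_equal(substr(acc$window, 4, 5), "AG")
  expect_equal(acc$center_pos, 19L)

  single <- toy_gene()
  single$exons <- list(tibble::tibble(start = 1L, end = 30L))
  expect_equal(nrow(extract_positive_windows(single, "donor", flank = 4)), 0)
  expect_equal(nrow(extract_positive_windows(g[0, ], "donor")), 0)
})

test_that("malformed exon maps are skipped with a warning", {
  g <- dplyr::bind_rows(toy_gene(), toy_gene())
  g$gene_id <- c("ok", "broken")
  g$exons[[2]] <- tibble::tibble(start = c(1L, 5L), end = c(10L, 30L))  # overlap
  expect_warning(out <- extract_positive_windows(g, "donor", flank = 4),
                 "broken")
  expect_equal(unique(out$gene_id), "ok")
})

test_that("trimming keeps the central dinucleotide at L/2, L/2+1", {
  # 600-nt window with the site dinucleotide planted at 301-302
  w600 <- paste0(strrep("A", 300), "GT", strrep("C", 298))
  w200 <- trim_windows(w600, 200)
  expect_equal(nchar(w200), 200)
  expect_equal(substr(w200, 101, 102), "GT")
  # index-arithmetic oracle: crop must start at L_old/2 - L/2 + 1
  expect_equal(w200, substr(w600, 600 / 2 - 200 / 2 + 1, 600 / 2 + 200 / 2))
  expect_equal(trim_windows("CGAGTAAG", 4), "AGTA")
  expect_equal(trim_windows("CGAGTAAG", 8), "CGAGTAAG")
  expect_error(trim_windows("CGAGTAAG", 10), "exceeds")
  expect_error(trim_windows("CGAGTAAG", 5), "even")
})

test_that("false-positive negatives enumerate exactly the non-site dinucleotides", {
  g <- toy_gene()
  # brute-force oracle: all GT occurrences by regex, minus the true donor
  hits <- gregexpr("GT", g$sequence)[[1]]
  expected <- setdiff(as.integer(hits), 11L)
  expected <- expected[expected - 4 + 1 >= 1 & expected + 4 <= 30]
  got <- sample_negatives(g, "donor", "fp_dinucleotide", n = length(expected),
                          flank = 4, seed = 1)
  expect_setequal(got$center_pos, expected)
  expect_true(all(substr(got$window, 4, 5) == "GT"))
  expect_true(all(got$label == 0L))

  expect_equal(nrow(sample_negatives(g, "donor", "fp_dinucleotide", n = 0,
                                     flank = 4)), 0)
  expect_error(sample_negatives(g, "donor", "fp_dinucleotide",
                                n = length(expected) + 5, flank = 4, seed = 1),
               "deficit")
})

test_that("background negatives stay inside their compartment and off the sites", {
  genes <- small_genes()
  for (cat in c("exon_bg", "intron_bg")) {
    neg <- sample_negatives(genes, "donor", cat, n = 200, flank = 10, seed = 2)
    expect_equal(nrow(neg), 200)
    expect_equal(anyDuplicated(neg[c("gene_id", "center_pos")]), 0L)
    for (i in seq_len(nrow(neg))) {
      ex <- genes$exons[[match(neg$gene_id[i], genes$gene_id)]]
      inside_exon <- any(neg$center_pos[i] >= ex$start &
                         neg$center_pos[i] + 1 <= ex$end)
      introns <- splicecnn:::gene_introns(ex)
      inside_intron <- any(neg$center_pos[i] >= introns$start &
                           neg$center_pos[i] + 1 <= introns$end)
      if (cat == "exon_bg") expect_true(inside_exon) else expect_true(inside_intron)
      expect_false(neg$center_pos[i] %in%
                     c(introns$donor_center, introns$acceptor_center))
    }
  }
})

test_that("deduplication keeps first occurrences by window string", {
  df <- tibble::tibble(window = c("ACGT", "ACGT"), label = c(1L, 0L))
  out <- dedup_windows(df)
  expect_equal(nrow(out), 1)
  expect_equal(out$label, 1L)                      # first occurrence wins

  uniq <- tibble::tibble(window = random_windows(20, 8, seed = 1), label = 1L)
  expect_identical(dedup_windows(uniq), uniq)

  # 100 windows containing 17 exact duplicates -> 83 survive
  base <- random_windows(83, 12, seed = 2)
  shuffled <- withr::with_seed(3, sample(c(base, base[1:17])))
  dup <- tibble::tibble(window = shuffled, label = 0L)
  expect_equal(nrow(dedup_windows(dup)), 83)
})

test_that("heterogeneous negative counts mirror the published composition", {
  expect_equal(unname(splicecnn:::neg_mix_counts(11000L)), c(3650L, 3650L, 3700L))
  expect_equal(unname(splicecnn:::neg_mix_counts(12000L)), c(4000L, 4000L, 4000L))
  expect_equal(unname(splicecnn:::neg_mix_counts(10L)), c(3L, 3L, 4L))
  expect_equal(names(splicecnn:::neg_mix_counts(9L)),
               c("intron_bg", "exon_bg", "fp_dinucleotide"))
  for (n in c(9L, 10L, 100L, 11000L, 12000L))
    expect_equal(sum(splicecnn:::neg_mix_counts(n)), n)
})

test_that("assembled datasets satisfy ratio, purity and replicate contracts", {
  genes <- small_genes()
  spec1 <- dataset_spec("GS_1", window_length = 80, seed = 3)
  ds <- assemble_dataset(genes, spec1, "donor")
  n_pos <- sum(ds$label == 1)
  expect_equal(sum(ds$label == 0), spec1$ratio * n_pos)
  expect_equal(anyDuplicated(ds$window), 0L)
  expect_false(any(grepl("N", ds$window)))
  # positives: central dinucleotide agrees with the canonical flag, by regex
  pos <- dplyr::filter(ds, label == 1)
  expect_equal(substr(pos$window, 40, 41) == "GT", pos$canonical)
  # heterogeneous mix: near-equal thirds with the remainder on FP
  mix <- table(dplyr::filter(ds, label == 0)$origin)
  expected <- splicecnn:::neg_mix_counts(spec1$ratio * n_pos)
  expect_equal(unname(mix[names(expected)]), unname(expected),
               ignore_attr = TRUE)

  # 1:2 ratio
  ds2 <- assemble_dataset(genes, dataset_spec("GS_2", window_length = 80, seed = 3),
                          "donor")
  expect_equal(sum(ds2$label == 0), 2 * sum(ds2$label == 1))

  # replicates share positives but draw different negatives
  r2 <- assemble_dataset(genes, dataset_spec("GS_1", window_length = 80,
                                             replicate = 2, seed = 3), "donor")
  expect_setequal(dplyr::filter(ds, label == 1)$window,
                  dplyr::filter(r2, label == 1)$window)
  expect_false(setequal(dplyr::filter(ds, label == 0)$window,
                        dplyr::filter(r2, label == 0)$window))
})

test_that("quality filtering drops unconfirmed genes from gold-standard sets", {
  genes <- simulate_genes(30, seed = 2, p_unconfirmed = 0.5)
  gs <- assemble_dataset(genes, dataset_spec("GS_1", window_length = 20, seed = 1),
                         "donor")
  confirmed <- genes$gene_id[genes$quality == "confirmed"]
  expect_true(all(dplyr::filter(gs, label == 1)$gene_id %in% confirmed))
  as <- assemble_dataset(genes, dataset_spec("AS_1", window_length = 20, seed = 1),
                         "donor")
  expect_gt(nrow(dplyr::filter(as, label == 1)), nrow(dplyr::filter(gs, label == 1)))
})

test_that("train/test split is stratified, exact and reproducible", {
  fake <- tibble::tibble(window = as.character(seq_len(2000)),
                         label = rep(c(0L, 1L), each = 1000))
  sp <- split_train_test(fake, 0.8, seed = 1)
  expect_equal(unname(table(sp$partition, sp$label)["train", ]), c(800, 800))
  expect_equal(unname(table(sp$partition, sp$label)["test", ]), c(200, 200))

  big <- tibble::tibble(window = as.character(seq_len(22000)),
                        label = rep(c(0L, 1L), each = 11000))
  spb <- split_train_test(big, 0.8, seed = 1)
  expect_equal(sum(spb$partition == "train"), 17600)
  expect_equal(sum(spb$partition == "test"), 4400)

  expect_identical(split_train_test(fake, 0.8, seed = 9),
                   split_train_test(fake, 0.8, seed = 9))
  expect_false(identical(split_train_test(fake, 0.8, seed = 9)$partition,
                         split_train_test(fake, 0.8, seed = 10)$partition))

  # stratification within one example per class at awkward sizes
  odd <- tibble::tibble(window = as.character(seq_len(25)),
                        label = rep(c(0L, 1L), c(13, 12)))
  so <- split_train_test(odd, 0.8, seed = 2)
  tab <- table(so$partition, so$label)
  expect_lte(abs(tab["train", "0"] / 13 - tab["train", "1"] / 12), 0.1)

  expect_error(split_train_test(odd[1:8, ], 0.8), "at least 5")
  expect_error(split_train_test(fake, 1.2), "must be in")
})
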