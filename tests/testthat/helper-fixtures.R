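# Shared fixtures, built in code and cached for the duration of a test run.

.fixtures <- new.env(parent = emptyenv())

# The three-part worked-example gene: 10-nt exon, 10-nt intron (GTAAGT...TAG
# would be 3' AG at 19-20), 10-nt exon.
toy_gene <- function() {
  tibble::tibble(
    gene_id = "toy",
    sequence = paste0("ACGACGACGA", "GTAAGTCTAG", "CCTACGTACG"),
    exons = list(tibble::tibble(start = c(1L, 21L), end = c(10L, 30L))),
    quality = "confirmed",
    seed = 0L)
}

small_genes <- function() {
  if (is.null(.fixtures$small_genes))
    .fixtures$small_genes <- simulate_genes(60, seed = 11)
  .fixtures$small_genes
}

# a quickly trained W = 80 donor model plus its train/test split
tiny_fit <- function() {
  if (is.null(.fixtures$tiny_fit)) {
    ds <- assemble_dataset(small_genes(),
                           dataset_spec("GS_1", window_length = 80, seed = 3),
                           "donor")
    sp <- split_train_test(ds, 0.8, seed = 4)
    model <- build_model(model_config(input_length = 80, seed = 5), "donor")
    fit <- train_cnn(model, dplyr::filter(sp, partition == "train"),
                     train_config(epochs = 12, batch_size = 32,
                                  learning_rate = 2e-3, seed = 6))
    .fixtures$tiny_fit <- list(fit = fit,
                               train = dplyr::filter(sp, partition == "train"),
                               test = dplyr::filter(sp, partition == "test"))
  }
  .fixtures$tiny_fit
}

# Desk-scale study conditions shared by the learnability and interpretability
# acceptance checks: 800 genes, GS_1 strategy at W = 200, up to 3500 windows
# per class, 80/20 split, 50 epochs of Adamax at lr 1e-3.
acceptance_fit <- function(site_type) {
  key <- paste0("acc_", site_type)
  if (is.null(.fixtures[[key]])) {
    if (is.null(.fixtures$acc_genes))
      .fixtures$acc_genes <- simulate_genes(800, seed = 20260)
    ds <- assemble_dataset(.fixtures$acc_genes,
                           dataset_spec("GS_1", window_length = 200, seed = 17),
                           site_type)
    pos <- dplyr::filter(ds, label == 1)
    neg <- dplyr::filter(ds, label == 0)
    keep <- withr::with_seed(18, sort(sample.int(nrow(pos), min(3500, nrow(pos)))))
    ds <- dplyr::bind_rows(pos[keep, ], neg[keep, ])
    sp <- split_train_test(ds, 0.8, seed = 19)
    model <- build_model(model_config(input_length = 200, seed = 20), site_type)
    fit <- train_cnn(model, dplyr::filter(sp, partition == "train"),
                     train_config(epochs = 50, batch_size = 32,
                                  learning_rate = 1e-3, seed = 21))
    .fixtures[[key]] <- list(fit = fit,
                             train = dplyr::filter(sp, partition == "train"),
                             test = dplyr::filter(sp, partition == "test"))
  }
  .fixtures[[key]]
}

random_windows <- function(n, L, seed = 1, alphabet = c("A", "C", "G", "T")) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1)))
}
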