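# The convolutional classifier: architecture arithmetic, determinism,
# training behaviour, prediction contracts and persistence.

test_that("the default architecture at W = 200 has 144,222 parameters", {
  m <- build_model(model_config(input_length = 200, seed = 1), "donor")
  expect_equal(m$n_params, 144222)
  # layer-shape oracle: 200 -> 194 -> 97 -> 92 -> 46 -> 41 -> 20
  expect_equal(splicecnn:::shape_trace(200, c(7, 6, 6)),
               c(194L, 97L, 92L, 46L, 41L, 20L))
  # per-layer parameter sums: 464 + 3104 + 12352 + 128100 + 202
  expect_equal(sum(vapply(m$weights$conv_W, length, double(1))) +
                 sum(vapply(m$weights$conv_b, length, double(1))),
               464 + 3104 + 12352)
  expect_equal(length(m$weights$W1) + length(m$weights$b1), 128100)
  expect_equal(length(m$weights$W2) + length(m$weights$b2), 202)
})

test_that("short inputs fall back to a reduced stack; impossible ones error", {
  expect_warning(m20 <- build_model(model_config(input_length = 20, seed = 1)),
                 "dropping the last convolution block")
  expect_true(m20$reduced)
  expect_length(m20$kernels, 2)
  p <- predict_proba(m20, random_windows(4, 20, seed = 1))
  expect_equal(rowSums(as.matrix(p)), rep(1, 4), tolerance = 1e-9)
  expect_error(suppressWarnings(build_model(model_config(input_length = 8))),
               "too short")
})

test_that("weight initialisation and training are seed-deterministic", {
  a <- build_model(model_config(input_length = 80, seed = 42))
  b <- build_model(model_config(input_length = 80, seed = 42))
  c <- build_model(model_config(input_length = 80, seed = 43))
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights$W1, c$weights$W1))

  wins <- random_windows(60, 80, seed = 2)
  labels <- rep(c(0L, 1L), 30)
  tc <- train_config(epochs = 3, batch_size = 16, learning_rate = 1e-3, seed = 7)
  f1 <- train_cnn(a, encode_batch(wins, labels), tc)
  f2 <- train_cnn(b, encode_batch(wins, labels), tc)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("probability rows are normalised and inference is bit-stable", {
  fit <- tiny_fit()$fit
  w <- tiny_fit()$test$window[1]
  p5 <- predict_proba(fit, rep(w, 5))
  expect_equal(rowSums(as.matrix(p5)), rep(1, 5), tolerance = 1e-9)
  expect_equal(as.matrix(p5), as.matrix(p5)[rep(1, 5), ], ignore_attr = TRUE)
  # dropout disabled at inference: repeated calls identical
  expect_identical(as.matrix(predict_proba(fit, w)),
                   as.matrix(predict_proba(fit, w)))
})

test_that("training improves the loss and rejects degenerate inputs", {
  fit <- tiny_fit()$fit
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
  m <- build_model(model_config(input_length = 80, seed = 1))
  one_class <- encode_batch(random_windows(20, 80, seed = 3), rep(1L, 20))
  expect_error(train_cnn(m, one_class), "both classes")
  expect_error(train_config(epochs = 0), "positive integer")
  expect_error(train_cnn(m, encode_batch(random_windows(20, 40, seed = 3),
                                         rep(c(0L, 1L), 10))),
               "does not match")
})

test_that("a trained model separates planted sites from background", {
  tf <- tiny_fit()
  te <- tf$test
  p <- predict_proba(tf$fit, te)
  expect_gt(mean(p$p_ss[te$label == 1]), mean(p$p_ss[te$label == 0]))
})

test_that("classification uses a strict threshold with ties called non-SS", {
  probs <- tibble::tibble(p_non_ss = c(0.8, 0.5, 0.2),
                          p_ss = c(0.2, 0.5, 0.8))
  expect_equal(classify(probs), c(0L, 0L, 1L))
  expect_equal(classify(matrix(c(0.2, 0.8), 1)), 1L)
  # monotonicity: raising the threshold can only turn 1s into 0s
  p_ss <- withr::with_seed(1, runif(200))
  prev <- classify(p_ss, 0)
  for (thr in seq(0.1, 1, by = 0.1)) {
    cur <- classify(p_ss, thr)
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("length adaptation crops or N-pads symmetrically", {
  w600 <- paste0(strrep("A", 300), "GT", strrep("C", 298))
  a <- adapt_length(w600, 200)
  expect_equal(substr(a, 101, 102), "GT")
  expect_identical(adapt_length("ACGTACGT", 8), "ACGTACGT")
  expect_equal(adapt_length("ACGTACGT", 12), "NNACGTACGTNN")
  expect_error(adapt_length("ACGTACGT", 7), "even")
  # padded windows one-hot to all-zero channels and still predict
  fit <- tiny_fit()$fit
  p <- predict_proba(fit, adapt_length(random_windows(3, 60, seed = 4), 80))
  expect_equal(rowSums(as.matrix(p)), rep(1, 3), tolerance = 1e-9)
})

test_that("saved models reload with bit-identical predictions", {
  tf <- tiny_fit()
  dir <- withr::local_tempdir()
  save_model(tf$fit, dir)
  expect_true(all(file.exists(file.path(dir, c("config.json", "weights.json",
                                               "training_history.tsv")))))
  back <- load_model(dir)
  expect_equal(back$n_params, tf$fit$n_params)
  expect_equal(back$site_type, "donor")
  w <- tf$test$window[1:10]
  expect_identical(as.matrix(predict_proba(tf$fit, w)),
                   as.matrix(predict_proba(back, w)))
})

test_that("sequence scanning reports per-position probabilities", {
  tf <- tiny_fit()
  g <- small_genes()[1, ]
  scan <- scan_sequence(tf$fit, g$sequence, step = 25)
  expect_true(all(scan$p_ss >= 0 & scan$p_ss <= 1))
  expect_equal(scan$dinucleotide,
               substring(g$sequence, scan$center, scan$center + 1))
  expect_error(scan_sequence(tf$fit, substr(g$sequence, 1, 50)), "shorter")
})
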