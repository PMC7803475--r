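test_that("pearson_cor matches the closed-form definition", {
  expect_equal(pearson_cor(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), -c(1, 2, 3)), -1)
  # hand-computed from covariance / (sd_x sd_y) for (1,2,3) vs (1,2,4)
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y), want, tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1), c(1, 2)), "predicted")
  expect_error(pearson_cor(c(1, 2), c(1, 1)), "gold")
  expect_error(pearson_cor(1, 1), "at least two")
})

test_that("pearson_cor is exactly affine-invariant", {
  set.seed(4)
  x <- rnorm(50)
  for (a in c(0.5, 2, 10)) {
    expect_equal(pearson_cor(x, a * x + 3), 1, tolerance = 1e-9)
    expect_equal(pearson_cor(x, -a * x + 3), -1, tolerance = 1e-9)
  }
})

test_that("folds partition the corpus into near-equal parts deterministically", {
  f <- make_folds(10, 5, seed = 2)
  expect_length(f, 5L)
  expect_equal(unname(lengths(f)), rep(2L, 5))
  expect_equal(sort(unname(unlist(f))), 1:10)
  expect_identical(f, make_folds(10, 5, seed = 2))
  f2 <- make_folds(11, 3, seed = 2)
  expect_equal(sort(unname(unlist(f2))), 1:11)
  expect_true(all(abs(lengths(f2) - 11 / 3) < 1))
  expect_error(make_folds(10, 1), "at least 2")
  expect_error(make_folds(3, 5), "smaller")
})

test_that("score_histogram counts the six similarity intervals", {
  h <- score_histogram(data.frame(g_score = rep(2.5, 7)))
  expect_equal(sum(h), 7L)
  expect_equal(unname(h["[2.5,3.5)"]), 7L)
  expect_equal(sum(score_histogram(data.frame(g_score = numeric()))), 0L)
  h2 <- score_histogram(data.frame(g_score = c(0, 0.49, 0.5, 4.5, 5)))
  expect_equal(unname(h2), c(2L, 1L, 0L, 0L, 0L, 2L))
})

test_that("training runs the configured epochs, logs loss, and is deterministic", {
  b <- tiny_bundle(n_pairs = 8, seed = 51)
  cfg <- tiny_cfg()
  tc <- train_config(lr = 0.01, epochs = 12, batch_size = 4, seed = 51)
  m1 <- train_sts(sts_model(b$pairs, b$lexicon, b$kg, cfg, seed = 51),
                  b$pairs, tc)
  expect_equal(nrow(m1$train_log), 12L)
  m2 <- train_sts(sts_model(b$pairs, b$lexicon, b$kg, cfg, seed = 51),
                  b$pairs, tc)
  expect_identical(m1$train_log$loss, m2$train_log$loss)
  # learning: final loss below initial on this small corpus
  expect_lt(m1$train_log$loss[12], m1$train_log$loss[1])
  unlabeled <- b$pairs[, c("pair_id", "snippet_a", "snippet_b")]
  expect_error(train_sts(m1, unlabeled, tc), "labeled")
})

test_that("cross-validation reports per-fold and mean correlation", {
  b <- tiny_bundle(n_pairs = 10, seed = 61)
  # tiny folds can have constant gold scores; those report NA with a warning
  cv <- suppressWarnings(
    crossvalidate(b$pairs, b$lexicon, b$kg, k = 5, config = tiny_cfg(),
                  train = train_config(lr = 0.01, epochs = 2,
                                       batch_size = 8, seed = 61)))
  expect_length(cv$fold_pcc, 5L)
  expect_equal(cv$mean_pcc, mean(cv$fold_pcc))
  expect_equal(sort(unname(unlist(cv$folds))), 1:10)
  expect_true(all(abs(cv$fold_pcc) <= 1 | is.na(cv$fold_pcc)))
})

test_that("evaluation clips predictions and reports correlation in range", {
  b <- tiny_bundle(n_pairs = 8, seed = 71)
  m <- train_sts(sts_model(b$pairs, b$lexicon, b$kg, tiny_cfg(), seed = 71),
                 b$pairs,
                 train_config(lr = 0.01, epochs = 5, batch_size = 8, seed = 71))
  ev <- evaluate_sts(m, b$pairs)
  expect_true(ev$pcc >= -1 && ev$pcc <= 1)
  expect_true(all(ev$predictions$p_score >= 0 & ev$predictions$p_score <= 5))
  expect_equal(nrow(ev$predictions), 8L)
})
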