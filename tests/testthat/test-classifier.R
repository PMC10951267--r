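toy_feature_matrix <- function(X, labels, representation = "time") {
  structure(
    list(
      features = as.matrix(X), labels = factor(labels),
      representation = representation
    ),
    class = "feature_matrix"
  )
}

test_that("a perfectly separable single feature stops at step 1 with 100%", {
  X <- cbind(rep(c(0, 10, 20, 30), each = 4) + rnorm(16, sd = 0.1), rnorm(16))
  fm <- toy_feature_matrix(X, rep(1:4, each = 4))
  res <- stepwise_svm_loo(fm, stop_accuracy = 90)
  expect_equal(res$best_accuracy, 100)
  expect_equal(res$best_n_features, 1)
  expect_equal(res$stopped_at, 1)
  expect_equal(res$selected_features[1], 1)
})

test_that("shuffled labels perform at chance on average", {
  # best-over-steps accuracy on pure noise: LOO is pessimistically biased
  # (the held-out class is underrepresented in training) while taking the
  # best step is optimistically biased; at this toy size the permutation
  # null sits within binomial noise of the 25% chance rate
  set.seed(8)
  X <- matrix(rnorm(64 * 4), 64, 4)
  accs <- vapply(seq_len(50), function(r) {
    set.seed(100 + r)
    fm <- toy_feature_matrix(X, sample(rep(1:4, each = 16)))
    stepwise_svm_loo(fm, max_steps = 4)$best_accuracy
  }, numeric(1))
  expect_gt(mean(accs), 20)
  expect_lt(mean(accs), 30)
})

test_that("in-fold ranking is available and runs end to end", {
  set.seed(9)
  X <- cbind(rep(c(0, 3, 6, 9), each = 4) + rnorm(16), matrix(rnorm(16 * 3), 16, 3))
  fm <- toy_feature_matrix(X, rep(1:4, each = 4))
  res_global <- stepwise_svm_loo(fm, max_steps = 2)
  res_fold <- stepwise_svm_loo(fm, max_steps = 2, rank_in_fold = TRUE)
  expect_s3_class(res_fold, "classifier_result")
  expect_length(res_fold$accuracy_by_step, res_fold$stopped_at)
  expect_true(is.numeric(res_global$best_accuracy))
})

test_that("too few rows or single-condition folds are rejected", {
  fm <- toy_feature_matrix(matrix(rnorm(4), 4, 1), c(1, 2, 3, 4))
  expect_error(stepwise_svm_loo(fm), "at least 8 rows")
  fm2 <- toy_feature_matrix(matrix(rnorm(8), 8, 1), c(1, 1, 1, 1, 1, 1, 1, 2))
  expect_error(stepwise_svm_loo(fm2), "2 rows per condition")
})

test_that("the exact binomial tail matches closed forms and direct summation", {
  expect_equal(binomial_vs_chance(64, 64), 0.25^64)
  expect_lt(binomial_vs_chance(27, 64), 0.005) # 42.2% of 64 rows
  # direct tail-sum oracle
  k <- 16
  n <- 64
  direct <- sum(choose(n, k:n) * 0.25^(k:n) * 0.75^(n - (k:n)))
  expect_equal(binomial_vs_chance(k, n), direct, tolerance = 1e-12)
  expect_gt(binomial_vs_chance(k, n), 0.4)
  expect_error(binomial_vs_chance(70, 64), "invalid")
})

test_that("tidy and glance expose the accuracy trajectory and headline numbers", {
  X <- cbind(rep(c(0, 10, 20, 30), each = 4), rnorm(16))
  fm <- toy_feature_matrix(X, rep(1:4, each = 4), representation = "tf")
  res <- stepwise_svm_loo(fm)
  td <- tidy(res)
  expect_named(td, c("step", "n_features", "accuracy_pct"))
  gl <- glance(res)
  expect_equal(gl$representation, "tf")
  expect_equal(gl$best_accuracy_pct, res$best_accuracy)
})
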