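test_that("equal condition means give all-zero, omitted signatures", {
  set.seed(1)
  base <- rnorm(8)
  X <- matrix(rep(base, each = 8), 8, 8) + 0 # identical columns per row-block
  # construct: every condition has the same mean per feature but nonzero
  # within-condition spread
  X <- rbind(
    matrix(c(1, -1), 2, 4), matrix(c(1, -1), 2, 4),
    matrix(c(1, -1), 2, 4), matrix(c(1, -1), 2, 4)
  )
  fm <- structure(
    list(
      features = X, labels = factor(rep(1:4, each = 2)),
      representation = "time"
    ),
    class = "feature_matrix"
  )
  sig <- condition_signature(fm, selected_features = 1:4)
  expect_true(all(sig$signature == 0))
  expect_true(all(sig$omitted))
})

test_that("the largest-magnitude cell anchors the scale at +/-1 with full contrast", {
  set.seed(2)
  X <- matrix(rnorm(16 * 6), 16, 6)
  X[1:4, 3] <- X[1:4, 3] + 10 # condition 1 dominates feature 3
  fm <- structure(
    list(
      features = X, labels = factor(rep(1:4, each = 4)),
      representation = "time"
    ),
    class = "feature_matrix"
  )
  sig <- condition_signature(fm, selected_features = 1:6)
  expect_equal(max(abs(sig$signature)), 1)
  top <- sig[abs(sig$signature) == 1, ]
  expect_equal(top$feature, 3)
  expect_equal(top$condition, 1)
  expect_equal(top$signature, 1) # condition mean above the grand mean
  expect_equal(top$display_contrast, 1)
  # signature sign follows the direction of the condition-mean deviation
  f3 <- sig[sig$feature == 3 & sig$condition != 1, ]
  expect_true(all(f3$signature <= 0))
})

test_that("weak signatures are floored at 30% display contrast", {
  sig <- tibble::tibble(signature = c(0.001, -0.0005))
  dc <- pmax(0.3, 1 - 0.7 * (1 - abs(sig$signature)))
  expect_equal(dc, c(0.3007, 0.30035))
  # through the real path: tiny deviations against a dominant cell
  set.seed(3)
  X <- matrix(rnorm(16 * 2, sd = 1), 16, 2)
  X[1:4, 1] <- X[1:4, 1] + 100
  fm <- structure(
    list(
      features = X, labels = factor(rep(1:4, each = 4)),
      representation = "time"
    ),
    class = "feature_matrix"
  )
  s <- condition_signature(fm, selected_features = 1:2)
  weak <- s[s$feature == 2, ]
  expect_true(all(weak$display_contrast >= 0.3))
  expect_true(any(weak$display_contrast < 0.31))
})

test_that("zero error variance and empty selections are rejected", {
  X <- matrix(rep(1:4, each = 4), 16, 1)
  fm <- structure(
    list(
      features = X, labels = factor(rep(1:4, each = 4)),
      representation = "time"
    ),
    class = "feature_matrix"
  )
  expect_error(condition_signature(fm, 1), "zero error variance")
  expect_error(condition_signature(fm, integer(0)), "non-empty")
})
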