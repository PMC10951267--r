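fake_ci_set <- function(n_participants = 16, domain = "time", f = NULL, seed = 1) {
  set.seed(seed)
  d <- if (domain == "time") c(1, 24) else c(11, 24)
  out <- list()
  for (p in seq_len(n_participants)) {
    for (cc in 1:4) {
      v <- if (is.null(f)) matrix(rnorm(prod(d)), d[1], d[2]) else f(p, cc, d)
      if (domain != "time") rownames(v) <- seq(5, 55, 5)
      out[[length(out) + 1]] <- structure(
        list(values = v, domain = domain, participant_id = p, condition = cc),
        class = "zci"
      )
    }
  }
  structure(out, class = "ci_set", domain = domain)
}

test_that("the four representations have the pinned feature counts", {
  time_set <- fake_ci_set(16, "time")
  tf_set <- fake_ci_set(16, "time_frequency")
  expect_equal(dim(featureize(time_set, "time")$features), c(64L, 24L))
  expect_equal(dim(featureize(time_set, "time_fourier")$features), c(64L, 144L))
  expect_equal(dim(featureize(tf_set, "tf")$features), c(64L, 264L))
  expect_equal(dim(featureize(tf_set, "tf_fourier")$features), c(64L, 1584L))
})

test_that("representations are matched to the CI domain they need", {
  time_set <- fake_ci_set(4, "time")
  expect_error(featureize(time_set, "tf"), "needs time_frequency")
})

test_that("identical CIs leave zero between-condition variance everywhere", {
  const <- function(p, cc, d) matrix(seq_len(prod(d)) / prod(d), d[1], d[2])
  fm <- featureize(fake_ci_set(4, "time", f = const), "time_fourier")
  d <- temposample:::discrimination_index(fm$features, fm$labels)
  expect_true(all(d == 0))
})

test_that("the discrimination index matches hand computations and an independent oracle", {
  # two-condition toy: means 0 vs 1, within-SD exactly 1
  x <- c(-1, 0, 1, 0, 1, 2)
  lab <- factor(c(1, 1, 1, 2, 2, 2))
  d <- temposample:::discrimination_index(matrix(x, ncol = 1), lab)
  # condition means 0 and 1, within-variance 1: D = Var({0, 1}) / 1 = 0.25
  expect_equal(d, 0.25)
  # constant feature ranks last with index 0
  m <- cbind(x, rep(3, 6))
  rk <- discrimination_ranking(m, lab)
  expect_equal(rk$feature[2], 2)
  expect_equal(rk$d_index[2], 0)
  # brute-force oracle on a random matrix: per-column one-way variance ratio
  set.seed(4)
  M <- matrix(rnorm(64 * 24), 64, 24)
  labs <- factor(rep(1:4, each = 16))
  oracle <- apply(M, 2, function(col) {
    mns <- tapply(col, labs, mean)
    wv <- sum(tapply(col, labs, function(g) sum((g - mean(g))^2))) / (64 - 4)
    sum((mns - mean(mns))^2) / length(mns) / wv
  })
  mine <- temposample:::discrimination_index(M, labs)
  expect_equal(mine, oracle, tolerance = 1e-12)
  expect_equal(
    discrimination_ranking(M, labs)$feature,
    order(-oracle, seq_along(oracle))
  )
})

test_that("the index is invariant to column shifts and positive scaling", {
  set.seed(5)
  M <- matrix(rnorm(32 * 6), 32, 6)
  labs <- factor(rep(1:4, each = 8))
  d0 <- temposample:::discrimination_index(M, labs)
  M2 <- sweep(M, 2, c(5, -3, 0, 100, 2, 1), "+")
  expect_equal(temposample:::discrimination_index(M2, labs), d0, tolerance = 1e-9)
  M3 <- M
  M3[, 2] <- 7 * M[, 2]
  expect_equal(temposample:::discrimination_index(M3, labs), d0, tolerance = 1e-9)
})

test_that("zero within-condition variance with separated means ranks first", {
  m <- cbind(rep(1:4, each = 4), rnorm(16))
  rk <- discrimination_ranking(m, factor(rep(1:4, each = 4)))
  expect_equal(rk$feature[1], 1)
  expect_equal(rk$d_index[1], Inf)
})
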