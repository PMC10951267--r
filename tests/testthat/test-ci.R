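test_that("the time-domain CI equals the brute-force class-mean difference", {
  rows <- random_snr_rows(6, seed0 = 10)
  correct <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  log <- toy_trial_log(rows, correct)
  ci <- compute_time_ci(log)
  S <- do.call(rbind, rows)
  brute <- colMeans(S[correct, ]) - colMeans(S[!correct, ])
  expect_equal(as.numeric(ci$values), brute, tolerance = 1e-12)
  expect_equal(dim(ci$values), c(1L, 24L))
  expect_equal(ci$n_correct, 3)
  expect_equal(ci$n_error, 3)
})

test_that("equal-count classes with functions a and b give exactly a - b", {
  a <- as.numeric(generate_snr_function(1))
  b <- as.numeric(generate_snr_function(2))
  log <- toy_trial_log(list(a, a, b, b), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.numeric(compute_time_ci(log)$values), a - b, tolerance = 1e-12)
  # identical correct and error sets cancel exactly
  log2 <- toy_trial_log(list(a, b, a, b), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.numeric(compute_time_ci(log2)$values), rep(0, 24), tolerance = 1e-14)
  expect_equal(as.numeric(compute_tf_ci(log2)$values), rep(0, 264), tolerance = 1e-12)
})

test_that("an empty response class is a named error", {
  log <- toy_trial_log(random_snr_rows(3), c(TRUE, TRUE, TRUE))
  expect_error(compute_time_ci(log), "error trials")
})

test_that("the Morlet map has the pinned shape and frequency selectivity", {
  p <- morlet_tf_power(generate_snr_function(1))
  expect_equal(dim(p), c(11L, 24L))
  expect_equal(as.numeric(rownames(p)), seq(5, 55, 5))
  # a pure 20 Hz cosine peaks in the 20 Hz row for interior frames
  s <- cos(2 * pi * 20 * (0:23) / 120)
  ps <- morlet_tf_power(s)
  expect_true(all(apply(ps[, 8:17], 2, which.max) == 4))
  expect_equal(morlet_tf_power(rep(0, 24)), matrix(0, 11, 24), ignore_attr = TRUE)
})

test_that("Morlet power is quadratic under scaling", {
  x <- as.numeric(generate_snr_function(4))
  p1 <- morlet_tf_power(x)
  p3 <- morlet_tf_power(3 * x)
  expect_lt(max(abs(p3 - 9 * p1)) / max(p1), 1e-9)
})

test_that("a concentrated tf kernel is recovered at the right cell", {
  tfk <- replicate(4, matrix(0, 11, 24, dimnames = list(seq(5, 55, 5), NULL)),
    simplify = FALSE
  )
  k <- matrix(0, 11, 24, dimnames = list(seq(5, 55, 5), NULL))
  k[4, 8:12] <- 3 # 20 Hz, frames 8-12
  tfk[[1]] <- 25 * k / sqrt(sum(k^2))
  obs <- observer_model(matrix(0, 24, 4), tfk, slope = 24, criterion = 0.08)
  rows <- random_snr_rows(2000, seed0 = 100)
  set.seed(6)
  correct <- vapply(rows, function(s) {
    runif(1) < observer_p_correct(obs, 1, s, 35)
  }, logical(1))
  ci <- compute_tf_ci(toy_trial_log(rows, correct))
  z <- smooth_ci(bootstrap_z(ci, toy_trial_log(rows, correct), n_boot = 300, seed = 7))
  peak <- which(z$values == max(z$values), arr.ind = TRUE)
  expect_lte(abs(peak[1] - 4), 1)
  expect_lte(abs(peak[2] - 10), 3)
})

test_that("bootstrap z-scoring is calibrated under an uninformative labeling", {
  # z across cells and replicates should be ~N(0,1)
  zs <- unlist(lapply(seq_len(200), function(r) {
    rows <- random_snr_rows(40, seed0 = r * 1000)
    set.seed(r)
    correct <- runif(40) < 0.5
    if (all(correct) || !any(correct)) correct[1] <- !correct[1]
    log <- toy_trial_log(rows, correct)
    z <- bootstrap_z(compute_time_ci(log), log, n_boot = 300, seed = r)
    as.numeric(z$values)
  }))
  expect_lt(abs(mean(zs)), 0.05)
  expect_lt(abs(sd(zs) - 1), 0.1)
})

test_that("bootstrap z is seed-deterministic", {
  rows <- random_snr_rows(30, seed0 = 9)
  log <- toy_trial_log(rows, rep(c(TRUE, FALSE), 15))
  raw <- compute_time_ci(log)
  expect_identical(
    bootstrap_z(raw, log, n_boot = 200, seed = 5)$values,
    bootstrap_z(raw, log, n_boot = 200, seed = 5)$values
  )
})

test_that("Gaussian smoothing preserves constants and matches the closed form", {
  z <- structure(
    list(
      values = matrix(2.5, 1, 24), domain = "time",
      n_boot = 0, smoothing = NULL, provenance = "raw"
    ),
    class = "zci"
  )
  zs <- smooth_ci(z)
  expect_equal(as.numeric(zs$values), rep(2.5, 24), tolerance = 1e-12)
  # impulse response vs the normalized discrete Gaussian, sigma in frames
  imp <- z
  imp$values <- matrix(0, 1, 24)
  imp$values[1, 12] <- 1
  out <- as.numeric(smooth_ci(imp, fwhm_time_ms = 19.6)$values)
  sigma <- 19.6 / 2.355 / (1000 / 120)
  d <- (1:24) - 12
  ref <- exp(-d^2 / (2 * sigma^2))
  ref <- ref / sum(exp(-(-100:100)^2 / (2 * sigma^2)))
  keep <- abs(d) <= 4 # compare where the kernel has support
  expect_lt(max(abs(out[keep] - ref[keep]) / ref[keep]), 1e-3)
  expect_equal(zs$smoothing$fwhm_time_ms, 19.6)
})

test_that("tf smoothing defaults apply 29.3 ms x 17.7 Hz", {
  z <- structure(
    list(
      values = matrix(rnorm(264), 11, 24, dimnames = list(seq(5, 55, 5), NULL)),
      domain = "time_frequency", n_boot = 0, smoothing = NULL, provenance = "raw"
    ),
    class = "zci"
  )
  zs <- smooth_ci(z)
  expect_equal(zs$smoothing$fwhm_time_ms, 29.3)
  expect_equal(zs$smoothing$fwhm_freq_hz, 17.7)
})

test_that("averaging identical z maps is order-stable", {
  rows <- random_snr_rows(30, seed0 = 21)
  log <- toy_trial_log(rows, rep(c(TRUE, FALSE), 15))
  z <- bootstrap_z(compute_time_ci(log), log, n_boot = 200, seed = 2)
  cset <- structure(list(z, z, z), class = "ci_set", domain = "time")
  expect_equal(average_cis(cset)$values, z$values, tolerance = 1e-14)
})
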