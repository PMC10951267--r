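zero_observer <- function(criterion = 0, slope = 24, lapse = 0) {
  tk <- matrix(0, 24, 4)
  tfk <- replicate(4,
    {
      k <- matrix(0, 11, 24)
      rownames(k) <- seq(5, 55, 5)
      k
    },
    simplify = FALSE
  )
  observer_model(tk, tfk, slope = slope, criterion = criterion, lapse = lapse)
}

test_that("zero kernels give the closed-form guessing-plus-logistic probability", {
  obs <- zero_observer(criterion = 0)
  s <- generate_snr_function(1)
  expect_equal(observer_p_correct(obs, 1, s, 50), 0.25 + 0.75 * 0.5) # 0.625
  # with a lapse the ceiling drops accordingly
  obsl <- zero_observer(criterion = 0, lapse = 0.05)
  expect_equal(observer_p_correct(obsl, 1, s, 50), 0.25 + 0.70 * 0.5)
  # criterion -> infinity drives p to the guessing floor
  obs_inf <- zero_observer(criterion = 1e6)
  expect_equal(observer_p_correct(obs_inf, 1, s, 50), 0.25)
})

test_that("p is non-decreasing in contrast when the drive gradient is positive", {
  obs <- make_paperlike_observer(seed = 2)
  s <- generate_snr_function(3)
  p <- vapply(1:100, function(ct) observer_p_correct(obs, 2, s, ct), numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("responses are seeded Bernoulli draws with correct long-run rate", {
  expect_true(sample_response(1, seed = 1))
  expect_false(sample_response(0, seed = 1))
  expect_error(sample_response(1.2, seed = 1), "probability")
  draws <- vapply(seq_len(10000), function(i) sample_response(0.5, seed = i), logical(1))
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.5 / sqrt(10000))
})

test_that("the packaged observer has ordered, distinct, reproducible kernels", {
  obs <- make_paperlike_observer(seed = 5)
  peaks <- apply(obs$time_kernel, 2, which.max)
  expect_lt(peaks[4], peaks[1]) # highest SF condition peaks earliest
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_lt(cosim(obs$time_kernel[, i], obs$time_kernel[, j]), 0.9)
      expect_lt(cosim(
        as.numeric(obs$tf_kernel[[i]]),
        as.numeric(obs$tf_kernel[[j]])
      ), 0.9)
    }
  }
  expect_identical(
    make_paperlike_observer(seed = 5)$time_kernel,
    obs$time_kernel
  )
  # the tidy kernel table covers both domains for all conditions
  expect_equal(nrow(obs$kernel_table), 4 * 24 + 4 * 11 * 24)
})

test_that("observer models round-trip through JSON", {
  obs <- make_paperlike_observer(seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_observer_json(obs, path)
  back <- read_observer_json(path)
  expect_equal(back$time_kernel, obs$time_kernel, ignore_attr = TRUE)
  expect_equal(back$tf_kernel[[3]], obs$tf_kernel[[3]], ignore_attr = TRUE)
  expect_equal(back$slope, obs$slope)
  expect_equal(back$criterion, obs$criterion)
})
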