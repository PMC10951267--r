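test_that("word rendering honors the display metrics and is deterministic", {
  img <- render_word_image("achat", px_per_deg = 32)
  expect_equal(dim(img), c(285L, 285L)) # 8.9 deg x 32 px/deg
  m <- matrix(as.numeric(img), nrow(img))
  ink <- which(m < 0.5, arr.ind = TRUE)
  width_px <- diff(range(ink[, "col"])) + 1
  expect_equal(width_px, 3.4 * 32, tolerance = 0.1) # +/- 10% glyph tolerance
  expect_identical(
    as.numeric(render_word_image("bonte")),
    as.numeric(render_word_image("bonte"))
  )
})

test_that("rendering rejects malformed words", {
  expect_error(render_word_image("abcdef"), "5 letters")
  expect_error(render_word_image("ab1cd"), "unrenderable")
})

test_that("the condition table matches the paradigm's center/cutoff list", {
  fs <- filter_specs()
  expect_equal(fs$center_cpd, c(1.2, 2.4, 4.8, 9.6))
  expect_equal(fs$low_cpd, c(0.9, 1.8, 3.6, 7.2))
  expect_equal(fs$high_cpd, c(1.5, 3.0, 6.0, 12.0))
})

test_that("the filter's radial response has half power at the cutoffs", {
  # FFT of the impulse response is the oracle for the realized gain
  n <- 285
  imp <- matrix(0.5, n, n)
  imp[143, 143] <- 1
  imp <- luminance_image(imp, 32)
  spec <- filter_specs()[1, ]
  k <- butterworth_bandpass(imp, spec, clip = FALSE)
  gain <- Mod(fft(matrix(as.numeric(k), n) - mean(as.numeric(k)))) / 0.5
  f_axis <- (0:(n - 1)) / n * 32
  at <- function(f) gain[1, which.min(abs(f_axis[1:143] - f))]
  f_near <- function(f) f_axis[which.min(abs(f_axis[1:143] - f))]
  expect_equal(at(1.2), butterworth_gain(f_near(1.2), 0.9, 1.5), tolerance = 1e-6)
  expect_gt(at(1.2), 0.99)
  expect_equal(at(0.9)^2, butterworth_gain(f_near(0.9), 0.9, 1.5)^2, tolerance = 1e-6)
  expect_equal(butterworth_gain(0.9, 0.9, 1.5)^2, 0.5, tolerance = 1e-12)
  expect_equal(butterworth_gain(1.5, 0.9, 1.5)^2, 0.5, tolerance = 1e-12)
})

test_that("filtering twice equals one pass of the squared response", {
  n <- 64
  set.seed(5)
  img <- luminance_image(matrix(runif(n * n), n), 16)
  spec <- filter_specs()[2, ]
  twice <- butterworth_bandpass(butterworth_bandpass(img, spec, clip = FALSE), spec, clip = FALSE)
  # squared-response filter applied once, via the FFT oracle
  x <- matrix(as.numeric(img), n)
  fy <- temposample:::dft_freqs(n) * 16
  f <- sqrt(outer(fy^2, fy^2, `+`))
  g2 <- butterworth_gain(f, spec$low_cpd, spec$high_cpd, spec$order)^2
  ref <- Re(fft(fft(x - mean(x)) * g2, inverse = TRUE)) / n^2 + mean(x)
  expect_lt(max(abs(twice - ref)) / max(abs(ref)), 1e-6)
})

test_that("a uniform image passes through the filter unchanged", {
  u <- luminance_image(matrix(0.42, 64, 64), 32)
  expect_equal(
    as.numeric(butterworth_bandpass(u, filter_specs()[1, ])),
    rep(0.42, 64 * 64)
  )
})

test_that("a cutoff at or above the image Nyquist is rejected", {
  img <- luminance_image(matrix(0.5, 64, 64), 16) # Nyquist 8 cpd
  expect_error(butterworth_bandpass(img, filter_specs()[4, ]), "Nyquist")
})

test_that("noise fields are independent, seed-stable, and mid-gray on average", {
  a <- generate_noise_field(64, seed = 1)
  b <- generate_noise_field(64, seed = 2)
  expect_identical(as.numeric(a), as.numeric(generate_noise_field(64, seed = 1)))
  expect_lt(abs(cor(as.numeric(a), as.numeric(b))), 3 / sqrt(64 * 64))
  # uniform marginal: mean 0.5, sd 1/sqrt(12); three standard errors
  se <- 1 / sqrt(12) / sqrt(64 * 64)
  expect_lt(abs(mean(a) - 0.5), 3 * se)
})

test_that("stimulus frames are the pinned convex signal/noise mixture", {
  sig <- luminance_image(matrix(0.9, 8, 8), 32)
  noi <- luminance_image(matrix(0.1, 8, 8), 32)
  snr <- c(0, 0.75, rep(0.3, 22))
  mov <- compose_stimulus_movie(sig, noi, snr, contrast = 80)
  expect_length(mov$frames, 24)
  expect_equal(as.numeric(mov$frames[[1]]), as.numeric(noi))
  sig_c <- 0.5 + 0.8 * (0.9 - 0.5)
  expect_equal(
    as.numeric(mov$frames[[2]]),
    rep(0.75 * sig_c + 0.25 * 0.1, 64)
  )
  expect_error(
    compose_stimulus_movie(sig, luminance_image(matrix(0.1, 9, 9), 32), snr, 50),
    "shapes differ"
  )
})

test_that("RMS contrast of the scaled signal grows with nominal contrast", {
  img <- butterworth_bandpass(render_word_image("achat", px_per_deg = 16), filter_specs()[2, ])
  rms <- vapply(c(5, 20, 50, 90), function(ct) {
    sd(as.numeric(apply_contrast(img, ct)))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})
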