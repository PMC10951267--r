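# Trial-level feature matrices ------------------------------------------

trial_snr_matrix <- function(log) {
  do.call(rbind, log$snr_values)
}

# Morlet power maps for many trials at once: rows = trials, columns = the
# 11 x 24 map vectorized column-major (frequency fastest).
morlet_power_batch <- function(S, frame_rate = FRAME_RATE_HZ,
                               freqs = SNR_FREQS_HZ, n_cycles = 3) {
  W <- morlet_bank(ncol(S), frame_rate, freqs, n_cycles)
  P <- (W$re %*% t(S))^2 + (W$im %*% t(S))^2 # (n_freq*n_frames) x n_trials
  # rows of P are stacked frequency-major with frames fastest; reorder each
  # trial's map to column-major freq x frame (frequency fastest).
  n_f <- length(freqs)
  n_t <- ncol(S)
  idx <- as.integer(t(matrix(seq_len(n_f * n_t), nrow = n_t, ncol = n_f)))
  t(P[idx, , drop = FALSE])
}

trial_feature_matrix <- function(log, domain = c("time", "time_frequency")) {
  domain <- match.arg(domain)
  S <- trial_snr_matrix(log)
  if (domain == "time") S else morlet_power_batch(S)
}

ci_dims <- function(domain) {
  if (domain == "time") c(1L, N_FRAMES) else c(length(SNR_FREQS_HZ), N_FRAMES)
}

# Class-mean difference over a trial feature matrix.
ci_mean_difference <- function(X, correct, weighting = c("class_means", "pooled")) {
  weighting <- match.arg(weighting)
  n_c <- sum(correct)
  n_e <- sum(!correct)
  if (n_c == 0 || n_e == 0) {
    abort(paste0("cannot compute a classification image: no ", if (n_c == 0) "correct" else "error", " trials"))
  }
  if (weighting == "class_means") {
    colMeans(X[correct, , drop = FALSE]) - colMeans(X[!correct, , drop = FALSE])
  } else {
    # count-weighted pooled difference: sums scaled by the total trial count
    (colSums(X[correct, , drop = FALSE]) - colSums(X[!correct, , drop = FALSE])) / nrow(X)
  }
}

# Raw classification images ---------------------------------------------

#' Raw classification images from a trial log slice
#'
#' A classification image correlates trial-to-trial stimulus fluctuations
#' with response correctness. In the time domain it is the weighted
#' subtraction of the SNR sampling functions of error trials from those of
#' correct trials (each class weighted by its own trial count, i.e. a
#' difference of class means); in the time-frequency domain the same
#' subtraction is applied to the Morlet power maps of the sampling functions.
#'
#' @param log A `trial_log` slice for one participant and one condition
#'   (with at least one correct and one error trial).
#' @param weighting `"class_means"` (default) or `"pooled"`
#'   (count-weighted pooled difference).
#' @return A `raw_ci`: list with `values` (1 x 24 or 11 x 24 matrix),
#'   `domain`, `n_correct`, `n_error`, `participant_id`, `condition`.
#' @export
compute_time_ci <- function(log, weighting = "class_means") {
  compute_raw_ci(log, "time", weighting)
}

#' @rdname compute_time_ci
#' @export
compute_tf_ci <- function(log, weighting = "class_means") {
  compute_raw_ci(log, "time_frequency", weighting)
}

compute_raw_ci <- function(log, domain, weighting = "class_means") {
  X <- trial_feature_matrix(log, domain)
  v <- ci_mean_difference(X, log$correct, weighting)
  d <- ci_dims(domain)
  values <- matrix(v, d[1], d[2])
  if (domain == "time_frequency") rownames(values) <- SNR_FREQS_HZ
  structure(
    list(
      values = values, domain = domain,
      n_correct = sum(log$correct), n_error = sum(!log$correct),
      participant_id = unique(log$participant_id)[1],
      condition = unique(log$condition)[1]
    ),
    class = "raw_ci"
  )
}

# Bootstrap z-scoring ----------------------------------------------------

# Null distribution of the CI under label exchangeability: resample trials
# with replacement and assign class labels at random (class counts
# preserved). Returns elementwise null mean and SD (vectors over cells).
bootstrap_null_stats <- function(X, correct, n_boot, seed,
                                 weighting = "class_means") {
  n <- nrow(X)
  n_c <- sum(correct)
  n_e <- n - n_c
  Wmat <- with_seed_(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx_c <- sample.int(n, n_c, replace = TRUE)
      idx_e <- sample.int(n, n_e, replace = TRUE)
      if (weighting == "class_means") {
        tabulate(idx_c, n) / n_c - tabulate(idx_e, n) / n_e
      } else {
        (tabulate(idx_c, n) - tabulate(idx_e, n)) / n
      }
    }, numeric(n))
  })
  CI_b <- crossprod(X, Wmat) # cells x n_boot
  mu <- rowMeans(CI_b)
  sdev <- apply(CI_b, 1, stats::sd)
  list(mean = mu, sd = sdev)
}

#' Transform a raw CI into z scores by bootstrap
#'
#' Builds the null distribution of the CI by resampling trials with
#' replacement while assigning correct/error labels at random (class counts
#' preserved), recomputing the CI for each resample, and standardizing the
#' observed CI elementwise: `Z = (raw - null mean) / null SD`.
#'
#' @param raw A [compute_time_ci()] / [compute_tf_ci()] result.
#' @param log The same `trial_log` slice the raw CI came from.
#' @param n_boot Number of bootstrap resamples (default 1000, minimum 500
#'   recommended).
#' @param seed Integer seed.
#' @param weighting CI weighting convention, as in [compute_time_ci()].
#' @return A `zci`: `values` (z-unit matrix), `domain`, `n_boot`,
#'   `smoothing` (`NULL` until [smooth_ci()]), `null_mean`, `null_sd`,
#'   `participant_id`, `condition`, and `provenance`.
#' @export
bootstrap_z <- function(raw, log, n_boot = 1000, seed = 1,
                        weighting = "class_means") {
  stopifnot(inherits(raw, "raw_ci"), n_boot >= 2)
  X <- trial_feature_matrix(log, raw$domain)
  ns <- bootstrap_null_stats(X, log$correct, n_boot, seed, weighting)
  if (any(ns$sd <= 0)) {
    abort("degenerate bootstrap null: zero SD at one or more cells")
  }
  d <- dim(raw$values)
  z <- matrix((as.numeric(raw$values) - ns$mean) / ns$sd, d[1], d[2])
  rownames(z) <- rownames(raw$values)
  structure(
    list(
      values = z, domain = raw$domain, n_boot = n_boot,
      smoothing = NULL,
      null_mean = matrix(ns$mean, d[1], d[2]),
      null_sd = matrix(ns$sd, d[1], d[2]),
      participant_id = raw$participant_id, condition = raw$condition,
      provenance = c("raw", "bootstrap_z")
    ),
    class = "zci"
  )
}

# Gaussian smoothing ------------------------------------------------------

# Row-stochastic operator for reflective-boundary gaussian smoothing of a
# length-n series; sigma in sample units. Returns identity for sigma ~ 0.
smoothing_matrix_1d <- function(n, sigma) {
  if (sigma < 1e-8) {
    return(diag(n))
  }
  r <- ceiling(4 * sigma)
  kern <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-r:r)
    # reflect indices at the boundaries
    idx <- ifelse(idx < 1, 2 - idx, idx)
    idx <- ifelse(idx > n, 2 * n - idx, idx)
    for (j in seq_along(idx)) K[i, idx[j]] <- K[i, idx[j]] + kern[j]
  }
  K
}

FWHM_TO_SIGMA <- 1 / 2.355

#' Smooth a z-scored CI with a Gaussian filter
#'
#' FWHMs are given in stimulus units (ms on the time axis, Hz on the
#' frequency axis) and converted to cell units (one frame = 1000/120 ms, one
#' row = 5 Hz), with `sigma = FWHM / 2.355`. Boundaries are handled by
#' reflection and the kernel is normalized to unit sum, so constant maps are
#' unchanged. Defaults follow the paradigm: 19.6 ms for time-domain CIs,
#' 29.3 ms x 17.7 Hz for time-frequency CIs.
#'
#' @param z A `zci` (or `raw_ci`).
#' @param fwhm_time_ms FWHM along time, in ms.
#' @param fwhm_freq_hz FWHM along frequency, in Hz (ignored for time-domain
#'   CIs).
#' @param frame_rate Frames per second (default 120).
#' @param freq_step_hz Frequency row spacing in Hz (default 5).
#' @return The input object with smoothed `values` and `smoothing` metadata.
#' @export
smooth_ci <- function(z, fwhm_time_ms = if (z$domain == "time") 19.6 else 29.3,
                      fwhm_freq_hz = 17.7, frame_rate = FRAME_RATE_HZ,
                      freq_step_hz = 5) {
  stopifnot(fwhm_time_ms > 0)
  frame_ms <- 1000 / frame_rate
  sig_t <- fwhm_time_ms * FWHM_TO_SIGMA / frame_ms
  Kt <- smoothing_matrix_1d(ncol(z$values), sig_t)
  if (z$domain == "time") {
    z$values <- z$values %*% t(Kt)
    z$smoothing <- list(fwhm_time_ms = fwhm_time_ms, fwhm_freq_hz = NA_real_)
  } else {
    stopifnot(fwhm_freq_hz > 0)
    sig_f <- fwhm_freq_hz * FWHM_TO_SIGMA / freq_step_hz
    Kf <- smoothing_matrix_1d(nrow(z$values), sig_f)
    z$values <- Kf %*% z$values %*% t(Kt)
    rownames(z$values) <- SNR_FREQS_HZ
    z$smoothing <- list(fwhm_time_ms = fwhm_time_ms, fwhm_freq_hz = fwhm_freq_hz)
  }
  z$provenance <- c(z$provenance, "smooth")
  z
}

# Full smoothing operator on vectorized (column-major) maps; used by the
# pixel test to smooth many permutation maps at once.
smoothing_operator <- function(domain, fwhm_time_ms, fwhm_freq_hz,
                               frame_rate = FRAME_RATE_HZ, freq_step_hz = 5) {
  frame_ms <- 1000 / frame_rate
  Kt <- smoothing_matrix_1d(N_FRAMES, fwhm_time_ms * FWHM_TO_SIGMA / frame_ms)
  if (domain == "time") {
    Kt
  } else {
    Kf <- smoothing_matrix_1d(length(SNR_FREQS_HZ), fwhm_freq_hz * FWHM_TO_SIGMA / freq_step_hz)
    Kt %x% Kf
  }
}

# Cohort-level wrappers ---------------------------------------------------

#' Individual z-scored CIs for every participant x condition
#'
#' Splits a cohort trial log by participant and condition, computes the raw
#' CI of the requested domain for each slice, and bootstraps it into z
#' scores.
#'
#' @param trials A `trial_log` covering one or more participants.
#' @param domain `"time"` or `"time_frequency"`.
#' @param n_boot Bootstrap resamples per CI.
#' @param seed Master seed (one derived seed per slice).
#' @param weighting CI weighting convention.
#' @return A `ci_set`: list of `zci` objects, ordered by participant then
#'   condition.
#' @export
compute_individual_cis <- function(trials, domain = c("time", "time_frequency"),
                                   n_boot = 1000, seed = 1,
                                   weighting = "class_means") {
  domain <- match.arg(domain)
  keys <- unique(trials[, c("participant_id", "condition")])
  keys <- keys[order(keys$participant_id, keys$condition), ]
  out <- purrr::map(seq_len(nrow(keys)), function(i) {
    slice <- trials[trials$participant_id == keys$participant_id[i] &
      trials$condition == keys$condition[i], ]
    raw <- compute_raw_ci(slice, domain, weighting)
    bootstrap_z(raw, slice,
      n_boot = n_boot,
      seed = derive_seed(seed, 40000L + i), weighting = weighting
    )
  })
  structure(out, class = "ci_set", domain = domain)
}

#' Average z-scored CIs across participants
#'
#' Once individual CIs share the z scale they are averaged elementwise; the
#' group map is then smoothed and thresholded.
#'
#' @param ci_set A [compute_individual_cis()] result (or list of `zci`),
#'   typically filtered to one condition.
#' @return A `zci` with `participant_id = NA` and `n_participants` recorded.
#' @export
average_cis <- function(ci_set) {
  stopifnot(length(ci_set) >= 1)
  vals <- Reduce(`+`, lapply(ci_set, `[[`, "values")) / length(ci_set)
  z <- ci_set[[1]]
  z$values <- vals
  z$participant_id <- NA_integer_
  z$n_participants <- length(ci_set)
  z$condition <- unique(vapply(ci_set, `[[`, numeric(1), "condition"))
  z$provenance <- c(z$provenance, "group_average")
  z
}

#' @export
`[.ci_set` <- function(x, i) {
  structure(unclass(x)[i], class = "ci_set", domain = attr(x, "domain"))
}

#' Tidy a set of z-scored CIs into a long tibble
#'
#' @param x A `ci_set`.
#' @param ... Unused.
#' @return Tibble: `participant_id`, `condition`, `domain`, `freq_hz`,
#'   `frame`, `time_ms`, `z`.
#' @export
tidy.ci_set <- function(x, ...) {
  purrr::map_dfr(x, tidy.zci)
}

#' @rdname tidy.ci_set
#' @export
tidy.zci <- function(x, ...) {
  v <- x$values
  frame <- rep(seq_len(ncol(v)), each = nrow(v))
  tibble::tibble(
    participant_id = x$participant_id,
    condition = x$condition[1],
    domain = x$domain,
    freq_hz = if (x$domain == "time") NA_real_ else rep(as.numeric(rownames(v)), times = ncol(v)),
    frame = frame,
    time_ms = (frame - 0.5) * 1000 / FRAME_RATE_HZ,
    z = as.numeric(v)
  )
}
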