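#' Parametric synthetic observer
#'
#' The synthetic observer turns a trial's stimulus into a probability of a
#' correct 4AFC response. Its sensitivity is a condition-specific template
#' over the display: a temporal kernel (one weight per frame, applied to the
#' SNR trajectory) plus a time-frequency kernel (one weight per oscillation
#' frequency x frame, applied to the Morlet power map of the trajectory).
#' The internal drive is
#' `contrast/100 * (<time_kernel, snr> + <tf_kernel, morlet_power(snr)>)`
#' and the response probability follows a logistic psychometric function with
#' a 4AFC guessing floor:
#' `p = 1/4 + (3/4 - lapse) * plogis(slope * (drive - criterion))`.
#'
#' `make_paperlike_observer()` builds the packaged default: four gaussian-bump
#' kernel pairs with condition-specific temporal peaks ordered
#' high-to-low spatial frequency (condition 4 peaks earliest, condition 1
#' late) and distinct oscillation-frequency peaks, with the two intermediate
#' conditions given higher sensitivity so the adaptive staircase settles at
#' lower contrasts there. Slope and criterion defaults come from the packaged
#' calibration (see the methods vignette).
#'
#' @param time_kernel 24 x n_conditions matrix of temporal weights (columns =
#'   conditions).
#' @param tf_kernel List of n_conditions 11 x 24 matrices of time-frequency
#'   weights.
#' @param slope Logistic slope (1/drive units).
#' @param criterion Drive at the psychometric midpoint.
#' @param lapse Lapse rate in `[0, 0.1]`.
#' @param seed Integer seed recorded on the model.
#' @return An `observer_model` list; `$kernel_table` holds the ground-truth
#'   kernels in tidy form (`condition`, `domain`, `freq_hz`, `frame`,
#'   `weight`).
#' @export
observer_model <- function(time_kernel, tf_kernel, slope = 24, criterion = 0.33,
                           lapse = 0, seed = NA_integer_) {
  stopifnot(
    is.matrix(time_kernel), length(tf_kernel) == ncol(time_kernel),
    lapse >= 0, lapse <= 0.1,
    all(vapply(tf_kernel, function(k) all(is.finite(k)), logical(1))),
    all(is.finite(time_kernel))
  )
  m <- structure(
    list(
      time_kernel = time_kernel, tf_kernel = tf_kernel,
      slope = slope, criterion = criterion,
      guess_rate = 0.25, lapse = lapse, seed = seed
    ),
    class = "observer_model"
  )
  m$kernel_table <- observer_kernel_table(m)
  m
}

observer_kernel_table <- function(model) {
  n_cond <- ncol(model$time_kernel)
  tk <- purrr::map_dfr(seq_len(n_cond), function(c) {
    tibble::tibble(
      condition = c, domain = "time", freq_hz = NA_real_,
      frame = seq_len(nrow(model$time_kernel)),
      weight = model$time_kernel[, c]
    )
  })
  tfk <- purrr::map_dfr(seq_len(n_cond), function(c) {
    k <- model$tf_kernel[[c]]
    tibble::tibble(
      condition = c, domain = "time_frequency",
      freq_hz = rep(as.numeric(rownames(k)), times = ncol(k)),
      frame = rep(seq_len(ncol(k)), each = nrow(k)),
      weight = as.numeric(k)
    )
  })
  dplyr::bind_rows(tk, tfk)
}

gaussian_bump <- function(n, peak, sigma) {
  w <- exp(-((seq_len(n) - peak)^2) / (2 * sigma^2))
  w / sqrt(sum(w^2))
}

#' @rdname observer_model
#' @param tf_weight Relative weight of the time-frequency drive term (0
#'   zeroes it).
#' @param time_weight Relative weight of the temporal drive term (0 zeroes
#'   it).
#' @export
make_paperlike_observer <- function(seed = 1, slope = 24, criterion = 0.33,
                                    lapse = 0, time_weight = 1, tf_weight = 2.5) {
  n <- N_FRAMES
  freqs <- SNR_FREQS_HZ
  # Temporal peaks ordered high-SF-early / low-SF-late; intermediate
  # conditions get higher gain (they need less contrast, as in the paradigm's
  # sensitivity profile across spatial frequency).
  peaks_t <- c(14, 19, 8, 4) # conditions 1..4
  gains <- c(1, 1.5, 1.5, 1)
  time_kernel <- vapply(
    seq_len(4),
    function(c) time_weight * gains[c] * gaussian_bump(n, peaks_t[c], 2.5),
    numeric(n)
  )
  peaks_f <- c(2, 4, 7, 9) # rows of 5..55 Hz: 10, 20, 35, 45 Hz
  peaks_tf_t <- c(16, 18, 9, 5)
  tf_kernel <- lapply(seq_len(4), function(c) {
    k <- outer(
      gaussian_bump(length(freqs), peaks_f[c], 1),
      gaussian_bump(n, peaks_tf_t[c], 2.5)
    )
    k <- k / sqrt(sum(k^2))
    rownames(k) <- freqs
    tf_weight * gains[c] * k
  })
  observer_model(time_kernel, tf_kernel,
    slope = slope, criterion = criterion,
    lapse = lapse, seed = seed
  )
}

#' Probability of a correct response on one trial
#'
#' @param model An `observer_model`.
#' @param condition Condition index (column of the kernels).
#' @param snr SNR sampling function (numeric length 24).
#' @param contrast Target contrast in percent.
#' @return Probability in `[guess_rate, 1 - lapse]`.
#' @export
observer_p_correct <- function(model, condition, snr, contrast) {
  stopifnot(condition >= 1, condition <= ncol(model$time_kernel))
  x <- as.numeric(snr)
  drive_sig <- sum(model$time_kernel[, condition] * x)
  tfk <- model$tf_kernel[[condition]]
  if (any(tfk != 0)) {
    drive_sig <- drive_sig + sum(tfk * morlet_tf_power(x))
  }
  drive <- contrast / 100 * drive_sig
  model$guess_rate + (1 - model$guess_rate - model$lapse) *
    stats::plogis(model$slope * (drive - model$criterion))
}

#' Draw a Bernoulli response
#'
#' @param p Probability of success in `[0, 1]`.
#' @param seed Integer seed.
#' @return Logical.
#' @export
sample_response <- function(p, seed) {
  if (!is.finite(p) || p < 0 || p > 1) abort(sprintf("p = %s is not a probability", format(p)))
  with_seed_(seed, runif(1) < p)
}

#' Serialize / restore an observer model as JSON
#'
#' @param model An `observer_model`.
#' @param path File path.
#' @return `read_observer_json()` returns the restored `observer_model`.
#' @export
write_observer_json <- function(model, path) {
  obj <- list(
    time_kernel = model$time_kernel,
    tf_kernel = lapply(model$tf_kernel, unclass),
    tf_freqs = as.numeric(rownames(model$tf_kernel[[1]])),
    slope = model$slope, criterion = model$criterion,
    guess_rate = model$guess_rate, lapse = model$lapse, seed = model$seed,
    schema_version = 1L
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_observer_json
#' @export
read_observer_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- if (is.list(obj$tf_kernel)) {
    lapply(obj$tf_kernel, as.matrix)
  } else {
    lapply(seq_len(dim(obj$tf_kernel)[1]), function(i) obj$tf_kernel[i, , ])
  }
  tf <- lapply(tf, function(k) {
    rownames(k) <- obj$tf_freqs
    k
  })
  observer_model(obj$time_kernel, tf,
    slope = obj$slope, criterion = obj$criterion,
    lapse = obj$lapse, seed = obj$seed
  )
}
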