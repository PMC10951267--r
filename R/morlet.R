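#' Complex Morlet wavelet transform of a sampling function
#'
#' Convolves the 24-sample SNR trajectory with three-cycle complex Morlet
#' wavelets (complex exponential under a gaussian envelope, `sigma_t =
#' n_cycles / (2 pi f)`, unit-energy normalized) at 5 to 55 Hz in 5 Hz steps
#' and returns the squared magnitude at each frame: an 11 x 24 map of
#' time-localized oscillatory power. Zero padding is used at the edges; the
#' short 24-sample window means edge columns are attenuated, so frequency
#' selectivity should be read from interior columns.
#'
#' @param snr Numeric vector (length 24 at defaults) sampled at `frame_rate`.
#' @param frame_rate Sampling rate in Hz (default 120).
#' @param freqs Wavelet center frequencies in Hz.
#' @param n_cycles Gaussian envelope width in cycles (default 3).
#' @return Matrix `length(freqs)` x `length(snr)` of power, with `freqs` as
#'   rownames.
#' @export
#' @examples
#' p <- morlet_tf_power(generate_snr_function(1))
#' dim(p) # 11 x 24
morlet_tf_power <- function(snr, frame_rate = FRAME_RATE_HZ,
                            freqs = SNR_FREQS_HZ, n_cycles = 3) {
  x <- as.numeric(snr)
  W <- morlet_bank(length(x), frame_rate, freqs, n_cycles)
  p <- (W$re %*% x)^2 + (W$im %*% x)^2
  # p is stacked frequency-major with frames fastest: reshape to freq x frame
  out <- t(matrix(p, nrow = length(x), ncol = length(freqs)))
  rownames(out) <- freqs
  out
}

# Bank of convolution operators: for each frequency, a (n x n) matrix whose
# row t holds the conjugated wavelet centered on frame t (zero padding
# outside the window). Stacked into (n_freq * n) x n real and imaginary
# parts so a whole transform is two matrix-vector products. Memoized.
morlet_bank <- local({
  cache <- new.env(parent = emptyenv())
  function(n, frame_rate, freqs, n_cycles) {
    key <- paste(n, frame_rate, paste(freqs, collapse = ","), n_cycles)
    if (!is.null(cache[[key]])) {
      return(cache[[key]])
    }
    rows_re <- vector("list", length(freqs))
    rows_im <- vector("list", length(freqs))
    for (i in seq_along(freqs)) {
      f <- freqs[i]
      sigma_t <- n_cycles / (2 * pi * f)
      # lag grid in seconds, covering the full window
      lag <- outer(seq_len(n), seq_len(n), `-`) / frame_rate # t - tau
      env <- exp(-lag^2 / (2 * sigma_t^2))
      norm <- 1 / sqrt(sigma_t * sqrt(pi)) / sqrt(frame_rate) # unit energy
      rows_re[[i]] <- norm * env * cos(2 * pi * f * lag)
      rows_im[[i]] <- norm * env * sin(2 * pi * f * lag)
    }
    val <- list(re = do.call(rbind, rows_re), im = do.call(rbind, rows_im))
    cache[[key]] <- val
    val
  }
})
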