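#' Generate a random SNR sampling function
#'
#' The visibility of the target within the noise oscillates over the 200 ms
#' display according to a random sampling function: a sum of sinusoids at 5 to
#' 55 Hz in 5 Hz steps with random amplitudes and phases, sampled at the frame
#' rate and then normalized so that its minimum is 0 and its maximum is 0.75.
#' At the default 24 frames / 120 Hz, the component frequencies fall exactly on
#' DFT bins, so the pre-normalization waveform carries no spectral power at DC,
#' at the 60 Hz Nyquist bin, or anywhere outside the 5-55 Hz set.
#'
#' @param seed Integer seed; the function is deterministic given the seed.
#' @param n_frames Number of display frames (default 24).
#' @param frame_rate Display frame rate in Hz (default 120).
#' @param freqs Component frequencies in Hz (default 5 to 55 by 5).
#' @param snr_max Upper bound of the normalized range (default 0.75).
#' @param amplitudes,phases Optional fixed component amplitudes/phases
#'   (length of `freqs`), bypassing the random draw; used for controlled
#'   single-component inputs.
#' @return An object of class `snr_function`: a numeric vector of length
#'   `n_frames` spanning exactly `[0, snr_max]`, with attributes `seed`,
#'   `frame_rate`, `freqs`, and `raw` (the pre-normalization waveform).
#' @export
#' @examples
#' s <- generate_snr_function(seed = 1)
#' range(s) # 0 .. 0.75
generate_snr_function <- function(seed, n_frames = N_FRAMES,
                                  frame_rate = FRAME_RATE_HZ,
                                  freqs = SNR_FREQS_HZ, snr_max = SNR_MAX,
                                  amplitudes = NULL, phases = NULL) {
  stopifnot(n_frames >= 2, frame_rate > 0, all(freqs > 0), snr_max > 0)
  t <- (seq_len(n_frames) - 1) / frame_rate
  draw <- function(s) {
    with_seed_(s, list(
      amp = runif(length(freqs)),
      ph = runif(length(freqs), 0, 2 * pi)
    ))
  }
  if (is.null(amplitudes) || is.null(phases)) {
    d <- draw(seed)
    amp <- if (is.null(amplitudes)) d$amp else amplitudes
    ph <- if (is.null(phases)) d$ph else phases
    # Degenerate flat draw (all amplitudes ~ 0): normalization would divide by
    # ~0, so re-draw from an offset seed until the waveform has range.
    tries <- 0L
    while (diff(range(wave_sum(t, freqs, amp, ph))) < 1e-9 && tries < 100L) {
      tries <- tries + 1L
      d <- draw(derive_seed(seed, 7000L + tries))
      amp <- d$amp
      ph <- d$ph
    }
  } else {
    amp <- amplitudes
    ph <- phases
  }
  raw <- wave_sum(t, freqs, amp, ph)
  rng <- range(raw)
  if (diff(rng) < 1e-12) {
    abort("degenerate sampling waveform: zero range after re-draws")
  }
  values <- (raw - rng[1]) / diff(rng) * snr_max
  structure(values,
    class = "snr_function", seed = seed, frame_rate = frame_rate,
    freqs = freqs, raw = raw
  )
}

wave_sum <- function(t, freqs, amp, ph) {
  colSums(amp * sin(outer(2 * pi * freqs, t) + ph))
}

#' One-sided DFT power spectrum of a sampled waveform
#'
#' Power at each DFT bin frequency, with the two-sided spectrum folded so the
#' sum over all non-DC bins equals the waveform's mean-removed power
#' (Parseval). Used to check band purity of sampling functions and to build
#' Fourier feature grids.
#'
#' @param x Numeric vector sampled at `frame_rate`.
#' @param frame_rate Sampling rate in Hz.
#' @return A tibble with columns `freq_hz`, `power`, and `phase` (radians, of
#'   the positive-frequency component).
#' @export
dft_power_spectrum <- function(x, frame_rate = FRAME_RATE_HZ) {
  n <- length(x)
  X <- fft(as.numeric(x))
  k <- seq_len(floor(n / 2)) # positive frequencies up to Nyquist
  fold <- ifelse(k == n / 2, 1, 2) # Nyquist bin has no mirror
  tibble::tibble(
    freq_hz = k * frame_rate / n,
    power = fold * Mod(X[k + 1])^2 / n^2,
    phase = Arg(X[k + 1])
  )
}
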