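#' Recode a 24-sample time course as a frequency x phase power grid
#'
#' Takes the DFT of the series, discards DC, and assigns each positive
#' frequency's (folded, Parseval-consistent) power to the phase bin
#' containing its phase. With 24 samples at 120 Hz the positive frequencies
#' are 5 to 60 Hz in 5 Hz steps (12 of them) and phases are binned into 12
#' bins of 30 degrees covering [-180, 180): a 144-cell grid in which each
#' frequency occupies exactly one cell, so the grid total equals the series'
#' total non-DC spectral power.
#'
#' @param series Numeric vector (length 24 at defaults).
#' @param frame_rate Sampling rate in Hz.
#' @param n_phase_bins Number of phase bins (default 12).
#' @return A `fourier_feature_grid`: 12 x 12 matrix (rows = frequencies in
#'   Hz, columns = phase-bin lower edges in degrees).
#' @export
#' @examples
#' g <- fourier_feature_grid(generate_snr_function(1))
#' dim(g) # 12 x 12
fourier_feature_grid <- function(series, frame_rate = FRAME_RATE_HZ,
                                 n_phase_bins = 12) {
  x <- as.numeric(series)
  spec <- dft_power_spectrum(x, frame_rate)
  n_freq <- nrow(spec)
  bin_w <- 360 / n_phase_bins
  ph_deg <- spec$phase * 180 / pi
  ph_deg <- ((ph_deg + 180) %% 360) - 180 # wrap into [-180, 180)
  bin <- pmin(n_phase_bins, floor((ph_deg + 180) / bin_w) + 1L)
  g <- matrix(0, n_freq, n_phase_bins)
  g[cbind(seq_len(n_freq), bin)] <- spec$power
  dimnames(g) <- list(spec$freq_hz, seq(-180, 180 - bin_w, by = bin_w))
  structure(g, class = c("fourier_feature_grid", "matrix", "array"))
}
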