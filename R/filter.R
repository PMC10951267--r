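#' Spatial-frequency conditions of the paradigm
#'
#' The four band-pass conditions used for the word signal, as retinal
#' frequencies (cycles per degree) with half-power cutoffs, plus the
#' object-frequency equivalents in cycles per letter derived from the word
#' geometry.
#'
#' @param order Butterworth order attached to each spec (default 2).
#' @return A tibble with one row per condition: `condition`, `center_cpd`,
#'   `low_cpd`, `high_cpd`, `center_cpl`, `low_cpl`, `high_cpl`, `order`.
#' @export
#' @examples
#' filter_specs()
filter_specs <- function(order = 2) {
  tibble::tibble(
    condition = 1:4,
    center_cpd = c(1.2, 2.4, 4.8, 9.6),
    low_cpd = c(0.9, 1.8, 3.6, 7.2),
    high_cpd = c(1.5, 3.0, 6.0, 12.0),
    center_cpl = c(1.7, 3.5, 7.1, 14.1),
    low_cpl = c(1.3, 2.6, 5.3, 10.6),
    high_cpl = c(2.2, 4.4, 8.8, 17.6),
    order = as.integer(order)
  )
}

#' Band-pass Butterworth magnitude response
#'
#' Canonical analog band-pass Butterworth gain: unity near the band center
#' (the geometric mean of the cutoffs) and exactly half power at `low` and
#' `high`.
#'
#' @param f Radial spatial frequency (cycles/degree); vector or matrix.
#' @param low,high Half-power cutoff frequencies (cycles/degree).
#' @param order Filter order (steepness).
#' @return Gain values in `[0, 1]`, same shape as `f`; gain at `f = 0` is 0.
#' @export
butterworth_gain <- function(f, low, high, order = 2) {
  stopifnot(low > 0, high > low, order >= 1)
  f0sq <- low * high
  bw <- high - low
  g <- array(0, dim = if (is.null(dim(f))) length(f) else dim(f))
  nz <- f > 0
  x <- (f[nz]^2 - f0sq) / (f[nz] * bw)
  g[nz] <- 1 / sqrt(1 + x^(2 * order))
  if (is.null(dim(f))) as.numeric(g) else g
}

#' Apply a band-pass Butterworth spatial-frequency filter to an image
#'
#' Filters the image's deviation from its mean luminance in the Fourier
#' domain with a radially symmetric Butterworth band-pass response, then
#' restores the mean. Half-power points sit at the spec's cutoff frequencies
#' and the gain is ~1 at the center frequency. The DC component (mean
#' luminance) passes through unchanged.
#'
#' @param image A `luminance_image`.
#' @param spec One row of [filter_specs()], or a list with `low_cpd`,
#'   `high_cpd`, `order`.
#' @param clip Clip the filtered image into `[0, 1]` (default `TRUE`). Set
#'   `FALSE` to keep the operation exactly linear (e.g. for kernel
#'   inspection).
#' @return A `luminance_image` of the same size.
#' @export
#' @examples
#' img <- render_word_image("achat")
#' flt <- butterworth_bandpass(img, filter_specs()[1, ])
butterworth_bandpass <- function(image, spec, clip = TRUE) {
  ppd <- px_per_deg(image)
  low <- spec$low_cpd
  high <- spec$high_cpd
  ord <- if (!is.null(spec$order)) spec$order else 2
  nyq <- ppd / 2 # cycles/degree at the pixel Nyquist
  if (high >= nyq) {
    abort(sprintf("high cutoff (%.2f cpd) must be below the image Nyquist (%.2f cpd)", high, nyq))
  }
  x <- unclass(image)
  nr <- nrow(x)
  nc <- ncol(x)
  fy <- dft_freqs(nr) * ppd # cycles/degree along rows
  fx <- dft_freqs(nc) * ppd
  f <- sqrt(outer(fy^2, fx^2, `+`))
  g <- butterworth_gain(f, low, high, ord)
  mu <- mean(x)
  filt <- Re(fft(fft(x - mu) * g, inverse = TRUE)) / (nr * nc) + mu
  luminance_image(filt, px_per_deg = ppd, clip = clip)
}

# DFT bin frequencies in cycles/pixel, in fft output order (0, +, -).
dft_freqs <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k <= n / 2, k, k - n) / n
}
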