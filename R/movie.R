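#' Compose the 24-frame stimulus movie
#'
#' The displayed stimulus is a linear combination of the contrast-scaled
#' filtered word (signal) and the white-noise field, with the mixing weight
#' given frame-by-frame by the SNR sampling function:
#' `frame_t = s_t * signal_c + (1 - s_t) * noise`. Contrast scales the
#' signal's deviation from mean luminance (0.5), in percent of the maximum
#' displayable deviation, so `s_t = 0` shows pure noise and larger SNR shows
#' more of the word.
#'
#' @param signal A `luminance_image` (the filtered word).
#' @param noise A `luminance_image` of the same size.
#' @param snr An [generate_snr_function()] object (or numeric vector in
#'   `[0, 1]`).
#' @param contrast Target contrast in percent, in `[1, 100]`.
#' @return A `stimulus_movie`: list of frames (`luminance_image`s, clipped to
#'   `[0, 1]`) plus `snr` and `contrast`.
#' @export
compose_stimulus_movie <- function(signal, noise, snr, contrast) {
  if (!all(dim(signal) == dim(noise))) {
    abort(sprintf(
      "signal (%dx%d) and noise (%dx%d) shapes differ",
      nrow(signal), ncol(signal), nrow(noise), ncol(noise)
    ))
  }
  stopifnot(contrast >= 1, contrast <= 100)
  sig_c <- apply_contrast(signal, contrast)
  frames <- lapply(as.numeric(snr), function(s) {
    luminance_image(s * unclass(sig_c) + (1 - s) * unclass(noise),
      px_per_deg = px_per_deg(signal), clip = TRUE
    )
  })
  structure(list(frames = frames, snr = snr, contrast = contrast),
    class = "stimulus_movie"
  )
}

#' @rdname compose_stimulus_movie
#' @param image A `luminance_image`.
#' @export
apply_contrast <- function(image, contrast) {
  luminance_image(0.5 + (contrast / 100) * (unclass(image) - 0.5),
    px_per_deg = px_per_deg(image), clip = FALSE
  )
}
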