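#' Luminance images
#'
#' Stimulus-side images are plain numeric matrices of luminance in `[0, 1]`
#' carrying a `px_per_deg` attribute (pixels per degree of visual angle).
#' `luminance_image()` constructs one; `px_per_deg()` reads the scale.
#'
#' @param pixels Numeric matrix of luminance values.
#' @param px_per_deg Pixels per degree of visual angle.
#' @param clip Clip values into `[0, 1]` (default `TRUE`).
#' @return A `luminance_image`: a matrix with attribute `px_per_deg`.
#' @export
luminance_image <- function(pixels, px_per_deg = 32, clip = TRUE) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), px_per_deg > 0)
  if (clip) pixels <- pmin(pmax(pixels, 0), 1) # keep pixels first: pmin/pmax take attributes (dim) from it
  structure(pixels, px_per_deg = px_per_deg, class = c("luminance_image", class(pixels)))
}

#' @rdname luminance_image
#' @param image A `luminance_image` (or matrix with a `px_per_deg` attribute).
#' @export
px_per_deg <- function(image) {
  p <- attr(image, "px_per_deg")
  if (is.null(p)) abort("image carries no px_per_deg attribute")
  p
}

#' Write a luminance image as an 8-bit grayscale PNG
#'
#' For visual inspection only; the analysis operates on the float matrices.
#'
#' @param image A `luminance_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(unclass(image), 0), 1), target = path)
  invisible(path)
}

# Stimulation area: 8.9 x 8.9 deg square.
STIM_AREA_DEG <- 8.9

stim_area_px <- function(px_per_deg) as.integer(round(STIM_AREA_DEG * px_per_deg))
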