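#' Generate a white-noise luminance field
#'
#' Independent per-pixel luminances with a flat expected spatial spectrum. The
#' default marginal is uniform on `[0, 1]` (mean luminance 0.5); a truncated
#' gaussian centered on 0.5 is available as an alternative. A fresh field is
#' drawn for every trial by passing a fresh seed.
#'
#' @param n_px Side length in pixels (square field), e.g.
#'   `stim_area_px(px_per_deg)`.
#' @param seed Integer seed; identical seeds give identical fields.
#' @param dist Marginal distribution: `"uniform"` (default) or `"gaussian"`
#'   (mean 0.5, sd 0.15, truncated to `[0, 1]`).
#' @param px_per_deg Pixels per degree recorded on the output image.
#' @return A `luminance_image` of size `n_px` x `n_px`.
#' @export
generate_noise_field <- function(n_px, seed, dist = c("uniform", "gaussian"),
                                 px_per_deg = 32) {
  dist <- match.arg(dist)
  stopifnot(n_px >= 1)
  vals <- with_seed_(seed, switch(dist,
    uniform = runif(n_px * n_px),
    gaussian = pmin(1, pmax(0, rnorm(n_px * n_px, mean = 0.5, sd = 0.15)))
  ))
  luminance_image(matrix(vals, n_px, n_px), px_per_deg = px_per_deg, clip = FALSE)
}
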