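#' Derive a stream seed from a master seed
#'
#' All stochastic stages take an explicit integer seed. Stage seeds are derived
#' from a single master seed with a fixed linear-congruential splitting rule so
#' that a whole run is reproducible from one number and streams do not collide
#' for distinct stream ids.
#'
#' @param master Integer master seed.
#' @param stream Integer stream identifier (>= 0); distinct stages/trials use
#'   distinct streams.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(master, stream = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(stream))
  m <- 2147483647 # 2^31 - 1, prime modulus of the minimal standard generator
  x <- (abs(as.numeric(master)) %% m)
  for (k in c(as.numeric(stream) %% m, 12345)) {
    x <- (48271 * x + k) %% m
  }
  as.integer(max(1, x))
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
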