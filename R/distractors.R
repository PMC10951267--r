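#' Image cross-correlation between word images
#'
#' Zero-lag normalized correlation of mean-subtracted images (i.e. the
#' Pearson correlation of their vectorized pixels), used as the proxy for
#' visual similarity when choosing 4AFC distractors.
#'
#' @param image_bank Named list of `luminance_image`s (unfiltered word
#'   renderings), one per word.
#' @return Symmetric similarity matrix with word names on both dimensions.
#' @export
word_similarity_matrix <- function(image_bank) {
  stopifnot(length(image_bank) >= 2, !is.null(names(image_bank)))
  m <- vapply(image_bank, function(im) as.numeric(unclass(im)),
    numeric(length(image_bank[[1]]))
  )
  s <- stats::cor(m)
  dimnames(s) <- list(names(image_bank), names(image_bank))
  s
}

#' Assign three distractor words to every target
#'
#' Presets the three 4AFC response foils for each target word. The goal is to
#' maximize target-distractor visual similarity while keeping the summed
#' similarity (the trial's difficulty) as even as possible across targets, and
#' never using any word as a distractor for more than `max_reuse` distinct
#' targets. A two-pass heuristic is used: pass 1 greedily assigns each
#' target's most similar available words; pass 2 swaps single distractors to
#' shrink the across-target spread of summed similarity, always respecting
#' the reuse cap.
#'
#' @param image_bank Named list of `luminance_image`s, one per word (>= 4).
#' @param max_reuse Maximum number of distinct targets a word may serve as a
#'   distractor for (default 6; `Inf` disables the cap).
#' @param seed Integer seed controlling tie-breaking order.
#' @param similarity Optional precomputed similarity matrix
#'   ([word_similarity_matrix()]); computed from the bank when `NULL`.
#' @param n_sweeps Number of balancing sweeps in pass 2.
#' @return A tibble (`distractor_map`): `target`, `distractor_1..3`,
#'   `summed_similarity`.
#' @export
select_distractors <- function(image_bank, max_reuse = 6, seed = 1,
                               similarity = NULL, n_sweeps = 3) {
  words <- names(image_bank)
  n <- length(words)
  if (n < 4) abort("image bank must contain at least 4 words")
  # Feasibility: n targets need 3n distractor slots; each word can fill at
  # most max_reuse of them.
  if (is.finite(max_reuse) && n * max_reuse < 3 * n) {
    abort(sprintf("reuse cap %d cannot supply 3 distractors per target", max_reuse))
  }
  sim <- if (is.null(similarity)) word_similarity_matrix(image_bank) else similarity
  use_count <- stats::setNames(integer(n), words)
  assign <- vector("list", n)
  names(assign) <- words

  order_idx <- with_seed_(derive_seed(seed, 11L), sample.int(n))
  for (i in order_idx) {
    tgt <- words[i]
    cand <- words[order(sim[tgt, ], decreasing = TRUE)]
    cand <- cand[cand != tgt & use_count[cand] < max_reuse]
    if (length(cand) < 3) abort(sprintf("reuse cap too tight: target '%s' has <3 available distractors", tgt))
    pick <- cand[1:3]
    assign[[tgt]] <- pick
    use_count[pick] <- use_count[pick] + 1L
  }

  sums <- vapply(words, function(w) sum(sim[w, assign[[w]]]), numeric(1))
  # Pass 2: pull the most extreme targets toward the median summed
  # similarity by single-distractor swaps.
  for (sweep in seq_len(n_sweeps)) {
    med <- stats::median(sums)
    for (w in words[order(abs(sums - med), decreasing = TRUE)]) {
      cur <- assign[[w]]
      best <- list(dev = abs(sums[w] - med), out = NULL, into = NULL)
      cand <- words[words != w & !(words %in% cur) & use_count[words] < max_reuse]
      for (out in cur) {
        gain <- sim[w, cand] - sim[w, out]
        dev <- abs(sums[w] + gain - med)
        j <- which.min(dev)
        if (length(j) && dev[j] < best$dev - 1e-12) {
          best <- list(dev = dev[j], out = out, into = cand[j])
        }
      }
      if (!is.null(best$out)) {
        assign[[w]] <- c(setdiff(cur, best$out), best$into)
        use_count[best$out] <- use_count[best$out] - 1L
        use_count[best$into] <- use_count[best$into] + 1L
        sums[w] <- sum(sim[w, assign[[w]]])
      }
    }
  }

  out <- tibble::tibble(
    target = words,
    distractor_1 = vapply(assign, `[`, character(1), 1),
    distractor_2 = vapply(assign, `[`, character(1), 2),
    distractor_3 = vapply(assign, `[`, character(1), 3),
    summed_similarity = as.numeric(sums)
  )
  class(out) <- c("distractor_map", class(out))
  out
}
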