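#' Two-way Pixel test on a smoothed group CI
#'
#' Determines which cells of the smoothed, group-averaged z-scored CI differ
#' significantly from zero while controlling the family-wise error rate over
#' the whole search space at `alpha`. The null distribution is built by a
#' max-statistic permutation scheme: in each permutation the correct/error
#' labels of every participant's trials are re-assigned at random (class
#' counts preserved), the per-participant CI is recomputed and standardized
#' with that participant's bootstrap null moments, the maps are averaged and
#' smoothed exactly as the observed map was, and the maximum absolute z over
#' the map is recorded. The two-tailed threshold is the upper order statistic
#' of these maxima; cells at or beyond `+/- threshold` are flagged.
#'
#' @param group_z A smoothed group-average `zci` (from [average_cis()] +
#'   [smooth_ci()]); must carry smoothing metadata.
#' @param ci_set The individual `zci` objects that were averaged (their
#'   bootstrap null moments are reused).
#' @param trials The `trial_log` covering those individuals.
#' @param n_perm Number of label permutations (default 500).
#' @param alpha Family-wise error level (default 0.05).
#' @param seed Integer seed.
#' @param weighting CI weighting convention, as in [compute_time_ci()].
#' @return A `pixel_test_result`: `z_threshold_high`, `z_threshold_low`,
#'   `significance_mask`, `alpha`, `n_perm`, `search_space`, `smoothing`,
#'   `null_max` (the permutation maxima), and `mode = "max_stat_permutation"`.
#' @export
pixel_test <- function(group_z, ci_set, trials, n_perm = 500, alpha = 0.05,
                       seed = 1, weighting = "class_means") {
  if (is.null(group_z$smoothing)) {
    abort("pixel test requires a smoothed map: smoothing metadata is missing")
  }
  domain <- group_z$domain
  K <- smoothing_operator(
    domain, group_z$smoothing$fwhm_time_ms,
    group_z$smoothing$fwhm_freq_hz
  )
  n_cells <- length(group_z$values)

  # Per participant: trial feature matrix, class counts, null moments.
  parts <- lapply(ci_set, function(z) {
    slice <- trials[trials$participant_id == z$participant_id &
      trials$condition == z$condition, ]
    if (nrow(slice) == 0) {
      abort(sprintf("no trials for participant %s, condition %s", z$participant_id, z$condition))
    }
    list(
      X = trial_feature_matrix(slice, domain),
      n_c = sum(slice$correct), n_e = sum(!slice$correct),
      mu = as.numeric(z$null_mean), sd = as.numeric(z$null_sd)
    )
  })

  null_max <- with_seed_(derive_seed(seed, 61L), {
    acc <- matrix(0, n_cells, n_perm)
    for (p in parts) {
      n <- p$n_c + p$n_e
      Wmat <- vapply(seq_len(n_perm), function(b) {
        lab <- sample.int(n) <= p$n_c
        w <- ifelse(lab, 1 / p$n_c, -1 / p$n_e)
        if (weighting == "pooled") w <- ifelse(lab, 1, -1) / n
        w
      }, numeric(n))
      Zp <- (crossprod(p$X, Wmat) - p$mu) / p$sd
      acc <- acc + Zp
    }
    apply(abs(K %*% (acc / length(parts))), 2, max)
  })

  k <- ceiling((1 - alpha) * (n_perm + 1))
  if (k > n_perm) k <- n_perm
  thr <- sort(null_max)[k]
  mask <- group_z$values >= thr | group_z$values <= -thr
  structure(
    list(
      z_threshold_high = thr, z_threshold_low = -thr,
      significance_mask = mask, alpha = alpha, n_perm = n_perm,
      search_space = n_cells, smoothing = group_z$smoothing,
      null_max = null_max, mode = "max_stat_permutation"
    ),
    class = "pixel_test_result"
  )
}
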