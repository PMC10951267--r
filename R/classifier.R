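#' Stepwise linear-SVM classification with leave-one-out cross-validation
#'
#' Features are introduced one at a time in ranking order: at step k the SVM
#' sees the top-k features. At each step, accuracy is estimated by
#' leave-one-out cross-validation over individual CIs: the model is trained
#' on all rows but one (linear kernel, cost 1, features standardized on the
#' training fold) and predicts the held-out row's condition. The procedure
#' stops when accuracy reaches `stop_accuracy` percent or the features are
#' exhausted, whichever comes first.
#'
#' @param m A `feature_matrix` ([featureize()]).
#' @param ranking A [discrimination_ranking()] tibble; computed from `m` when
#'   `NULL`. Ignored when `rank_in_fold = TRUE`.
#' @param stop_accuracy Stop threshold in percent (default 90).
#' @param max_steps Optional cap on the number of steps (default: all
#'   features).
#' @param rank_in_fold Recompute the ranking inside every training fold
#'   (avoids selection leakage; default `FALSE`, matching a single global
#'   ranking).
#' @param cost SVM regularization constant (default 1).
#' @return A `classifier_result`: `accuracy_by_step` (%), `selected_features`
#'   (ordered, as used at the best step), `best_accuracy`, `best_n_features`,
#'   `p_value` (exact binomial vs 25% chance at the best step), `stopped_at`,
#'   `representation`, `n_rows`.
#' @export
stepwise_svm_loo <- function(m, ranking = NULL, stop_accuracy = 90,
                             max_steps = Inf, rank_in_fold = FALSE, cost = 1) {
  stopifnot(inherits(m, "feature_matrix"))
  X <- m$features
  y <- m$labels
  n <- nrow(X)
  if (n < 8) abort("need at least 8 rows for leave-one-out classification")
  if (min(table(y)) < 2) {
    abort("classifier needs at least 2 rows per condition (each training fold must contain every condition)")
  }
  if (is.null(ranking)) ranking <- discrimination_ranking(m)
  global_order <- ranking$feature
  fold_orders <- if (rank_in_fold) {
    lapply(seq_len(n), function(i) {
      discrimination_ranking(
        structure(list(features = X[-i, , drop = FALSE], labels = y[-i]),
          class = "feature_matrix"
        )
      )$feature
    })
  } else {
    NULL
  }

  p_max <- min(ncol(X), max_steps)
  acc <- numeric(0)
  for (k in seq_len(p_max)) {
    hits <- vapply(seq_len(n), function(i) {
      feats <- if (rank_in_fold) fold_orders[[i]][seq_len(k)] else global_order[seq_len(k)]
      tr <- X[-i, feats, drop = FALSE]
      te <- X[i, feats, drop = FALSE]
      if (nlevels(droplevels(y[-i])) < 2) abort("degenerate training fold: single class")
      mu <- colMeans(tr)
      sdev <- apply(tr, 2, stats::sd)
      sdev[sdev == 0] <- 1
      tr <- sweep(sweep(tr, 2, mu), 2, sdev, "/")
      te <- sweep(sweep(te, 2, mu), 2, sdev, "/")
      fit <- e1071::svm(tr, y[-i], kernel = "linear", cost = cost, scale = FALSE)
      as.character(predict(fit, te)) == as.character(y[i])
    }, logical(1))
    acc[k] <- 100 * mean(hits)
    if (acc[k] >= stop_accuracy) break
  }

  best_k <- which.max(acc)
  best_acc <- acc[best_k]
  k_hits <- round(best_acc / 100 * n)
  structure(
    list(
      accuracy_by_step = acc,
      selected_features = global_order[seq_len(best_k)],
      best_accuracy = best_acc,
      best_n_features = best_k,
      p_value = binomial_vs_chance(k_hits, n),
      stopped_at = length(acc),
      representation = m$representation,
      n_rows = n
    ),
    class = "classifier_result"
  )
}

#' Exact binomial test of classification accuracy against chance
#'
#' One-sided upper tail probability `P(X >= k)` for
#' `X ~ Binomial(n, p0)`, the chance of doing at least as well as observed
#' when guessing among the response alternatives.
#'
#' @param k Number of correct classifications.
#' @param n Number of classifications.
#' @param p0 Chance rate (default 0.25 for 4 alternatives).
#' @return The p-value.
#' @export
#' @examples
#' binomial_vs_chance(27, 64) # well below 0.005
binomial_vs_chance <- function(k, n, p0 = 0.25) {
  if (!is.finite(k) || !is.finite(n) || k < 0 || n < 1 || k > n) {
    abort(sprintf("invalid counts: k = %s, n = %s", format(k), format(n)))
  }
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' @export
tidy.classifier_result <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$accuracy_by_step),
    n_features = seq_along(x$accuracy_by_step),
    accuracy_pct = x$accuracy_by_step
  )
}

#' @export
glance.classifier_result <- function(x, ...) {
  tibble::tibble(
    representation = x$representation,
    best_accuracy_pct = x$best_accuracy,
    best_n_features = x$best_n_features,
    p_value = x$p_value,
    steps_run = x$stopped_at,
    n_rows = x$n_rows
  )
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf(
    "Stepwise linear-SVM LOO classification (%s representation)\n  best accuracy %.1f%% with %d feature(s) over %d rows (binomial p vs 25%% = %.3g)\n",
    x$representation, x$best_accuracy, x$best_n_features, x$n_rows, x$p_value
  ))
  invisible(x)
}
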