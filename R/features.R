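#' Build the feature matrix for condition classification
#'
#' Recodes a set of individual z-scored CIs into one of the four feature
#' spaces used to classify individuals by spatial-frequency condition:
#'
#' * `time`: the 24 time-domain CI frames;
#' * `time_fourier`: the 12 x 12 frequency-by-phase grid
#'   ([fourier_feature_grid()]) of the time-domain CI (144 features);
#' * `tf`: the 11 x 24 time-frequency CI (264 features);
#' * `tf_fourier`: a frequency-by-phase grid of each of the 11
#'   oscillation-frequency rows of the time-frequency CI (11 x 144 = 1584
#'   features).
#'
#' Column order is deterministic: grids are flattened column-major
#' (frequency fastest), and in `tf_fourier` the 11 source rows are stacked
#' in ascending oscillation frequency.
#'
#' @param zci_set A `ci_set` of individual CIs (all the same shape); time
#'   representations need a time-domain set, `tf*` a time-frequency set.
#' @param representation One of `"time"`, `"time_fourier"`, `"tf"`,
#'   `"tf_fourier"`.
#' @return A `feature_matrix`: list with `features` (rows = individual CIs),
#'   `labels` (condition per row), `representation`.
#' @export
featureize <- function(zci_set, representation = c("time", "time_fourier", "tf", "tf_fourier")) {
  representation <- match.arg(representation)
  shapes <- vapply(zci_set, function(z) paste(dim(z$values), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1) {
    abort(paste0("mixed CI shapes in set: ", paste(unique(shapes), collapse = ", ")))
  }
  need <- if (representation %in% c("time", "time_fourier")) "time" else "time_frequency"
  if (attr(zci_set, "domain") != need) {
    abort(sprintf("representation '%s' needs %s-domain CIs", representation, need))
  }
  rows <- lapply(zci_set, function(z) {
    v <- z$values
    switch(representation,
      time = as.numeric(v),
      time_fourier = as.numeric(fourier_feature_grid(as.numeric(v))),
      tf = as.numeric(v),
      tf_fourier = as.numeric(vapply(
        seq_len(nrow(v)),
        function(r) as.numeric(fourier_feature_grid(v[r, ])),
        numeric(144)
      ))
    )
  })
  m <- do.call(rbind, rows)
  structure(
    list(
      features = m,
      labels = factor(vapply(zci_set, function(z) z$condition[1], numeric(1))),
      representation = representation
    ),
    class = "feature_matrix"
  )
}

#' Rank features by their discrimination index
#'
#' For each feature, the discrimination index is the variance of the
#' condition means divided by the pooled within-condition (error) variance
#' -- an F-ratio-like statistic. Features are returned in descending index
#' order; ties (and equal indices) break toward the lower column index. A
#' feature with zero within-condition variance gets index `Inf` when its
#' condition means differ and 0 when they do not.
#'
#' @param m A `feature_matrix`, or a plain matrix plus `labels`.
#' @param labels Condition labels (unused when `m` is a `feature_matrix`).
#' @return A tibble: `rank`, `feature` (column index), `d_index`.
#' @export
discrimination_ranking <- function(m, labels = NULL) {
  if (inherits(m, "feature_matrix")) {
    labels <- m$labels
    m <- m$features
  }
  labels <- as.factor(labels)
  if (nlevels(labels) < 2) abort("need at least two conditions to rank features")
  if (min(table(labels)) < 2) abort("need at least two rows per condition")
  d <- discrimination_index(m, labels)
  ord <- order(-d, seq_along(d))
  tibble::tibble(rank = seq_along(ord), feature = ord, d_index = d[ord])
}

discrimination_index <- function(m, labels) {
  groups <- split(seq_len(nrow(m)), labels)
  means <- vapply(groups, function(ix) colMeans(m[ix, , drop = FALSE]), numeric(ncol(m)))
  means <- matrix(means, nrow = ncol(m))
  vars <- vapply(groups, function(ix) apply(m[ix, , drop = FALSE], 2, stats::var), numeric(ncol(m)))
  vars <- matrix(vars, nrow = ncol(m))
  df <- vapply(groups, length, numeric(1)) - 1
  # population variance of the condition means (divide by the number of
  # conditions, not K - 1)
  between <- apply(means, 1, function(m) mean((m - mean(m))^2))
  within <- as.numeric(vars %*% df) / sum(df)
  d <- between / within
  d[within == 0 & between == 0] <- 0
  d[within == 0 & between > 0] <- Inf
  d
}
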