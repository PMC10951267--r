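#' Condition signatures of the selected features
#'
#' Illustrates what characterizes each condition on the features the
#' classifier retained. For condition c and feature f the signature is the
#' squared difference between the condition mean and the overall mean across
#' conditions, divided by the feature's pooled error variance, with the sign
#' of (condition mean - overall mean) re-attached so the map spans both
#' directions. Values are then linearly normalized by the maximum absolute
#' value over all conditions x features into `[-1, 1]`, and a display
#' contrast is derived that dims weaker features linearly down to a floor of
#' 0.3. Cells whose signature is exactly 0 are flagged omitted.
#'
#' @param m A `feature_matrix`.
#' @param selected_features Integer feature (column) indices retained by the
#'   classifier.
#' @return A `signature_map` tibble: `condition`, `feature`, `signature`
#'   (in `[-1, 1]`), `display_contrast` (in `[0.3, 1]`), `omitted`.
#' @export
condition_signature <- function(m, selected_features) {
  stopifnot(inherits(m, "feature_matrix"))
  if (length(selected_features) == 0) abort("selected_features must be non-empty")
  X <- m$features[, selected_features, drop = FALSE]
  labels <- m$labels
  groups <- split(seq_len(nrow(X)), labels)
  means <- vapply(groups, function(ix) colMeans(X[ix, , drop = FALSE]), numeric(ncol(X)))
  means <- matrix(means, ncol = length(groups))
  vars <- vapply(groups, function(ix) apply(X[ix, , drop = FALSE], 2, stats::var), numeric(ncol(X)))
  vars <- matrix(vars, ncol = length(groups))
  df <- vapply(groups, length, numeric(1)) - 1
  err_var <- as.numeric(vars %*% df) / sum(df)
  if (any(err_var == 0)) abort("zero error variance for one or more selected features")
  grand <- rowMeans(means)
  dev <- means - grand # features x conditions
  s <- sign(dev) * dev^2 / err_var
  mx <- max(abs(s))
  if (mx > 0) s <- s / mx
  out <- tibble::tibble(
    condition = rep(as.numeric(levels(labels)), each = ncol(X)),
    feature = rep(selected_features, times = length(groups)),
    signature = as.numeric(s),
    display_contrast = pmax(0.3, 1 - 0.7 * (1 - abs(as.numeric(s)))),
    omitted = as.numeric(s) == 0
  )
  class(out) <- c("signature_map", class(out))
  out
}
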