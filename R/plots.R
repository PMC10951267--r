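#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a classification image
#'
#' Time-domain CIs are drawn as an efficiency-by-time curve (with optional
#' horizontal significance thresholds); time-frequency CIs as a
#' time-by-oscillation-frequency heat map (optionally masking
#' non-significant cells to white).
#'
#' @param object A `zci`.
#' @param pixel A `pixel_test_result` for the same map (optional).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zci <- function(object, pixel = NULL, ...) {
  df <- tidy.zci(object)
  if (object$domain == "time") {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$z)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time from target onset (ms)", y = "processing efficiency (z)")
    if (!is.null(pixel)) {
      p <- p + ggplot2::geom_hline(
        yintercept = c(pixel$z_threshold_low, pixel$z_threshold_high),
        linetype = 2, colour = "red"
      )
    }
    p
  } else {
    if (!is.null(pixel)) df$z[!as.logical(pixel$significance_mask)] <- NA_real_
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$freq_hz, fill = .data$z)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(na.value = "white") +
      ggplot2::labs(
        x = "time from target onset (ms)",
        y = "SNR oscillation frequency (Hz)", fill = "z"
      )
  }
}

#' Plot the staircase contrast trajectories of a trial log
#'
#' @param log A `trial_log` (one participant is clearest).
#' @return A ggplot object: contrast against trial number, one line per
#'   condition.
#' @export
plot_staircase <- function(log) {
  df <- dplyr::mutate(log, trial_no = dplyr::row_number(), .by = "participant_id")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$trial_no, y = .data$contrast,
    colour = factor(.data$condition)
  )) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~ .data$participant_id) +
    ggplot2::labs(x = "trial", y = "target contrast (%)", colour = "condition")
}

#' @export
autoplot.classifier_result <- function(object, ...) {
  ggplot2::ggplot(
    tidy.classifier_result(object),
    ggplot2::aes(x = .data$n_features, y = .data$accuracy_pct)
  ) +
    ggplot2::geom_hline(yintercept = 25, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "features entered", y = "LOO accuracy (%)",
      title = paste0(object$representation, " representation")
    )
}

#' @export
autoplot.signature_map <- function(object, ...) {
  df <- object[!object$omitted, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$feature, y = factor(.data$condition),
    fill = .data$signature, alpha = .data$display_contrast
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(x = "feature index", y = "condition", fill = "signature")
}
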