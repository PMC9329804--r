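# ggplot2 autoplot() methods for the result containers.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a time-frequency map
#'
#' Raster of power (or baseline-relative change) over time and frequency.
#'
#' @param object an `eeg_tfr`.
#' @param baseline_relative show `(P - P_base)/P_base` per frequency row.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.eeg_tfr <- function(object, baseline_relative = TRUE, ...) {
  pw <- object$power
  lab <- "power (uV^2)"
  if (baseline_relative) {
    bi <- which(object$times >= object$baseline[1] &
                  object$times < object$baseline[2])
    base <- rowMeans(pw[, bi, drop = FALSE])
    pw <- sweep(pw, 1, base, "/") - 1
    lab <- "relative power change"
  }
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$value <- as.vector(t(pw))  # row-major flatten matches expand_grid order
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = lab) +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  title = paste("Channel", object$channel)) +
    ggplot2::theme_minimal()
}

#' Plot a fatigue time course
#'
#' Per-trial composite fatigue index with a linear trend; one facet per
#' channel if `by_channel`.
#'
#' @param object a `fatigue_series`.
#' @param by_channel facet per channel instead of the channel mean.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fatigue_series <- function(object, by_channel = FALSE, ...) {
  if (by_channel) {
    p <- ggplot2::ggplot(object$by_channel,
                         ggplot2::aes(x = .data$trial, y = .data$index)) +
      ggplot2::facet_wrap(~channel, scales = "free_y")
  } else {
    p <- ggplot2::ggplot(object$index,
                         ggplot2::aes(x = .data$trial, y = .data$index))
  }
  p + ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "trial", y = "fatigue index") +
    ggplot2::theme_minimal()
}

#' Plot an entropy report
#'
#' Per-trial rhythm entropy averaged over the frontal channels, with the
#' awake/fatigue state means.
#'
#' @param object an `entropy_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.entropy_report <- function(object, ...) {
  pt <- object$per_trial |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(entropy = mean(.data$entropy), .groups = "drop")
  ggplot2::ggplot(pt, ggplot2::aes(x = .data$trial, y = .data$entropy)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(object$awake_mean,
                                       object$fatigue_mean),
                        linetype = "dashed") +
    ggplot2::labs(x = "trial", y = "rhythm entropy (bits)") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' Loss and test accuracy per epoch for a trained model.
#'
#' @param object a trained `mi_cnn`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mi_cnn <- function(object, ...) {
  if (is.null(object$history)) stop("model has no training history")
  df <- tidyr::pivot_longer(object$history, c("train_loss", "test_acc"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
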