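#' Plot a spectrum
#'
#' Log-log power spectral density.
#'
#' @param object a `hippo_spectrum` from [welch_psd()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.hippo_spectrum <- function(object, ...) {
  df <- filter(as_tibble(object), .data$freq_hz > 0, .data$power > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq_hz, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power (units²/Hz)") +
    ggplot2::theme_minimal()
}

#' Plot an aperiodic fit
#'
#' Spectrum with the fitted 1/f model overlaid and detected peaks marked.
#'
#' @param object an [fit_aperiodic()] result.
#' @param spec the spectrum that was fitted (for the raw trace); when `NULL`
#'   only the model and residual are shown.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.aperiodic_fit <- function(object, spec = NULL, ...) {
  ap <- filter(as_tibble(object$aperiodic_power), .data$freq_hz > 0)
  p <- ggplot2::ggplot(ap, ggplot2::aes(.data$freq_hz, .data$power)) +
    ggplot2::geom_line(linetype = 2, color = "grey40")
  if (!is.null(spec)) {
    p <- p + ggplot2::geom_line(
      data = filter(as_tibble(spec), .data$freq_hz > 0, .data$power > 0))
  }
  if (nrow(object$peaks) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = object$peaks$center_hz,
                                 linetype = 3, color = "firebrick")
  }
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power",
                  subtitle = sprintf("offset %.2f, exponent %.2f",
                                     object$offset, object$exponent)) +
    ggplot2::theme_minimal()
}

#' Plot detected oscillation epochs over the signal
#'
#' @param object an `osc_epochs` tibble from [detect_osc_epochs()].
#' @param ts the analyzed [new_ts()] signal (optional background trace).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.osc_epochs <- function(object, ts = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(ts)) {
    p <- p + ggplot2::geom_line(data = as_tibble(ts),
                                ggplot2::aes(.data$time_s, .data$value),
                                linewidth = 0.2)
  }
  p + ggplot2::geom_rect(
    data = as_tibble(object),
    ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                 ymin = -Inf, ymax = Inf, fill = .data$band),
    alpha = 0.25) +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ripple events over the trace
#'
#' @param object a `ripple_events` tibble from [detect_swr()].
#' @param ts the analyzed [new_ts()] LFP (optional background trace).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ripple_events <- function(object, ts = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(ts)) {
    p <- p + ggplot2::geom_line(data = as_tibble(ts),
                                ggplot2::aes(.data$time_s, .data$value),
                                linewidth = 0.2)
  }
  p + ggplot2::geom_rect(
    data = as_tibble(object),
    ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                 ymin = -Inf, ymax = Inf),
    fill = "firebrick", alpha = 0.3) +
    ggplot2::labs(x = "Time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a peri-SWR firing histogram
#'
#' @param object an [swr_modulation()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.swr_modulation <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(.data$bin, .data$rate_hz)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$baseline_rate_hz,
                        linetype = 2) +
    ggplot2::labs(x = "Peri-SWR bin", y = "Rate (Hz)",
                  subtitle = if (object$single_peaked) "single-peaked"
                             else "not single-peaked") +
    ggplot2::theme_minimal()
}
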