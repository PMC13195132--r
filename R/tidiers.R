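#' Tidy an aperiodic fit
#'
#' One row per detected Gaussian peak (`center_hz`, `height_log10`,
#' `width_hz`).
#'
#' @param x an [fit_aperiodic()] result.
#' @param ... unused.
#' @export
tidy.aperiodic_fit <- function(x, ...) {
  select(x$peaks, "center_hz", "height_log10", "width_hz")
}

#' @rdname tidy.aperiodic_fit
#' @export
glance.aperiodic_fit <- function(x, ...) {
  tibble(offset = x$offset, exponent = x$exponent,
         fit_lo_hz = x$fit_range_hz[1], fit_hi_hz = x$fit_range_hz[2],
         n_peaks = nrow(x$peaks))
}

#' Tidy a per-cell phase-locking result
#'
#' @param x a [phase_lock_cell()] result.
#' @param ... unused.
#' @export
tidy.phase_lock_result <- function(x, ...) as_tibble(x)

#' @rdname tidy.phase_lock_result
#' @export
glance.phase_lock_result <- function(x, ...) {
  tibble(mean_R = attr(x, "mean_R"), locked = attr(x, "locked"),
         n_thresholds = nrow(x))
}

#' Tidy a burst report
#'
#' One row per burst.
#'
#' @param x a [detect_bursts()] result.
#' @param ... unused.
#' @export
tidy.burst_report <- function(x, ...) x$bursts

#' @rdname tidy.burst_report
#' @export
glance.burst_report <- function(x, ...) {
  tibble(n_bursts = nrow(x$bursts), burst_index = x$burst_index,
         burst_event_rate_hz = x$burst_event_rate_hz,
         n_spikes_total = x$n_spikes_total, isi_thresh_ms = x$isi_thresh_ms)
}

#' Tidy an intrinsic-property report
#'
#' One row per detected action potential.
#'
#' @param x an [intrinsic_analysis()] result.
#' @param ... unused.
#' @export
tidy.intrinsic_report <- function(x, ...) x$ap_features

#' @rdname tidy.intrinsic_report
#' @export
glance.intrinsic_report <- function(x, ...) {
  tibble(vm_mv = x$vm_mv, rin_mohm = x$rin_mohm,
         n_aps = nrow(x$ap_features),
         mean_half_width_ms = if (nrow(x$ap_features))
           mean(x$ap_features$half_width_ms) else NA_real_)
}
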