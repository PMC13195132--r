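#' Unit classification and burst analysis
#'
#' Cell-type classification of sorted extracellular units from spike width
#' (trough-to-peak of the mean waveform) and the first moment of the 0-50 ms
#' autocorrelogram; firing-rate categories per class; burst detection as
#' maximal runs of >= 3 spikes with inter-spike intervals below threshold;
#' and inter-spike-interval distributions.
#'
#' @name units
NULL

#' Trough-to-peak spike width
#'
#' Time from the global trough of the mean waveform to the subsequent
#' maximum. A waveform with no post-trough peak cannot be measured and the
#' unit is excluded.
#'
#' @param mean_waveform numeric vector (mean extracellular spike waveform).
#' @param rate_hz waveform sampling rate.
#' @return width in ms, or `NA` (excluded) when no post-trough peak exists.
#' @export
spike_width <- function(mean_waveform, rate_hz) {
  tr <- which.min(mean_waveform)
  if (tr >= length(mean_waveform)) return(NA_real_)
  post <- mean_waveform[(tr + 1):length(mean_waveform)]
  pk <- which.max(post)
  # a genuine post-trough peak must be prominent relative to the spike
  # depth; a near-flat recovery tail (e.g. a time-reversed waveform) is not
  # a measurable trough-to-peak interval
  depth <- max(mean_waveform) - mean_waveform[tr]
  prominence <- post[pk] - min(post[pk:length(post)])
  if (post[pk] <= mean_waveform[tr] || prominence < 0.05 * depth) {
    return(NA_real_)
  }
  pk / rate_hz * 1000
}

#' Autocorrelogram first moment
#'
#' One-sided autocorrelogram over lags `(0, lag_max_ms]`; the first moment is
#' the count-weighted mean of the bin centers (center of mass along the time
#' axis), and `peak_count` the maximum bin count. Units whose ACG peak count
#' is below 10 are excluded from classification.
#'
#' @param spike_times sorted spike times, seconds.
#' @param lag_max_ms maximum lag.
#' @param bin_ms bin width.
#' @return list: `first_moment_ms`, `peak_count`.
#' @export
acg_first_moment <- function(spike_times, lag_max_ms = 50, bin_ms = 1) {
  stopifnot(length(spike_times) >= 2)
  lag_max <- lag_max_ms / 1000
  edges <- seq(0, lag_max_ms, by = bin_ms)
  counts <- numeric(length(edges) - 1)
  n <- length(spike_times)
  j <- 1L
  for (i in seq_len(n - 1L)) {
    k <- i + 1L
    while (k <= n && spike_times[k] - spike_times[i] <= lag_max) {
      lag_ms <- (spike_times[k] - spike_times[i]) * 1000
      b <- min(max(ceiling(lag_ms / bin_ms), 1L), length(counts))
      counts[b] <- counts[b] + 1
      k <- k + 1L
    }
  }
  if (sum(counts) == 0) {
    return(list(first_moment_ms = NA_real_, peak_count = 0))
  }
  centers <- edges[-length(edges)] + bin_ms / 2
  list(first_moment_ms = sum(centers * counts) / sum(counts),
       peak_count = max(counts))
}

#' Classify a unit from width and ACG first moment
#'
#' Putative pyramidal cell: width > 0.5 ms AND first moment < 25 ms.
#' Putative fast-spiking interneuron: width < 0.5 ms AND first moment
#' > 20 ms. Strict inequalities; anything else (including exact boundaries)
#' is unclassified, and non-finite metrics are excluded.
#'
#' @param width_ms trough-to-peak spike width, ms.
#' @param first_moment_ms ACG first moment, ms.
#' @return one of `"pyramidal"`, `"fs_interneuron"`, `"unclassified"`,
#'   `"excluded"`. Vectorized.
#' @export
classify_unit <- function(width_ms, first_moment_ms) {
  out <- rep("unclassified", length(width_ms))
  out[width_ms > 0.5 & first_moment_ms < 25] <- "pyramidal"
  out[width_ms < 0.5 & first_moment_ms > 20] <- "fs_interneuron"
  out[!is.finite(width_ms) | !is.finite(first_moment_ms)] <- "excluded"
  out
}

#' Firing-rate category
#'
#' Class-specific cutpoints: pyramidal low < 1 Hz, medium 1-5 Hz, high
#' >= 5 Hz; interneuron low < 25 Hz, medium 25-40 Hz, high >= 40 Hz.
#' Interval edges follow the half-open `[low, high)` convention.
#'
#' @param mean_rate_hz mean firing rate.
#' @param cell_class `"pyramidal"` or `"fs_interneuron"`. Vectorized.
#' @return `"low"`, `"medium"` or `"high"` (`NA` for other classes).
#' @export
rate_category <- function(mean_rate_hz, cell_class) {
  cut_for <- function(rate, lo, hi) {
    ifelse(rate < lo, "low", ifelse(rate < hi, "medium", "high"))
  }
  ifelse(cell_class == "pyramidal", cut_for(mean_rate_hz, 1, 5),
         ifelse(cell_class == "fs_interneuron", cut_for(mean_rate_hz, 25, 40),
                NA_character_))
}

#' Detect burst firing
#'
#' A burst is a maximal run of `min_spikes` or more spikes whose consecutive
#' inter-spike intervals are all below `isi_thresh_ms`. The burst index is
#' the ratio of bursting spikes to all spikes; the burst event rate is the
#' number of bursts divided by the total recording time. Thresholds of 10
#' and 15 ms support the sensitivity analysis.
#'
#' @param spike_times sorted spike times, seconds.
#' @param isi_thresh_ms intra-burst ISI threshold.
#' @param min_spikes minimum spikes per burst.
#' @param total_time_s total recording time.
#' @return a `burst_report` list: `bursts` tibble (`start_s`, `end_s`,
#'   `n_spikes`, `mean_intra_isi_ms`), `burst_index`, `burst_event_rate_hz`,
#'   `spikes_per_burst` probability table, `n_spikes_total`, `isi_thresh_ms`.
#' @export
detect_bursts <- function(spike_times, isi_thresh_ms = 5, min_spikes = 3,
                          total_time_s) {
  stopifnot(total_time_s > 0)
  if (is.unsorted(spike_times)) abort("Spike times must be sorted.")
  n <- length(spike_times)
  empty <- tibble(start_s = numeric(), end_s = numeric(),
                  n_spikes = integer(), mean_intra_isi_ms = numeric())
  if (n < min_spikes) {
    return(structure(list(bursts = empty, burst_index = 0,
                          burst_event_rate_hz = 0,
                          spikes_per_burst = table(integer(0)),
                          n_spikes_total = n, isi_thresh_ms = isi_thresh_ms),
                     class = "burst_report"))
  }
  short <- diff(spike_times) < isi_thresh_ms / 1000
  r <- rle(short)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  rows <- list()
  for (k in which(r$values & r$lengths >= min_spikes - 1L)) {
    i0 <- starts[k]                    # first ISI of the run
    i1 <- ends[k] + 1L                 # last spike of the run
    rows[[length(rows) + 1L]] <- tibble(
      start_s = spike_times[i0], end_s = spike_times[i1],
      n_spikes = i1 - i0 + 1L,
      mean_intra_isi_ms = mean(diff(spike_times[i0:i1])) * 1000)
  }
  bursts <- if (length(rows)) bind_rows(rows) else empty
  n_burst_spikes <- sum(bursts$n_spikes)
  structure(
    list(bursts = bursts,
         burst_index = n_burst_spikes / n,
         burst_event_rate_hz = nrow(bursts) / total_time_s,
         spikes_per_burst = if (nrow(bursts))
           table(bursts$n_spikes) / nrow(bursts) else table(integer(0)),
         n_spikes_total = n, isi_thresh_ms = isi_thresh_ms),
    class = "burst_report")
}

#' @export
print.burst_report <- function(x, ...) {
  cat(sprintf("<burst_report> %d burst(s), burst index %.3f, rate %.3f Hz (ISI < %g ms)\n",
              nrow(x$bursts), x$burst_index, x$burst_event_rate_hz,
              x$isi_thresh_ms))
  invisible(x)
}

#' Inter-spike-interval distribution
#'
#' Normalized ISI histogram over `[0, range_ms]` plus the cumulative
#' fraction of all ISIs below 5 ms.
#'
#' @param spike_times sorted spike times, seconds (>= 2 spikes).
#' @param range_ms histogram range.
#' @param bin_ms bin width.
#' @return list: `histogram` tibble (`isi_ms` bin centers, `count`,
#'   `density` normalized over all ISIs), `cum_frac_5ms`.
#' @export
isi_distribution <- function(spike_times, range_ms = 15, bin_ms = 0.5) {
  stopifnot(length(spike_times) >= 2)
  isi_ms <- diff(spike_times) * 1000
  edges <- seq(0, range_ms, by = bin_ms)
  counts <- as.numeric(table(cut(isi_ms, edges, right = FALSE)))
  list(histogram = tibble(isi_ms = edges[-length(edges)] + bin_ms / 2,
                          count = counts,
                          density = counts / length(isi_ms)),
       cum_frac_5ms = mean(isi_ms < 5))
}

#' Build a unit table from a spike table
#'
#' Per-unit metrics over a recording: spike counts, mean rate over the full
#' session, ACG first moment and peak count, optional spike width from mean
#' waveforms, classification label, rate category and burst metrics.
#'
#' @param spikes a spike table tibble (`unit_id`, `time_s`), e.g. from
#'   [read_spike_table()].
#' @param total_time_s session duration.
#' @param waveforms optional named list of mean waveforms per unit id.
#' @param waveform_rate_hz sampling rate of the waveforms.
#' @param isi_thresh_ms burst ISI threshold.
#' @return tibble with one row per unit: `unit_id`, `n_spikes`,
#'   `mean_rate_hz`, `spike_width_ms`, `acg_first_moment_ms`,
#'   `acg_peak_count`, `label`, `rate_category`, `burst_index`,
#'   `burst_event_rate_hz`, `n_bursts`.
#' @export
unit_table <- function(spikes, total_time_s, waveforms = NULL,
                       waveform_rate_hz = 20000, isi_thresh_ms = 5) {
  ids <- sort(unique(spikes$unit_id))
  bind_rows(map(ids, function(id) {
    st <- sort(spikes$time_s[spikes$unit_id == id])
    acg <- if (length(st) >= 2) acg_first_moment(st) else
      list(first_moment_ms = NA_real_, peak_count = 0)
    w <- if (!is.null(waveforms) && !is.null(waveforms[[as.character(id)]])) {
      spike_width(waveforms[[as.character(id)]], waveform_rate_hz)
    } else NA_real_
    label <- if (acg$peak_count < 10) "excluded" else
      classify_unit(w, acg$first_moment_ms)
    br <- detect_bursts(st, isi_thresh_ms = isi_thresh_ms,
                        total_time_s = total_time_s)
    rate <- length(st) / total_time_s
    tibble(unit_id = id, n_spikes = length(st), mean_rate_hz = rate,
           spike_width_ms = w, acg_first_moment_ms = acg$first_moment_ms,
           acg_peak_count = acg$peak_count, label = label,
           rate_category = rate_category(rate, label),
           burst_index = br$burst_index,
           burst_event_rate_hz = br$burst_event_rate_hz,
           n_bursts = nrow(br$bursts))
  }))
}
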