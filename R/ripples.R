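#' Sharp-wave ripples and putative PV+ basket cells
#'
#' Pyramidal-layer channel selection by ripple-band power, SWR detection by
#' envelope thresholding with duration and control-band specificity gates,
#' peri-SWR firing histograms against duration-matched baseline periods,
#' theta phase preference of units (trough-referenced degrees), and the
#' putative PV+ basket-cell criterion (single-peaked peri-SWR firing with
#' theta phase preference between 203 and 339 degrees).
#'
#' @name ripples
NULL

gaussian_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- ceiling(4 * sigma_samples)
  k <- exp(-(-half:half)^2 / (2 * sigma_samples^2))
  k <- k / sum(k)
  n <- length(x)
  xe <- c(rev(x[seq_len(half)]), x, rev(x[seq(n - half + 1, n)]))
  as.numeric(convolve(xe, rev(k), type = "filter"))[seq_len(n) + 0L]
}

#' Select the pyramidal-layer channel per shank
#'
#' Per shank, the channel with the largest mean power of the 150-250 Hz
#' band-passed LFP (squared Hilbert envelope) is designated the pyramidal
#' cell layer. Ties go to the lowest channel index (reported in the result).
#'
#' @param lfp a multichannel [new_ts()] with a `channel_shank` map.
#' @param band ripple band for the power criterion, Hz.
#' @return tibble (`shank`, `channel`, `mean_power`, `tie`).
#' @export
select_pyramidal_channel <- function(lfp, band = c(150, 250)) {
  if (is.null(lfp$channel_shank)) abort("`lfp` needs a channel_shank map.")
  nch <- ts_n_channels(lfp)
  powers <- map_dbl(seq_len(nch), function(i) {
    f <- bandpass(ts_channel(lfp, i), band[1], band[2], order = 4)
    mean(Mod(analytic_signal(f$data))^2)
  })
  bind_rows(map(sort(unique(lfp$channel_shank)), function(s) {
    ch <- which(lfp$channel_shank == s)
    p <- powers[ch]
    best <- ch[which.max(p)]
    tie <- sum(abs(p - max(p)) < 1e-12 * max(1, max(p))) > 1
    if (tie) warn(sprintf("Shank %s: tied ripple power; lowest channel %d chosen.",
                          s, best))
    tibble(shank = s, channel = best, mean_power = max(p), tie = tie)
  }))
}

#' Detect sharp-wave ripples
#'
#' The LFP is band-pass filtered in the ripple range (100-250 Hz, 4th-order
#' zero-phase Butterworth), the squared Hilbert envelope is smoothed with a
#' Gaussian kernel (sigma = 4 ms), and candidate events are contiguous
#' periods above `mean + sd_mult x SD` of the smoothed power, with bounds
#' extended to the nearest crossings of the mean on both sides. The
#' `duration_ms` criterion is applied to the supra-threshold core (sustained
#' ripple power is what separates an event from a brief background
#' excursion); reported bounds and duration are the mean-extended ones, and
#' events whose extended span exceeds the upper duration bound are dropped.
#' Candidates must also have within-event mean ripple-band power at least
#' `min_specificity` times the identically processed control-band
#' (250-400 Hz) power. Per event: duration, cycle
#' count (peaks of the ripple-filtered trace within bounds), z-scored peak
#' power, and the specificity ratio.
#'
#' @param lfp a single-channel [new_ts()] at a rate above 800 Hz.
#' @param ripple_band,control_band band definitions, Hz.
#' @param sd_mult threshold multiplier on the SD of the smoothed power.
#' @param duration_ms admissible event duration range.
#' @param min_specificity minimum ripple/control power ratio.
#' @param smooth_sigma_ms Gaussian smoothing sigma.
#' @return a `ripple_events` tibble: `start_s`, `end_s`, `peak_s`,
#'   `duration_ms`, `n_cycles`, `power_z`, `specificity_ratio`.
#' @export
detect_swr <- function(lfp, ripple_band = c(100, 250),
                       control_band = c(250, 400), sd_mult = 3,
                       duration_ms = c(15, 150), min_specificity = 4,
                       smooth_sigma_ms = 4) {
  fs <- lfp$rate_hz
  if (fs / 2 <= control_band[2]) {
    abort("Sampling rate too low for the control band.")
  }
  rb <- bandpass(lfp, ripple_band[1], ripple_band[2], order = 4)$data
  cb <- bandpass(lfp, control_band[1], control_band[2], order = 4)$data
  sig <- smooth_sigma_ms / 1000 * fs
  pr <- gaussian_smooth(Mod(analytic_signal(rb))^2, sig)
  pc <- gaussian_smooth(Mod(analytic_signal(cb))^2, sig)
  mu <- mean(pr); s <- sd(pr)
  thr <- mu + sd_mult * s
  above <- pr > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  n <- length(pr)
  cand <- list()
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    # the duration criterion applies to the supra-threshold core: that is
    # what separates sustained ripple power from brief background excursions
    core_ms <- (b - a + 1) / fs * 1000
    if (core_ms < duration_ms[1] || core_ms > duration_ms[2]) next
    while (a > 1 && pr[a - 1] > mu) a <- a - 1
    while (b < n && pr[b + 1] > mu) b <- b + 1
    cand[[length(cand) + 1L]] <- c(a, b)
  }
  empty <- tibble(start_s = numeric(), end_s = numeric(), peak_s = numeric(),
                  duration_ms = numeric(), n_cycles = integer(),
                  power_z = numeric(), specificity_ratio = numeric())
  if (length(cand) == 0) {
    return(structure(empty, class = c("ripple_events", class(empty))))
  }
  # extension can make neighbors touch; merge identical/overlapping bounds
  m <- do.call(rbind, cand)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- merged[[length(merged)]]
    if (m[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], m[i, 2]))
    } else merged[[length(merged) + 1L]] <- m[i, ]
  }
  rows <- map(merged, function(ab) {
    a <- ab[1]; b <- ab[2]
    dur <- (b - a + 1) / fs * 1000
    if (dur > duration_ms[2]) return(NULL)   # merged extension overlong
    ratio <- mean(pr[a:b]) / mean(pc[a:b])
    if (!is.finite(ratio) || ratio < min_specificity) return(NULL)
    seg <- rb[a:b]
    npk <- sum(diff(sign(diff(seg))) < 0)
    pk <- a + which.max(pr[a:b]) - 1L
    tibble(start_s = lfp$t0_s + (a - 1) / fs,
           end_s = lfp$t0_s + b / fs,
           peak_s = lfp$t0_s + (pk - 1) / fs,
           duration_ms = dur, n_cycles = as.integer(npk),
           power_z = (pr[pk] - mu) / s,
           specificity_ratio = ratio)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(structure(empty, class = c("ripple_events", class(empty))))
  }
  structure(out, class = c("ripple_events", class(out)))
}

#' Sample duration-matched control periods
#'
#' Draws one random window per ripple event from the labeled baseline
#' segments (typically non-theta time), excluding SWR windows, matched in
#' duration to that event.
#'
#' @param segments tibble (`start_s`, `end_s`) of admissible baseline time.
#' @param ripples a [detect_swr()] table to exclude and match.
#' @param seed RNG seed for reproducible sampling.
#' @param max_tries rejection-sampling cap per event.
#' @return tibble (`start_s`, `end_s`), one row per ripple event.
#' @export
sample_control_periods <- function(segments, ripples, seed = 1,
                                   max_tries = 1000) {
  if (nrow(segments) == 0) abort("No baseline time available for controls.")
  with_seed(seed, {
    rows <- map(seq_len(nrow(ripples)), function(i) {
      dur <- (ripples$end_s[i] - ripples$start_s[i])
      for (try in seq_len(max_tries)) {
        j <- sample.int(nrow(segments), 1,
                        prob = segments$end_s - segments$start_s)
        if (segments$end_s[j] - segments$start_s[j] < dur) next
        s <- runif(1, segments$start_s[j], segments$end_s[j] - dur)
        overlaps <- any(s < ripples$end_s & (s + dur) > ripples$start_s)
        if (!overlaps) return(tibble(start_s = s, end_s = s + dur))
      }
      abort("Could not place a control period; baseline too fragmented.")
    })
    bind_rows(rows)
  })
}

#' Peri-SWR modulation of a unit
#'
#' Each SWR event is divided into eight equal bins centered on the SWR peak
#' (the event midpoint); spike counts are aggregated across events and
#' converted to rates. Baseline is the firing rate over the duration-matched
#' control set. The firing pattern is single-peaked when the aggregate
#' histogram has exactly one local maximum and it lies in the two central
#' bins.
#'
#' @param spike_times sorted spike times, seconds.
#' @param ripples a [detect_swr()] table.
#' @param control_periods tibble (`start_s`, `end_s`), e.g. from
#'   [sample_control_periods()].
#' @param n_bins number of peri-event bins (8).
#' @return an `swr_modulation` list: `histogram` tibble (`bin`, `count`,
#'   `rate_hz`), `baseline_rate_hz`, `single_peaked`, `n_events`.
#' @export
swr_modulation <- function(spike_times, ripples, control_periods,
                           n_bins = 8) {
  if (nrow(control_periods) == 0) abort("No control periods supplied.")
  counts <- numeric(n_bins)
  bin_time <- numeric(n_bins)
  for (i in seq_len(nrow(ripples))) {
    a <- ripples$start_s[i]; b <- ripples$end_s[i]
    edges <- seq(a, b, length.out = n_bins + 1)
    counts <- counts + as.numeric(table(cut(spike_times, edges, right = FALSE)))
    bin_time <- bin_time + diff(edges)
  }
  rate <- ifelse(bin_time > 0, counts / bin_time, NA_real_)
  ctrl_dur <- sum(control_periods$end_s - control_periods$start_s)
  ctrl_n <- sum(map_dbl(seq_len(nrow(control_periods)), function(i)
    sum(spike_times >= control_periods$start_s[i] &
          spike_times < control_periods$end_s[i])))
  h <- counts
  # interior local maxima only: edge-bin wiggles say nothing about firing
  # "surrounding the SWR peak"
  interior <- 2:(n_bins - 1)
  is_max <- map_dbl(interior, function(i)
    as.numeric(h[i] > h[i - 1] && h[i] > h[i + 1]))
  central <- c(n_bins / 2, n_bins / 2 + 1)
  single <- sum(is_max) == 1 && interior[which(is_max == 1)] %in% central &&
    sum(h) > 0
  structure(
    list(histogram = tibble(bin = seq_len(n_bins), count = counts,
                            rate_hz = rate),
         baseline_rate_hz = ctrl_n / ctrl_dur,
         single_peaked = isTRUE(single),
         n_events = nrow(ripples)),
    class = "swr_modulation")
}

# symmetric FIR bandpass with exact delay compensation
fir_bandpass <- function(ts, lo, hi, order = NULL) {
  fs <- ts$rate_hz
  nyq <- fs / 2
  if (is.null(order)) order <- 2L * round(1.65 * fs / lo)   # even order
  h <- signal::fir1(order, c(lo, hi) / nyq, type = "pass")
  half <- order / 2
  x <- ts$data
  xf <- as.numeric(stats::filter(c(x, numeric(half)), h, sides = 1))
  ts_with_data(ts, {
    y <- xf[-seq_len(half)]
    y[is.na(y)] <- 0
    y
  })
}

#' Theta phase preference of a unit
#'
#' Spikes inside theta segments are assigned phases of the FIR
#' theta-band-filtered LFP via the Hilbert transform, expressed in
#' trough-referenced degrees (trough = 0/360, peak = 180), binned at 18
#' degrees. The preferred phase is the circular mean; significance is the
#' Rayleigh test.
#'
#' @param spike_times sorted spike times, seconds.
#' @param theta_segments tibble of theta periods (`start_s`, `end_s`), e.g.
#'   the theta rows of [theta_state_segments()].
#' @param lfp a single-channel [new_ts()].
#' @param band theta band, Hz.
#' @param min_spikes minimum in-segment spikes for a defined preference.
#' @param bin_deg histogram bin width, degrees.
#' @param phase_ts optional precomputed analytic-phase series of the
#'   theta-filtered LFP (cosine convention), e.g. shared across the units of
#'   a session; when `NULL` it is derived from `lfp`.
#' @return list: `preferred_phase_deg` (in `[0, 360)`), `rayleigh_p`,
#'   `vector_length`, `n_spikes`, `histogram` tibble (`phase_deg`, `count`);
#'   statistics are `NA` (flagged) below `min_spikes`.
#' @export
theta_phase_pref <- function(spike_times, theta_segments, lfp,
                             band = c(4, 12), min_spikes = 10,
                             bin_deg = 18, phase_ts = NULL) {
  ph <- if (is.null(phase_ts)) {
    Arg(analytic_signal(fir_bandpass(lfp, band[1], band[2])$data))
  } else phase_ts$data
  keep <- rep(FALSE, length(spike_times))
  for (i in seq_len(nrow(theta_segments))) {
    keep <- keep | (spike_times >= theta_segments$start_s[i] &
                      spike_times < theta_segments$end_s[i])
  }
  st <- spike_times[keep]
  idx <- pmin(pmax(round((st - lfp$t0_s) * lfp$rate_hz) + 1, 1), ts_n(lfp))
  deg <- ((ph[idx] + pi) %% (2 * pi)) * 180 / pi    # trough-referenced
  edges <- seq(0, 360, by = bin_deg)
  hist <- tibble(phase_deg = edges[-length(edges)] + bin_deg / 2,
                 count = as.numeric(table(cut(deg, edges, right = FALSE))))
  if (length(deg) < min_spikes) {
    return(list(preferred_phase_deg = NA_real_, rayleigh_p = NA_real_,
                vector_length = NA_real_, n_spikes = length(deg),
                histogram = hist))
  }
  cs <- circ_stats(deg * pi / 180)
  rt <- rayleigh_test(deg * pi / 180)
  list(preferred_phase_deg = (cs$circ_mean * 180 / pi) %% 360,
       rayleigh_p = rt$p_value, vector_length = cs$R,
       n_spikes = length(deg), histogram = hist)
}

#' Putative PV+ basket-cell criterion
#'
#' TRUE iff the unit shows a single-peaked peri-SWR firing pattern and a
#' theta phase-locking preference between 203 and 339 degrees
#' (trough-referenced).
#'
#' @param single_peaked logical from [swr_modulation()].
#' @param preferred_phase_deg trough-referenced preferred theta phase.
#' @param phase_range_deg admissible phase window.
#' @return logical. Vectorized; `NA` phase gives `FALSE`.
#' @export
classify_pv_basket <- function(single_peaked, preferred_phase_deg,
                               phase_range_deg = c(203, 339)) {
  ok <- !is.na(preferred_phase_deg) &
    preferred_phase_deg >= phase_range_deg[1] &
    preferred_phase_deg <= phase_range_deg[2]
  as.logical(single_peaked & ok)
}
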