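#' Voltage-clamp and current-clamp analytics
#'
#' Spontaneous postsynaptic-current (sPSC) detection by derivative
#' thresholding with amplitude, baseline-return and separation criteria;
#' event kinetics (20-80% rise rate, single-exponential decay tau); sweep
#' charge transfer and E/I ratio; derivative-percentile onset detection for
#' phase analysis; and intrinsic-property extraction from current steps.
#'
#' @name patch
NULL

#' Detection configuration for spontaneous PSCs
#'
#' Defaults carry the published minima per polarity: derivative threshold
#' 1.8 SD (EPSC) / 1.2 SD (IPSC) above the mean, minimum amplitude 7 / 15 pA,
#' event start within 1.5 / 0.3 SD of baseline, end value within 10 / 70 pA
#' of the start value, and a minimum separation of 200 / 100 samples. All of
#' them were operator-tuned quantities in practice, so every knob is
#' overridable per run.
#'
#' @param polarity `"inward"` (EPSC) or `"outward"` (IPSC).
#' @param dvdt_sd_thresh derivative peak threshold, SD above the mean of the
#'   derivative trace.
#' @param min_amp_pa minimum event amplitude, pA.
#' @param start_sd maximum distance of the event start from baseline, in
#'   robust SDs of the sweep.
#' @param end_match_pa maximum difference between event end and start values,
#'   pA (rejects summating events).
#' @param min_separation_samples minimum distance between successive events.
#' @return a config list for [detect_psc()].
#' @export
psc_detect_config <- function(polarity = c("inward", "outward"),
                              dvdt_sd_thresh = NULL, min_amp_pa = NULL,
                              start_sd = NULL, end_match_pa = NULL,
                              min_separation_samples = NULL) {
  polarity <- match.arg(polarity)
  def <- if (polarity == "inward") {
    list(dvdt_sd_thresh = 1.8, min_amp_pa = 7, start_sd = 1.5,
         end_match_pa = 10, min_separation_samples = 200L)
  } else {
    list(dvdt_sd_thresh = 1.2, min_amp_pa = 15, start_sd = 0.3,
         end_match_pa = 70, min_separation_samples = 100L)
  }
  cfg <- list(polarity = polarity,
              dvdt_sd_thresh = dvdt_sd_thresh %||% def$dvdt_sd_thresh,
              min_amp_pa = min_amp_pa %||% def$min_amp_pa,
              start_sd = start_sd %||% def$start_sd,
              end_match_pa = end_match_pa %||% def$end_match_pa,
              min_separation_samples =
                min_separation_samples %||% def$min_separation_samples)
  if (any(unlist(cfg[-1]) <= 0)) abort("All detection thresholds must be > 0.")
  cfg
}

boxcar_smooth <- function(x, width) {
  if (width <= 1) return(x)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(x, k, sides = 2, circular = FALSE)) |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; y })()
}

#' Detect spontaneous postsynaptic currents
#'
#' Pipeline: (1) peaks of the first derivative exceeding
#' `mean + dvdt_sd_thresh x SD` of the derivative trace (sign per polarity;
#' the derivative is lightly smoothed over 1 ms for peak finding);
#' (2) candidate amplitude at least `min_amp_pa`; (3) event start within
#' `start_sd` robust SDs of baseline (median / MAD of the sweep);
#' (4) event end value within `end_match_pa` of the start value, rejecting
#' summating events; (5) successive detections at least
#' `min_separation_samples` apart, keeping the larger-amplitude event on
#' conflict.
#'
#' @param sweep a demeaned single-channel [new_ts()] in pA.
#' @param cfg a [psc_detect_config()]; built from `polarity` when `NULL`.
#' @param polarity `"inward"` or `"outward"`.
#' @return tibble of candidates: `onset_s`, `peak_s`, `amplitude_pa`,
#'   `rise_rate_pa_per_ms` (20-80% slope), `max_dvdt_pa_per_ms`,
#'   `decay_tau_ms`, `polarity`, `accepted`, `rejection_reason`. Accepted
#'   events (`accepted == TRUE`) are sorted by onset. Use
#'   [accepted_events()] for the accepted subset.
#' @export
detect_psc <- function(sweep, cfg = NULL, polarity = c("inward", "outward")) {
  polarity <- match.arg(polarity)
  if (is.null(cfg)) cfg <- psc_detect_config(polarity)
  x <- sweep$data
  if (length(x) == 0) abort("Empty sweep.")
  fs <- sweep$rate_hz
  sgn <- if (cfg$polarity == "inward") -1 else 1
  y <- sgn * x                                   # events positive-going
  ys <- boxcar_smooth(y, max(1L, round(0.001 * fs)))
  dy <- c(diff(ys), 0) * fs / 1000               # pA/ms, on the smoothed trace
  dy_raw <- c(diff(y), 0) * fs / 1000
  thr <- mean(dy) + cfg$dvdt_sd_thresh * sd(dy)
  n <- length(y)
  # one candidate per contiguous supra-threshold derivative run (one rise)
  above <- dy > thr
  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- c(1L, head(run_end, -1L) + 1L)
  keep_runs <- which(r$values)
  baseline <- median(ys)
  noise_sd <- mad(y)                             # robust noise of the raw trace
  max_evt <- round(0.05 * fs)                    # 50 ms search horizon
  decay_win <- round(0.04 * fs)                  # decay-end search horizon

  nc <- length(keep_runs)
  onset_idx <- peak_idx <- end_idx <- integer(nc)
  amp_v <- numeric(nc)
  reason <- rep(NA_character_, nc)
  for (ci in seq_len(nc)) {
    k <- keep_runs[ci]
    a <- run_start[k]; b <- run_end[k]
    # onset: walk back while the rise continues
    j <- a
    while (j > 1 && dy[j - 1] > 0 && a - j < max_evt) j <- j - 1
    # peak: end of the rising phase after the run
    p <- b
    while (p < n && dy[p] > 0 && p - b < max_evt) p <- p + 1
    amp <- ys[p] - ys[j]
    if (amp < cfg$min_amp_pa) reason[ci] <- "amplitude"
    else if (abs(ys[j] - baseline) > cfg$start_sd * noise_sd) {
      reason[ci] <- "start_baseline"
    }
    # decay end: minimum of the smoothed trace over the post-peak window
    e <- p + which.min(ys[p:min(p + decay_win, n)]) - 1L
    if (is.na(reason[ci]) && abs(ys[e] - ys[j]) > cfg$end_match_pa) {
      reason[ci] <- "end_match"
    }
    onset_idx[ci] <- j; peak_idx[ci] <- p; end_idx[ci] <- e
    amp_v[ci] <- amp
  }
  dup <- duplicated(peak_idx)
  onset_idx <- onset_idx[!dup]; peak_idx <- peak_idx[!dup]
  end_idx <- end_idx[!dup]; amp_v <- amp_v[!dup]; reason <- reason[!dup]
  if (length(onset_idx) == 0) {
    return(tibble(onset_s = numeric(), peak_s = numeric(),
                  amplitude_pa = numeric(), rise_rate_pa_per_ms = numeric(),
                  max_dvdt_pa_per_ms = numeric(), decay_tau_ms = numeric(),
                  polarity = character(), accepted = logical(),
                  rejection_reason = character()))
  }

  # separation: greedy by amplitude among currently-accepted candidates
  ok <- is.na(reason)
  ord <- order(-amp_v)
  kept <- logical(length(amp_v))
  for (i in ord) {
    if (!ok[i]) next
    if (!any(kept & abs(peak_idx - peak_idx[i]) < cfg$min_separation_samples)) {
      kept[i] <- TRUE
    } else {
      reason[i] <- "separation"
    }
  }
  t0 <- sweep$t0_s
  rise_v <- max_dvdt_v <- tau_v <- rep(NA_real_, length(amp_v))
  for (i in which(kept)) {        # kinetics only for accepted events
    seg <- y[onset_idx[i]:min(end_idx[i] + 1L, n)] - ys[onset_idx[i]]
    kin <- psc_kinetics(seg, fs)
    rise_v[i] <- kin$rise_rate_pa_per_ms
    max_dvdt_v[i] <- max(dy_raw[onset_idx[i]:peak_idx[i]])
    tau_v[i] <- kin$decay_tau_ms
  }
  out <- tibble(
    onset_s = t0 + (onset_idx - 1) / fs,
    peak_s = t0 + (peak_idx - 1) / fs,
    amplitude_pa = amp_v,
    rise_rate_pa_per_ms = rise_v,
    max_dvdt_pa_per_ms = max_dvdt_v,
    decay_tau_ms = tau_v,
    polarity = cfg$polarity,
    accepted = kept,
    rejection_reason = ifelse(kept, NA_character_, reason))
  arrange(out, .data$onset_s)
}

#' @rdname detect_psc
#' @param events a [detect_psc()] candidate table.
#' @export
accepted_events <- function(events) filter(events, .data$accepted)

#' PSC kinetics from an event waveform
#'
#' The waveform is baseline-referenced and positive-going (rising to the
#' peak). The rise rate is the 20-80% amplitude slope; the decay tau comes
#' from a single-exponential fit to the decay segment bounded by the 80% and
#' 20% crossings of the peak amplitude. Events whose decay segment is too
#' short or breaks the fit get `NA` tau (flagged, excluded from means).
#'
#' @param waveform numeric vector, baseline at 0, event positive.
#' @param rate_hz sampling rate.
#' @return list: `amplitude`, `rise_rate_pa_per_ms`, `decay_tau_ms`.
#' @export
psc_kinetics <- function(waveform, rate_hz) {
  # peak and crossing levels from a lightly smoothed copy so that single-
  # sample noise excursions do not bias the fit window; fit on the raw trace
  ws <- boxcar_smooth(waveform, max(1L, round(0.00025 * rate_hz)))
  pk <- which.max(ws)
  amp <- ws[pk]
  out <- list(amplitude = amp, rise_rate_pa_per_ms = NA_real_,
              decay_tau_ms = NA_real_)
  if (amp <= 0 || pk < 2) return(out)
  # 20-80% rise slope
  i20 <- which(ws[1:pk] >= 0.2 * amp)[1]
  i80 <- which(ws[1:pk] >= 0.8 * amp)[1]
  if (!is.na(i20) && !is.na(i80) && i80 > i20) {
    out$rise_rate_pa_per_ms <- (ws[i80] - ws[i20]) /
      ((i80 - i20) / rate_hz * 1000)
  }
  dec <- waveform[pk:length(waveform)]
  decs <- ws[pk:length(ws)]
  d80 <- which(decs <= 0.8 * amp)[1]
  d20 <- which(decs <= 0.2 * amp)[1]
  if (is.na(d80) || is.na(d20) || d20 - d80 < 5) return(out)
  seg <- dec[d80:d20]
  tt <- (seq_along(seg) - 1) / rate_hz * 1000    # ms
  pos <- seg > 0
  if (sum(pos) < 5) return(out)
  lf <- lm(log(seg[pos]) ~ tt[pos])
  tau0 <- -1 / coef(lf)[2]
  fit <- tryCatch(
    stats::nls(seg ~ a * exp(-tt / tau), start = list(a = seg[1], tau = tau0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  tau <- if (!is.null(fit)) coef(fit)[["tau"]] else unname(tau0)
  tau_max <- 10 * tt[length(tt)]
  if (!is.finite(tau) || tau <= 0 || tau > tau_max) tau <- unname(tau0)
  if (!is.finite(tau) || tau <= 0 || tau > tau_max) return(out)
  out$decay_tau_ms <- tau
  out
}

#' Summary statistics of detected events
#'
#' Frequency is the event count normalized per second of sweep; inter-event
#' intervals come from successive onsets.
#'
#' @param events a [detect_psc()] table (only accepted rows are used when an
#'   `accepted` column is present).
#' @param sweep_duration_s sweep length, seconds.
#' @return tibble: `n_events`, `frequency_hz`, `mean_amplitude_pa`,
#'   `mean_iei_s` (`NA` with fewer than two events), `mean_decay_tau_ms`,
#'   `mean_rise_rate_pa_per_ms`.
#' @export
event_stats <- function(events, sweep_duration_s) {
  stopifnot(sweep_duration_s > 0)
  if ("accepted" %in% names(events)) events <- filter(events, .data$accepted)
  n <- nrow(events)
  tibble(
    n_events = n,
    frequency_hz = n / sweep_duration_s,
    mean_amplitude_pa = if (n > 0) mean(events$amplitude_pa) else NA_real_,
    mean_iei_s = if (n >= 2) mean(diff(sort(events$onset_s))) else NA_real_,
    mean_decay_tau_ms = if (n > 0) mean(events$decay_tau_ms, na.rm = TRUE)
                        else NA_real_,
    mean_rise_rate_pa_per_ms = if (n > 0)
      mean(events$rise_rate_pa_per_ms, na.rm = TRUE) else NA_real_)
}

#' Charge transfer and E/I ratio
#'
#' `charge_transfer()` integrates the absolute deflection of a
#' baseline-normalized sweep by the trapezoid rule and reports nA*s;
#' `ei_ratio()` is excitatory over inhibitory charge from the same cell.
#'
#' @param sweep a baseline-normalized [new_ts()] in pA.
#' @return charge in nA*s.
#' @export
charge_transfer <- function(sweep) {
  x <- abs(sweep$data)
  dt <- 1 / sweep$rate_hz
  sum((head(x, -1) + x[-1]) / 2 * dt) / 1000     # pA*s -> nA*s
}

#' @rdname charge_transfer
#' @param q_exc,q_inh excitatory / inhibitory charge, nA*s.
#' @export
ei_ratio <- function(q_exc, q_inh) {
  if (q_inh == 0) abort("Inhibitory charge is zero; E/I ratio undefined.")
  q_exc / q_inh
}

#' Derivative-percentile onset detection
#'
#' Smooths the sweep with a 2.5 ms moving average, takes the first
#' derivative, finds local extrema of the event-onset sign (minima for
#' inward/EPSC, maxima for outward/IPSC), and keeps the extrema whose
#' magnitude is within the top `percentile` percent of all extremum
#' magnitudes. Returned times are the extremum times.
#'
#' @param sweep a single-channel [new_ts()] at the analysis rate (2 kHz).
#' @param polarity `"inward"` or `"outward"`.
#' @param percentile top-percentile of derivative-peak magnitudes to keep,
#'   in `(0, 100]`.
#' @param smooth_ms moving-average width.
#' @return onset times in seconds, sorted.
#' @export
derivative_onsets <- function(sweep, polarity = c("inward", "outward"),
                              percentile = 25, smooth_ms = 2.5) {
  polarity <- match.arg(polarity)
  if (percentile <= 0 || percentile > 100) abort("`percentile` must be in (0, 100].")
  fs <- sweep$rate_hz
  xs <- boxcar_smooth(sweep$data, max(1L, round(smooth_ms / 1000 * fs)))
  d <- diff(xs)
  sgn <- if (polarity == "inward") -1 else 1
  ds <- sgn * d                                   # onsets are maxima of ds
  n <- length(ds)
  if (n < 3) return(numeric(0))
  ext <- which(ds[2:(n - 1)] > ds[1:(n - 2)] & ds[2:(n - 1)] >= ds[3:n] &
                 ds[2:(n - 1)] > 0) + 1L
  if (length(ext) == 0) return(numeric(0))
  mag <- ds[ext]
  keep <- mag >= quantile(mag, 1 - percentile / 100, type = 7)
  sort(sweep$t0_s + (ext[keep] - 1) / fs)
}

#' Intrinsic membrane properties from current steps
#'
#' Input resistance from the -100 pA hyperpolarizing sweep (steady-state
#' deflection over injected current); action potentials detected by an
#' upward dv/dt crossing (default 20 mV/ms) plus a minimum-amplitude
#' criterion; per-AP threshold (V at the dv/dt crossing), peak, amplitude,
#' maximum dv/dt, width at half height and width at threshold; and the F-I
#' curve of AP count versus injected current.
#'
#' @param sweeps list of current-clamp [new_ts()] sweeps (mV).
#' @param protocol tibble with `step_pa`, `step_start_s`, `step_end_s`
#'   (one row per sweep).
#' @param dvdt_thresh_mv_per_ms AP detection threshold on dv/dt.
#' @param min_amp_mv minimum AP amplitude.
#' @return an `intrinsic_report` list: `vm_mv`, `rin_mohm` (`NA` and flagged
#'   when no -100 pA sweep exists), `ap_features` tibble, `fi_curve` tibble.
#' @export
intrinsic_analysis <- function(sweeps, protocol, dvdt_thresh_mv_per_ms = 20,
                               min_amp_mv = 20) {
  stopifnot(length(sweeps) == nrow(protocol))
  fs <- sweeps[[1]]$rate_hz
  pre_win <- function(sw, row) {
    i1 <- max(1, round((row$step_start_s - 0.05) * fs))
    i2 <- max(1, round(row$step_start_s * fs) - 1)
    mean(sw$data[i1:i2])
  }
  vm <- pre_win(sweeps[[1]], protocol[1, ])

  i_m100 <- which(protocol$step_pa == -100)
  rin <- NA_real_
  rin_flag <- "missing -100 pA sweep"
  if (length(i_m100) >= 1) {
    i <- i_m100[1]
    row <- protocol[i, ]
    sw <- sweeps[[i]]
    v_pre <- pre_win(sw, row)
    j1 <- round((row$step_end_s - 0.1) * fs)
    j2 <- round(row$step_end_s * fs) - 1
    v_ss <- mean(sw$data[j1:j2])
    rin <- (v_ss - v_pre) / (-100) * 1000          # mV / pA -> MOhm
    rin_flag <- NA_character_
  }

  width_at <- function(v, pk, level) {
    a <- pk; while (a > 1 && v[a - 1] > level) a <- a - 1
    b <- pk; while (b < length(v) && v[b + 1] > level) b <- b + 1
    # sub-sample interpolation of the level crossings
    fa <- if (a > 1 && v[a] != v[a - 1]) (v[a] - level) / (v[a] - v[a - 1]) else 0
    fb <- if (b < length(v) && v[b] != v[b + 1]) (v[b] - level) / (v[b] - v[b + 1]) else 0
    (b - a + fa + fb) / fs * 1000
  }
  ap_rows <- list()
  fi <- protocol |> mutate(n_aps = 0L)
  for (si in seq_along(sweeps)) {
    sw <- sweeps[[si]]
    v <- sw$data
    dv <- c(diff(v), 0) * fs / 1000               # mV/ms
    cross <- which(dv[-1] >= dvdt_thresh_mv_per_ms &
                     dv[-length(dv)] < dvdt_thresh_mv_per_ms) + 1L
    if (length(cross) > 1) cross <- cross[c(TRUE, diff(cross) > 0.002 * fs)]
    n_ok <- 0L
    for (ci in cross) {
      pk <- ci + which.max(v[ci:min(ci + round(0.004 * fs), length(v))]) - 1L
      thr_v <- v[ci]
      amp <- v[pk] - thr_v
      if (amp < min_amp_mv) next
      n_ok <- n_ok + 1L
      ap_rows[[length(ap_rows) + 1L]] <- tibble(
        sweep = si, step_pa = protocol$step_pa[si],
        time_s = sw$t0_s + (pk - 1) / fs,
        threshold_mv = thr_v, peak_mv = v[pk], amplitude_mv = amp,
        max_dvdt_mv_per_ms = max(dv[max(1, ci - 2):pk]),
        half_width_ms = width_at(v, pk, thr_v + amp / 2),
        width_at_threshold_ms = width_at(v, pk, thr_v))
    }
    fi$n_aps[si] <- n_ok
  }
  structure(
    list(vm_mv = vm, rin_mohm = rin, rin_flag = rin_flag,
         ap_features = if (length(ap_rows)) bind_rows(ap_rows) else
           tibble(sweep = integer(), step_pa = numeric(), time_s = numeric(),
                  threshold_mv = numeric(), peak_mv = numeric(),
                  amplitude_mv = numeric(), max_dvdt_mv_per_ms = numeric(),
                  half_width_ms = numeric(), width_at_threshold_ms = numeric()),
         fi_curve = select(fi, "step_pa", "n_aps")),
    class = "intrinsic_report")
}

#' @export
print.intrinsic_report <- function(x, ...) {
  cat(sprintf("<intrinsic_report> Vm %.1f mV, Rin %s MOhm, %d AP(s)\n",
              x$vm_mv, ifelse(is.na(x$rin_mohm), "NA",
                              sprintf("%.1f", x$rin_mohm)),
              nrow(x$ap_features)))
  invisible(x)
}
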