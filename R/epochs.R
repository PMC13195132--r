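#' Oscillation episodes and behavioral states
#'
#' Oscillation-episode detection in the BOSC family: Morlet time-frequency
#' power thresholded against a chi-squared criterion scaled to an aperiodic
#' (1/f) background fitted on the wavelet spectrum itself, with a minimum
#' duration in cycles. Behavioral-state segmentation from the theta/delta
#' ratio plus treadmill speed, and pure run/rest segmentation from speed.
#'
#' @name epochs
NULL

#' Morlet wavelet time-frequency power
#'
#' Complex Morlet convolution via FFT with mirrored edge padding. Kernels are
#' scaled so that a unit-amplitude sinusoid at the wavelet's center frequency
#' yields unit power.
#'
#' @param ts a single-channel [new_ts()].
#' @param freqs_hz analysis frequencies.
#' @param n_cycles wavelet width in cycles (Gaussian SD
#'   `n_cycles / (2 pi f)` seconds).
#' @return list: `power` (samples x frequencies matrix), `freqs_hz`,
#'   `rate_hz`, `n_cycles`.
#' @export
morlet_power <- function(ts, freqs_hz, n_cycles = 6) {
  x <- ts$data
  fs <- ts$rate_hz
  n <- length(x)
  npad <- min(n, round(4 * n_cycles / (2 * pi * min(freqs_hz)) * fs))
  xe <- c(rev(x[seq_len(npad)]), x, rev(x[seq(n - npad + 1, n)]))
  ne <- length(xe)
  X <- fft(xe)
  pow <- matrix(0, n, length(freqs_hz))
  for (j in seq_along(freqs_hz)) {
    f <- freqs_hz[j]
    sd_t <- n_cycles / (2 * pi * f)
    tk <- seq(-4 * sd_t, 4 * sd_t, by = 1 / fs)
    env <- exp(-tk^2 / (2 * sd_t^2))
    k <- env * exp(2i * pi * f * tk) * (2 / sum(env))
    nk <- length(k)
    K <- fft(c(k, complex(real = numeric(ne - nk))))
    w <- fft(X * K, inverse = TRUE) / ne
    shift <- (nk - 1) %/% 2
    idx <- npad + shift + seq_len(n)
    pow[, j] <- Mod(w[idx])^2
  }
  list(power = pow, freqs_hz = freqs_hz, rate_hz = fs, n_cycles = n_cycles)
}

#' Detect oscillation episodes
#'
#' Per frequency on a log-spaced grid, power must exceed the 95th percentile
#' of the chi-squared(2) distribution scaled to the aperiodic-model mean
#' power at that frequency, for at least `min_cycles` cycles. Because a
#' Morlet wavelet smears transients in time, a run's duration is corrected
#' by subtracting the wavelet envelope FWHM at that frequency before the
#' duration test, so sub-criterion transients are not promoted by detector
#' bandwidth. Supra-threshold episodes at in-band frequencies are merged
#' (union of time supports) into band-level epochs.
#'
#' @param ts a single-channel [new_ts()] LFP at the analysis rate,
#'   notch-cleaned.
#' @param band `"delta"` (1-4 Hz) or `"theta"` (4-12 Hz), or a numeric
#'   `c(lo, hi)`.
#' @param aperiodic optional [fit_aperiodic()] of the time-averaged wavelet
#'   spectrum on the same grid; computed internally when `NULL`.
#' @param min_cycles minimum episode duration in oscillation cycles.
#' @param freq_grid_hz full analysis grid (must cover the band).
#' @param n_cycles wavelet width.
#' @param percentile power threshold percentile of the chi-squared(2)
#'   background distribution.
#' @return an `osc_epochs` tibble: `band`, `start_s`, `end_s`, `n_cycles`,
#'   `mean_freq_hz`, sorted and disjoint.
#' @export
detect_osc_epochs <- function(ts, band = "theta", aperiodic = NULL,
                              min_cycles = 2,
                              freq_grid_hz = 2^seq(0, 6, by = 0.1),
                              n_cycles = 6, percentile = 0.95) {
  band_hz <- if (is.character(band)) {
    switch(band, delta = c(1, 4), theta = c(4, 12),
           abort("Unknown band name; use 'delta', 'theta' or c(lo, hi)."))
  } else band
  band_name <- if (is.character(band)) band else
    sprintf("%g-%g", band[1], band[2])
  if (band_hz[1] < min(freq_grid_hz) || band_hz[2] > max(freq_grid_hz)) {
    abort("Band outside the analysis frequency grid.")
  }
  mp <- morlet_power(ts, freq_grid_hz, n_cycles)
  if (is.null(aperiodic)) {
    meanspec <- tibble(freq_hz = freq_grid_hz, power = colMeans(mp$power))
    aperiodic <- fit_aperiodic(meanspec, fit_range_hz = range(freq_grid_hz))
  }
  fs <- ts$rate_hz
  chi_scale <- qchisq(percentile, df = 2) / 2
  inband <- which(freq_grid_hz >= band_hz[1] & freq_grid_hz <= band_hz[2])
  eps <- list()
  for (j in inband) {
    f <- freq_grid_hz[j]
    thr <- chi_scale * aperiodic_model(aperiodic, f)
    above <- mp$power[, j] > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    sd_t <- n_cycles / (2 * pi * f)
    for (k in which(r$values)) {
      dur <- r$lengths[k] / fs
      # subtract the amplitude-dependent wavelet smear: a Gaussian envelope
      # of SD sd_t stays above thr for ~2 sd_t sqrt(2 ln(Pmax/thr)) even for
      # an instantaneous transient, so that width is not oscillation time
      pmax_run <- max(mp$power[starts[k]:ends[k], j])
      smear_s <- 2 * sd_t * sqrt(2 * max(log(pmax_run / thr), 0))
      if (dur - smear_s >= min_cycles / f) {
        eps[[length(eps) + 1L]] <- tibble(
          freq_hz = f,
          start_s = ts$t0_s + (starts[k] - 1) / fs,
          end_s = ts$t0_s + ends[k] / fs,
          mean_power = mean(mp$power[starts[k]:ends[k], j]))
      }
    }
  }
  empty <- tibble(band = character(), start_s = numeric(), end_s = numeric(),
                  n_cycles = numeric(), mean_freq_hz = numeric())
  if (length(eps) == 0) return(structure(empty, class = c("osc_epochs",
                                                          class(empty))))
  ep <- arrange(bind_rows(eps), .data$start_s)
  # merge overlapping per-frequency episodes into band-level epochs
  merged <- list()
  cur <- ep[1, ]
  members <- list(ep[1, ])
  for (i in seq_len(nrow(ep))[-1]) {
    if (ep$start_s[i] <= cur$end_s) {
      cur$end_s <- max(cur$end_s, ep$end_s[i])
      members[[length(members) + 1L]] <- ep[i, ]
    } else {
      merged[[length(merged) + 1L]] <- list(cur = cur, m = bind_rows(members))
      cur <- ep[i, ]
      members <- list(ep[i, ])
    }
  }
  merged[[length(merged) + 1L]] <- list(cur = cur, m = bind_rows(members))
  out <- bind_rows(map(merged, function(g) {
    w <- g$m$mean_power * (g$m$end_s - g$m$start_s)
    mf <- sum(g$m$freq_hz * w) / sum(w)
    tibble(band = band_name, start_s = g$cur$start_s, end_s = g$cur$end_s,
           n_cycles = (g$cur$end_s - g$cur$start_s) * mf, mean_freq_hz = mf)
  }))
  structure(out, class = c("osc_epochs", class(out)))
}

# discrete prolate spheroidal sequences via the symmetric tridiagonal system
dpss_tapers <- function(n, nw, k) {
  w <- nw / n
  tvec <- seq_len(n) - 1
  dg <- ((n - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * w)
  od <- tvec[-1] * (n - tvec[-1]) / 2
  m <- diag(dg)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- od
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- od
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  }
  v
}

# multitaper band power (sum of one-sided PSD) for one window
mtm_band_power <- function(x, fs, tapers, band) {
  n <- length(x)
  nfreq <- n %/% 2 + 1
  f <- (seq_len(nfreq) - 1) * fs / n
  acc <- numeric(nfreq)
  for (j in seq_len(ncol(tapers))) {
    X <- fft(x * tapers[, j])
    acc <- acc + Mod(X[seq_len(nfreq)])^2 / fs
  }
  p <- acc / ncol(tapers)
  p[c(-1, -nfreq)] <- 2 * p[c(-1, -nfreq)]
  sel <- f >= band[1] & f <= band[2]
  sum(p[sel]) * fs / n
}

runs_to_segments <- function(labels, rate_hz, t0_s, min_dur_s = 2,
                             ambiguous = "ambiguous") {
  prune <- function(lab) {
    r <- rle(lab)
    short <- r$values != ambiguous & r$lengths < min_dur_s * rate_hz
    r$values[short] <- ambiguous
    inverse.rle(r)
  }
  lab <- prune(prune(labels))   # second pass: merged ambiguous may absorb
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  tibble(start_s = t0_s + (starts - 1) / rate_hz,
         end_s = t0_s + ends / rate_hz,
         label = r$values)
}

# sample-and-hold a speed trace onto an arbitrary time grid
speed_at <- function(speed, times) {
  idx <- pmin(pmax(floor((times - speed$t0_s) * speed$rate_hz) + 1L, 1L),
              ts_n(speed))
  speed$data[idx]
}

#' Theta / non-theta state segmentation
#'
#' Sliding-window multitaper estimates (1.6 s window, 0.8 s step, NW = 3)
#' of theta (4-12 Hz) and delta (2-4 Hz; narrower than the spectral-analysis
#' delta on purpose) band power give a theta/delta (T/D) ratio that is
#' linearly interpolated to sample times. Theta requires `T/D > 2` and speed
#' > 5 cm/s, non-theta `T/D < 2` and speed < 1 cm/s; all else is ambiguous,
#' and non-ambiguous segments shorter than 2 s are discarded (relabelled
#' ambiguous). The LFP is decimated internally to 250 Hz for the window
#' spectra; theta and delta lie far below that Nyquist.
#'
#' @param lfp a single-channel [new_ts()] LFP at 2 kHz.
#' @param speed a 50 Hz speed trace [new_ts()] covering the LFP (aligned by
#'   sample-and-hold).
#' @param window_s,step_s sliding-window geometry.
#' @param nw time-bandwidth product; `2 nw - 1` tapers are used.
#' @param td_thresh T/D ratio threshold.
#' @param run_speed,rest_speed speed thresholds, cm/s.
#' @param min_dur_s minimum segment duration.
#' @return tibble (`start_s`, `end_s`, `label`) with labels `theta`,
#'   `non_theta`, `ambiguous`, partitioning the analyzed span.
#' @export
theta_state_segments <- function(lfp, speed, window_s = 1.6, step_s = 0.8,
                                 nw = 3, td_thresh = 2, run_speed = 5,
                                 rest_speed = 1, min_dur_s = 2) {
  if (ts_duration(speed) + speed$t0_s < ts_duration(lfp) + lfp$t0_s - 1 / speed$rate_hz) {
    abort("Speed trace does not cover the LFP.")
  }
  fs_int <- 250
  x <- if (lfp$rate_hz > fs_int) downsample(lfp, fs_int) else lfp
  fs <- x$rate_hz
  nper <- round(window_s * fs)
  k <- 2 * nw - 1
  tapers <- dpss_tapers(nper, nw, k)
  starts <- seq(1L, ts_n(x) - nper + 1L, by = max(1L, round(step_s * fs)))
  centers <- x$t0_s + (starts - 1 + nper / 2) / fs
  td <- map_dbl(starts, function(s) {
    seg <- x$data[s:(s + nper - 1L)]
    th <- mtm_band_power(seg, fs, tapers, c(4, 12))
    de <- mtm_band_power(seg, fs, tapers, c(2, 4))
    if (de <= 0) Inf else th / de
  })
  tgrid <- ts_times(x)
  td_t <- approx(centers, td, xout = tgrid, rule = 2)$y
  sp_t <- speed_at(speed, tgrid)
  lab <- ifelse(td_t > td_thresh & sp_t > run_speed, "theta",
                ifelse(td_t < td_thresh & sp_t < rest_speed, "non_theta",
                       "ambiguous"))
  runs_to_segments(lab, fs, x$t0_s, min_dur_s)
}

#' Run / rest segmentation from treadmill speed
#'
#' Running requires speed > 5 cm/s, resting < 1 cm/s; 1-5 cm/s is ambiguous
#' and excluded from both states. Non-ambiguous segments shorter than 2 s
#' are discarded.
#'
#' @param speed a 50 Hz speed trace [new_ts()] (cm/s, non-negative).
#' @param run_speed,rest_speed thresholds, cm/s.
#' @param min_dur_s minimum segment duration.
#' @return tibble (`start_s`, `end_s`, `label`) with labels `running`,
#'   `resting`, `ambiguous`.
#' @export
run_rest_segments <- function(speed, run_speed = 5, rest_speed = 1,
                              min_dur_s = 2) {
  if (any(speed$data < 0)) abort("Negative speeds are invalid.")
  lab <- ifelse(speed$data > run_speed, "running",
                ifelse(speed$data < rest_speed, "resting", "ambiguous"))
  runs_to_segments(lab, speed$rate_hz, speed$t0_s, min_dur_s)
}
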