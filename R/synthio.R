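#' Synthetic data with ground truth
#'
#' Generators for every signal class the pipeline consumes: 1/f LFP with
#' band-limited oscillations, mains lines and injected ripple transients;
#' voltage-clamp sweeps with biexponential postsynaptic-current kernels at
#' Poisson or phase-locked event times; spike trains with parameterized
#' bursts and theta-rate modulation; block-structured run/rest speed traces;
#' and stepwise current-clamp sweeps with a stereotyped action-potential
#' template. Each generator returns the signal together with the ground
#' truth needed to score its matched detector. Fixed seed gives bit-identical
#' output; no global RNG state leaks (the caller's `.Random.seed` is
#' restored).
#'
#' @name synthio
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' LFP generation spec
#'
#' @param duration_s,rate_hz length and sampling rate.
#' @param aperiodic_offset log10-power offset of the 1/f background.
#' @param aperiodic_exponent exponent chi of the `1/f^chi` background (>= 0).
#' @param oscillations tibble/data.frame with columns `freq_hz`, `amp`,
#'   `bandwidth_hz` (0 gives an amplitude-stable sinusoid; positive values add
#'   Gaussian spectral broadening via slow phase diffusion); optional
#'   `start_s`/`end_s` columns confine an oscillation to a time window with
#'   smooth cosine ramps.
#' @param mains tibble with `freq_hz`, `amp` for line interference.
#' @param ripples optional list `(n, freq_hz, duration_ms, snr)` of transient
#'   oscillation bursts to inject; `snr` is the peak ripple envelope over the
#'   RMS of the 100-250 Hz band of the background. An optional `window_s =
#'   c(lo, hi)` restricts placement.
#' @param seed integer RNG seed.
#' @return a spec list for [gen_lfp()].
#' @export
lfp_spec <- function(duration_s, rate_hz, aperiodic_offset = 0,
                     aperiodic_exponent = 1, oscillations = NULL,
                     mains = NULL, ripples = NULL, seed = 1) {
  stopifnot(duration_s > 0, rate_hz > 0, aperiodic_exponent >= 0)
  fmax <- c(if (!is.null(oscillations)) oscillations$freq_hz,
            if (!is.null(mains)) mains$freq_hz,
            if (!is.null(ripples)) ripples$freq_hz)
  if (length(fmax) && rate_hz < 2 * max(fmax)) {
    abort("Sampling rate below Nyquist of a requested component.")
  }
  list(duration_s = duration_s, rate_hz = rate_hz,
       aperiodic_offset = aperiodic_offset,
       aperiodic_exponent = aperiodic_exponent,
       oscillations = oscillations, mains = mains, ripples = ripples,
       seed = seed)
}

# one-sided aperiodic PSD model of the generator, units^2/Hz
lfp_psd_model <- function(spec, f) {
  p <- 10^spec$aperiodic_offset / f^spec$aperiodic_exponent
  p[f <= 0] <- 0
  p
}

#' Generate an LFP trace
#'
#' The aperiodic background is synthesized by spectral shaping of white
#' noise (the FFT magnitude is multiplied by `f^(-chi/2)`), so the target
#' log-log slope is exact in expectation. Oscillations are amplitude-stable
#' sinusoids with optional phase-diffusion broadening; ripples are
#' Hann-windowed tone bursts at uniformly drawn, non-overlapping times.
#'
#' @param spec an [lfp_spec()].
#' @return a list with `ts` (an [new_ts()], microvolts) and `truth`
#'   (list with `ripple_windows` tibble: `start_s`, `end_s`, `peak_s`).
#' @export
gen_lfp <- function(spec) {
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$rate_hz)
    fs <- spec$rate_hz
    t <- (seq_len(n) - 1) / fs
    # spectrally shaped background
    z <- rnorm(n)
    fk <- (seq_len(n) - 1) * fs / n
    f2 <- pmin(fk, fs - fk)                      # two-sided frequency
    h <- sqrt(lfp_psd_model(spec, f2) * fs / 2)
    h[1] <- 0
    x <- Re(fft(fft(z) * h, inverse = TRUE)) / n
    # oscillations
    if (!is.null(spec$oscillations)) {
      for (i in seq_len(nrow(spec$oscillations))) {
        o <- spec$oscillations[i, ]
        ph0 <- runif(1, 0, 2 * pi)
        ph <- 2 * pi * o$freq_hz * t + ph0
        if (o$bandwidth_hz > 0) {
          d <- pi * o$bandwidth_hz                # Lorentzian linewidth rad^2/s
          ph <- ph + cumsum(rnorm(n, 0, sqrt(d / fs)))
        }
        w <- rep(1, n)
        if (!is.null(o$start_s) && is.finite(o$start_s)) {
          # smooth half-second cosine ramps confine the oscillation in time
          # without the broadband splice transient a hard gate would create
          ramp <- 0.5
          w <- pmin(1, pmax(0, (t - o$start_s) / ramp)) *
            pmin(1, pmax(0, (o$end_s - t) / ramp))
          w <- (1 - cos(pi * w)) / 2
        }
        x <- x + o$amp * w * cos(ph)
      }
    }
    if (!is.null(spec$mains)) {
      for (i in seq_len(nrow(spec$mains))) {
        m <- spec$mains[i, ]
        x <- x + m$amp * sin(2 * pi * m$freq_hz * t + runif(1, 0, 2 * pi))
      }
    }
    ripple_windows <- tibble(start_s = numeric(), end_s = numeric(),
                             peak_s = numeric())
    if (!is.null(spec$ripples) && spec$ripples$n > 0) {
      rp <- spec$ripples
      dur <- rp$duration_ms / 1000
      # band RMS of the background from the analytic PSD
      fgrid <- seq(100, 250, by = 1)
      band_rms <- sqrt(sum(lfp_psd_model(spec, fgrid)) * 1)
      amp <- rp$snr * band_rms
      t_lo <- if (is.null(rp$window_s)) 0.5 else rp$window_s[1]
      t_hi <- if (is.null(rp$window_s)) spec$duration_s - 0.5 else rp$window_s[2]
      starts <- sort(runif(rp$n, t_lo, t_hi - dur))
      # enforce a gap of 4 durations between consecutive events
      keep <- c(TRUE, diff(starts) > 4 * dur)
      while (!all(keep)) {
        starts <- starts[keep]
        extra <- runif(rp$n - length(starts), t_lo, t_hi - dur)
        starts <- sort(c(starts, extra))
        keep <- c(TRUE, diff(starts) > 4 * dur)
      }
      for (s in starts) {
        idx <- which(t >= s & t < s + dur)
        tt <- t[idx] - s
        win <- 0.5 - 0.5 * cos(2 * pi * tt / dur)   # Hann envelope
        x[idx] <- x[idx] + amp * win * sin(2 * pi * rp$freq_hz * tt)
      }
      ripple_windows <- tibble(start_s = starts, end_s = starts + dur,
                               peak_s = starts + dur / 2)
    }
    list(ts = new_ts(x, fs, units = "uV"),
         truth = list(ripple_windows = ripple_windows))
  })
}

#' Voltage-clamp sweep spec
#'
#' @param duration_s,rate_hz length and sampling rate.
#' @param polarity `"inward"` (EPSC at -70 mV, downward) or `"outward"`
#'   (IPSC at +10 mV, upward).
#' @param event_rate_hz mean event rate.
#' @param amp_mean_pa,amp_sd_pa event amplitude distribution (truncated > 1 pA).
#' @param rise_ms,decay_ms biexponential kernel time constants; rise < decay.
#' @param noise_sd_pa Gaussian noise SD.
#' @param drift_pa_per_s linear drift slope.
#' @param locking optional list `(carrier_freq_hz, kappa, preferred_phase_rad)`
#'   for von Mises phase-locked event times.
#' @param seed integer RNG seed.
#' @export
psc_sweep_spec <- function(duration_s = 30, rate_hz = 2000,
                           polarity = c("inward", "outward"),
                           event_rate_hz = 5, amp_mean_pa = 20, amp_sd_pa = 5,
                           rise_ms = 0.8, decay_ms = 6, noise_sd_pa = 2,
                           drift_pa_per_s = 0, locking = NULL, seed = 1) {
  polarity <- match.arg(polarity)
  stopifnot(rise_ms < decay_ms, amp_mean_pa > 0, event_rate_hz >= 0)
  if (!is.null(locking)) stopifnot(locking$kappa >= 0)
  list(duration_s = duration_s, rate_hz = rate_hz, polarity = polarity,
       event_rate_hz = event_rate_hz, amp_mean_pa = amp_mean_pa,
       amp_sd_pa = amp_sd_pa, rise_ms = rise_ms, decay_ms = decay_ms,
       noise_sd_pa = noise_sd_pa, drift_pa_per_s = drift_pa_per_s,
       locking = locking, seed = seed)
}

# unit-peak biexponential kernel
psc_kernel <- function(rate_hz, rise_ms, decay_ms, len_factor = 8) {
  tr <- rise_ms / 1000; td <- decay_ms / 1000
  tt <- seq(0, len_factor * td, by = 1 / rate_hz)
  k <- exp(-tt / td) - exp(-tt / tr)
  k / max(k)
}

#' Generate a voltage-clamp sweep of spontaneous PSCs
#'
#' Event times are homogeneous Poisson, or — when `locking` is set — an
#' oscillation-phase-modulated Poisson process thinned so that event phases
#' follow a von Mises distribution around the preferred phase. The carrier
#' phase convention is the analytic-signal (cosine) convention used by
#' [instantaneous_phase()], so generator and detector agree.
#'
#' @param spec a [psc_sweep_spec()].
#' @param carrier optional [new_ts()] narrowband carrier; when `NULL` and
#'   `locking` is set, an internal cosine at `carrier_freq_hz` is used.
#' @return list with `ts` (pA) and `truth`: tibble `events`
#'   (`time_s`, `amp_pa`, and `phase_rad` when locked).
#' @export
gen_psc_sweep <- function(spec, carrier = NULL) {
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$rate_hz)
    fs <- spec$rate_hz
    t <- (seq_len(n) - 1) / fs
    sgn <- if (spec$polarity == "inward") -1 else 1

    if (is.null(spec$locking) || spec$event_rate_hz == 0) {
      n_ev <- rpois(1, spec$event_rate_hz * spec$duration_s)
      times <- sort(runif(n_ev, 0, spec$duration_s))
      phases <- rep(NA_real_, n_ev)
    } else {
      lk <- spec$locking
      if (is.null(carrier)) {
        phase_t <- (2 * pi * lk$carrier_freq_hz * t + pi) %% (2 * pi) - pi
      } else {
        stopifnot(carrier$rate_hz == fs)
        phase_t <- as.numeric(Arg(analytic_signal(carrier$data)))
      }
      if (is.infinite(lk$kappa)) {
        cand <- which(abs(circ_diff(phase_t, lk$preferred_phase_rad)) <=
                        pi / 1000)
        cand <- cand[c(TRUE, diff(cand) > 1)]
        n_ev <- min(rpois(1, spec$event_rate_hz * spec$duration_s), length(cand))
        times <- sort(t[sample(cand, n_ev)])
        phases <- rep(lk$preferred_phase_rad, n_ev)
      } else {
        w <- exp(lk$kappa * cos(phase_t - lk$preferred_phase_rad))
        w <- w / mean(w)
        lmax <- spec$event_rate_hz * max(w)
        n_cand <- rpois(1, lmax * spec$duration_s)
        cand <- sort(runif(n_cand, 0, spec$duration_s))
        ci <- pmin(floor(cand * fs) + 1, n)
        keep <- runif(n_cand) < spec$event_rate_hz * w[ci] / lmax
        times <- cand[keep]
        phases <- phase_t[ci[keep]]
      }
    }
    amps <- pmax(rnorm(length(times), spec$amp_mean_pa, spec$amp_sd_pa), 1)
    x <- rnorm(n, 0, spec$noise_sd_pa) + spec$drift_pa_per_s * t
    if (length(times)) {
      k <- psc_kernel(fs, spec$rise_ms, spec$decay_ms)
      for (i in seq_along(times)) {
        i0 <- floor(times[i] * fs) + 1
        idx <- i0:min(i0 + length(k) - 1, n)
        x[idx] <- x[idx] + sgn * amps[i] * k[seq_along(idx)]
      }
    }
    truth <- tibble(time_s = times, amp_pa = amps, phase_rad = phases)
    list(ts = new_ts(x, fs, units = "pA"), truth = list(events = truth))
  })
}

#' Spike-train spec
#'
#' @param duration_s recording length.
#' @param base_rate_hz background (non-burst) firing rate.
#' @param burst_rate_hz rate of burst events.
#' @param spikes_per_burst named probability vector over spike counts >= 3,
#'   e.g. `c("3" = 0.6, "4" = 0.3, "5" = 0.1)`.
#' @param intra_burst_isi_ms within-burst inter-spike interval.
#' @param theta_mod optional list `(freq_hz, depth, preferred_phase_rad)` for
#'   sinusoidal rate modulation (`depth` in `[0, 1]`).
#' @param refractory_ms absolute refractory period (> 0).
#' @param seed integer RNG seed.
#' @export
spike_train_spec <- function(duration_s = 600, base_rate_hz = 2,
                             burst_rate_hz = 0,
                             spikes_per_burst = c("3" = 1),
                             intra_burst_isi_ms = 3, theta_mod = NULL,
                             refractory_ms = 2, seed = 1) {
  stopifnot(refractory_ms > 0, burst_rate_hz >= 0, base_rate_hz >= 0)
  stopifnot(abs(sum(spikes_per_burst) - 1) < 1e-9)
  list(duration_s = duration_s, base_rate_hz = base_rate_hz,
       burst_rate_hz = burst_rate_hz, spikes_per_burst = spikes_per_burst,
       intra_burst_isi_ms = intra_burst_isi_ms, theta_mod = theta_mod,
       refractory_ms = refractory_ms, seed = seed)
}

#' Generate a spike train with parameterized bursts
#'
#' Background spikes are a (possibly theta-modulated) Poisson process with an
#' absolute refractory period; bursts are inserted at Poisson event times as
#' runs of `n >= 3` spikes at the intra-burst interval. Background spikes
#' falling within a burst's guarded window are removed so that ground-truth
#' burst windows stay exact.
#'
#' @param spec a [spike_train_spec()].
#' @return list with `spike_times` (sorted, seconds) and `truth`: tibble
#'   `burst_windows` (`start_s`, `end_s`, `n_spikes`).
#' @export
gen_spike_train <- function(spec) {
  with_seed(spec$seed, {
    dur <- spec$duration_s
    refr <- spec$refractory_ms / 1000
    # background: thinned Poisson with refractory
    bg <- numeric(0)
    if (spec$base_rate_hz > 0) {
      depth <- if (is.null(spec$theta_mod)) 0 else spec$theta_mod$depth
      lmax <- spec$base_rate_hz * (1 + depth)
      cand <- sort(runif(rpois(1, lmax * dur), 0, dur))
      if (length(cand)) {
        if (depth > 0) {
          tm <- spec$theta_mod
          lam <- spec$base_rate_hz *
            (1 + depth * cos(2 * pi * tm$freq_hz * cand - tm$preferred_phase_rad))
          cand <- cand[runif(length(cand)) < lam / lmax]
        }
        bg <- cand[c(TRUE, diff(cand) >= refr)]
        while (any(diff(bg) < refr)) bg <- bg[c(TRUE, diff(bg) >= refr)]
      }
    }
    burst_windows <- tibble(start_s = numeric(), end_s = numeric(),
                            n_spikes = integer())
    burst_spikes <- numeric(0)
    if (spec$burst_rate_hz > 0) {
      isi <- spec$intra_burst_isi_ms / 1000
      nb <- rpois(1, spec$burst_rate_hz * dur)
      counts <- as.integer(names(spec$spikes_per_burst))[
        sample.int(length(spec$spikes_per_burst), nb, replace = TRUE,
                   prob = spec$spikes_per_burst)]
      maxlen <- max(c(counts, 3)) * isi
      starts <- sort(runif(nb, 0, dur - maxlen))
      keep <- c(TRUE, diff(starts) > maxlen + 0.1)   # keep bursts separated
      starts <- starts[keep]; counts <- counts[keep]
      for (i in seq_along(starts)) {
        sp <- starts[i] + (seq_len(counts[i]) - 1) * isi
        burst_spikes <- c(burst_spikes, sp)
      }
      burst_windows <- tibble(start_s = starts,
                              end_s = starts + (counts - 1) * isi,
                              n_spikes = counts)
      # guard background spikes away from bursts
      if (length(bg) && nrow(burst_windows)) {
        guard <- 0.006
        bad <- rep(FALSE, length(bg))
        for (i in seq_len(nrow(burst_windows))) {
          bad <- bad | (bg >= burst_windows$start_s[i] - guard &
                          bg <= burst_windows$end_s[i] + guard)
        }
        bg <- bg[!bad]
      }
    }
    list(spike_times = sort(c(bg, burst_spikes)),
         truth = list(burst_windows = burst_windows))
  })
}

#' Generate a treadmill speed trace
#'
#' Block-structured run/rest trace at 50 samples/s with Gaussian jitter,
#' clipped at zero.
#'
#' @param blocks tibble/data.frame with columns `duration_s`, `mean_speed`
#'   (cm/s, non-negative).
#' @param noise_sd jitter SD, cm/s.
#' @param seed integer RNG seed.
#' @param rate_hz output sampling rate (50 Hz motion sensor).
#' @return list with `ts` (cm/s) and `truth`: tibble `state_blocks`
#'   (`start_s`, `end_s`, `label`), labelled by the run (>5 cm/s) / rest
#'   (<1 cm/s) thresholds with everything between ambiguous.
#' @export
gen_speed_trace <- function(blocks, noise_sd = 0.2, seed = 1, rate_hz = 50) {
  if (nrow(blocks) == 0) abort("`blocks` must be nonempty.")
  if (any(blocks$mean_speed < 0)) abort("Negative speeds are not allowed.")
  with_seed(seed, {
    vals <- unlist(map(seq_len(nrow(blocks)), function(i) {
      nb <- round(blocks$duration_s[i] * rate_hz)
      pmax(blocks$mean_speed[i] + rnorm(nb, 0, noise_sd), 0)
    }))
    ends <- cumsum(blocks$duration_s)
    truth <- tibble(
      start_s = c(0, head(ends, -1)), end_s = ends,
      label = ifelse(blocks$mean_speed > 5, "running",
                     ifelse(blocks$mean_speed < 1, "resting", "ambiguous")))
    list(ts = new_ts(vals, rate_hz, units = "cm/s"),
         truth = list(state_blocks = truth))
  })
}

# Gaussian SD (seconds) such that the half-width measured by the intrinsic
# analysis convention (threshold at the rising dv/dt crossing, width at
# threshold + amplitude/2) equals the template's nominal half-width.
ap_sigma_s <- function(amp_mv, half_width_ms, dvdt_thresh_mv_per_ms = 20) {
  width_of <- function(sigma_ms) {
    # rising-edge dv/dt crossing of A*exp(-u^2/2): largest root of
    # (A u / sigma) exp(-u^2/2) = thresh
    f <- function(u) amp_mv * u / sigma_ms * exp(-u^2 / 2) - dvdt_thresh_mv_per_ms
    u <- tryCatch(stats::uniroot(f, c(1, 10))$root, error = function(e) 3)
    thr_rel <- amp_mv * exp(-u^2 / 2)
    level <- thr_rel + (amp_mv - thr_rel) / 2
    2 * sigma_ms * sqrt(2 * log(amp_mv / level))
  }
  g <- function(sigma_ms) width_of(sigma_ms) - half_width_ms
  sig <- tryCatch(stats::uniroot(g, c(half_width_ms / 6, half_width_ms))$root,
                  error = function(e) half_width_ms / (2 * sqrt(2 * log(2))))
  sig / 1000
}

#' Generate current-clamp step sweeps
#'
#' Membrane responses to stepwise current injection: hyperpolarizing steps
#' deflect by `I x Rin` with a single membrane time constant; suprathreshold
#' steps emit stereotyped action potentials (Gaussian waveform rising from
#' the depolarized steady state to `peak_mv`, width set by
#' `half_width_ms`) at a rate increasing linearly with current above
#' rheobase.
#'
#' @param rin_mohm input resistance, megaohm.
#' @param vm_mv resting membrane potential, mV.
#' @param step_pa_list injected currents, pA (one sweep per entry).
#' @param ap_template list `(threshold_mv, peak_mv, half_width_ms)`.
#' @param rate_hz sampling rate.
#' @param pre_s,step_s,post_s sweep timing (baseline, step, tail).
#' @param tau_m_ms membrane time constant.
#' @param rheobase_pa current at which firing starts.
#' @param fi_gain_hz_per_pa firing-rate gain above rheobase.
#' @param noise_sd_mv additive noise.
#' @param seed integer RNG seed.
#' @return list with `sweeps` (list of [new_ts()], mV, each carrying its
#'   injected current as attribute `step_pa`), `protocol` tibble
#'   (`step_pa`, `step_start_s`, `step_end_s`, `n_aps`), and the template.
#' @export
gen_currentclamp_sweeps <- function(rin_mohm, vm_mv, step_pa_list,
                                    ap_template = list(threshold_mv = -45,
                                                       peak_mv = 35,
                                                       half_width_ms = 0.8),
                                    rate_hz = 20000, pre_s = 0.2, step_s = 0.5,
                                    post_s = 0.2, tau_m_ms = 15,
                                    rheobase_pa = 50,
                                    fi_gain_hz_per_pa = 0.2,
                                    noise_sd_mv = 0.1, seed = 1) {
  with_seed(seed, {
    n <- round((pre_s + step_s + post_s) * rate_hz)
    t <- (seq_len(n) - 1) / rate_hz
    in_step <- t >= pre_s & t < pre_s + step_s
    tau <- tau_m_ms / 1000
    sweeps <- list()
    n_aps <- integer(length(step_pa_list))
    for (si in seq_along(step_pa_list)) {
      i_pa <- step_pa_list[si]
      dv <- i_pa * rin_mohm * 1e-3                  # pA x MOhm -> mV
      v <- rep(vm_mv, n)
      tt <- t[in_step] - pre_s
      v[in_step] <- vm_mv + dv * (1 - exp(-tt / tau))
      after <- t >= pre_s + step_s
      v[after] <- vm_mv + dv * (exp(-(t[after] - pre_s - step_s) / tau)) *
        (1 - exp(-step_s / tau))
      if (i_pa > rheobase_pa) {
        rate <- fi_gain_hz_per_pa * (i_pa - rheobase_pa)
        k <- max(1L, round(rate * step_s))
        ap_times <- pre_s + (seq_len(k) - 0.5) * step_s / k
        v_ss <- vm_mv + dv
        sigma_s <- ap_sigma_s(ap_template$peak_mv - v_ss,
                              ap_template$half_width_ms)
        for (t0 in ap_times) {
          w <- (ap_template$peak_mv - v_ss) *
            exp(-(t - t0)^2 / (2 * sigma_s^2))
          v <- v + w
        }
        n_aps[si] <- k
      }
      v <- v + rnorm(n, 0, noise_sd_mv)
      sw <- new_ts(v, rate_hz, units = "mV")
      attr(sw, "step_pa") <- i_pa
      sweeps[[si]] <- sw
    }
    protocol <- tibble(step_pa = step_pa_list, step_start_s = pre_s,
                       step_end_s = pre_s + step_s, n_aps = n_aps)
    list(sweeps = sweeps, protocol = protocol, ap_template = ap_template,
         rin_mohm = rin_mohm, vm_mv = vm_mv)
  })
}
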