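#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window, one-sided density
#' scaling. The frequency step is set by zero-padding each segment to
#' `rate / step_hz` points, mirroring the conventional `pwelch(window, step,
#' overlap)` parameterization. Defaults match the LFP analysis (10 s window,
#' 0.1 Hz step, 50% overlap); synaptic-current spectra use 2 s / 0.5 Hz / 90%.
#'
#' @param ts an [new_ts()] single-channel signal.
#' @param window_s segment length in seconds.
#' @param overlap_frac fractional overlap between segments, in `[0, 1)`.
#' @param step_hz frequency grid step; must not exceed `1 / window_s`.
#' @return a `hippo_spectrum`: a tibble with columns `freq_hz` and `power`
#'   (signal-units^2 per Hz), with the estimation parameters as attributes.
#' @export
welch_psd <- function(ts, window_s = 10, overlap_frac = 0.5, step_hz = 0.1) {
  x <- ts$data
  if (is.matrix(x)) abort("`welch_psd()` expects a single-channel signal.")
  fs <- ts$rate_hz
  nper <- round(window_s * fs)
  if (nper > length(x)) abort("Window longer than the signal.")
  nfft <- max(nper, round(fs / step_hz))
  hop <- max(1L, nper - floor(nper * overlap_frac))
  starts <- seq(1L, length(x) - nper + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / nper)   # periodic Hann
  u <- fs * sum(w^2)                                     # density scale
  nfreq <- nfft %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)] * w
    X <- fft(c(seg, numeric(nfft - nper)))
    acc <- acc + (Mod(X[seq_len(nfreq)])^2) / u
  }
  p <- acc / length(starts)
  p[c(-1L, -nfreq)] <- 2 * p[c(-1L, -nfreq)]            # one-sided
  out <- tibble(freq_hz = (seq_len(nfreq) - 1L) * fs / nfft, power = p)
  structure(out, window_s = window_s, overlap_frac = overlap_frac,
            step_hz = fs / nfft, rate_hz = fs,
            class = c("hippo_spectrum", class(out)))
}

#' Repair mains-contaminated spectral bins
#'
#' Replaces power bins within `halfwidth_hz` of each line frequency by the
#' mean of the nearest clean bins on either side (a single neighbor at grid
#' edges). All other bins are untouched.
#'
#' @param spec a spectrum tibble (`freq_hz`, `power`).
#' @param line_freqs_hz contaminated frequencies, Hz.
#' @param halfwidth_hz contamination half-width around each line, Hz.
#' @return the repaired spectrum, same shape and attributes.
#' @export
repair_line_bins <- function(spec, line_freqs_hz = c(50, 100, 150, 250),
                             halfwidth_hz = 1) {
  f <- spec$freq_hz
  p <- spec$power
  bad <- rep(FALSE, length(f))
  for (lf in line_freqs_hz) bad <- bad | abs(f - lf) <= halfwidth_hz
  if (any(bad)) {
    runs <- rle(bad)
    idx <- cumsum(runs$lengths)
    start <- c(1L, head(idx, -1L) + 1L)
    for (k in which(runs$values)) {
      lo <- start[k] - 1L
      hi <- idx[k] + 1L
      flank <- c(if (lo >= 1L) p[lo], if (hi <= length(p)) p[hi])
      p[start[k]:idx[k]] <- mean(flank)
    }
  }
  spec$power <- p
  spec
}

gaussian_log <- function(f, center, height, sd) {
  height * exp(-(f - center)^2 / (2 * sd^2))
}

peaks_model <- function(f, peaks) {
  if (nrow(peaks) == 0) return(numeric(length(f)))
  Reduce(`+`, pmap(peaks[, c("center_hz", "height_log10", "sd_hz")],
                   function(center_hz, height_log10, sd_hz)
                     gaussian_log(f, center_hz, height_log10, sd_hz)))
}

#' Aperiodic (1/f) spectral parameterization
#'
#' Fits the fixed (knee-free) aperiodic model `log10 P(f) = offset -
#' exponent * log10 f` to a power spectrum, detects up to `max_peaks`
#' Gaussian peaks on the flattened spectrum, and returns the peak-only
#' residual spectrum `max(P - 10^model, 0)` on the full input grid (the
#' aperiodic model is extrapolated below the fit range, down to the lowest
#' positive frequency, so the slow band can be integrated).
#'
#' The aperiodic fit is made robust to peaks by refitting on the bins whose
#' positive residual from an initial least-squares fit is at or below its
#' 2.5th percentile; peaks are then detected iteratively wherever the
#' flattened spectrum exceeds `peak_threshold_sd` standard deviations,
#' fitted as bounded Gaussians, subtracted, and finally the aperiodic
#' component is refitted on the peak-removed spectrum.
#'
#' @param spec a spectrum tibble (`freq_hz`, `power`), line bins repaired.
#' @param fit_range_hz frequency range of the aperiodic fit (default 1-100 Hz).
#' @param peak_threshold_sd relative peak detection threshold, in SD of the
#'   flattened spectrum.
#' @param max_peaks maximum number of Gaussian peaks.
#' @param peak_width_hz allowed peak full-width-at-half-maximum bounds, Hz.
#' @param min_peak_height absolute minimum peak height, log10-power units;
#'   guards against fitting estimator noise as periodic structure.
#' @return an `aperiodic_fit` object: offset, exponent, a `peaks` tibble
#'   (`center_hz`, `height_log10`, `width_hz`), and `residual`, the peak-only
#'   spectrum. Has [tidy()] and [glance()] methods.
#' @export
fit_aperiodic <- function(spec, fit_range_hz = c(1, 100),
                          peak_threshold_sd = 2, max_peaks = 6,
                          peak_width_hz = c(0.5, 12),
                          min_peak_height = 0.1) {
  sel <- spec$freq_hz >= fit_range_hz[1] & spec$freq_hz <= fit_range_hz[2]
  f <- spec$freq_hz[sel]
  p <- spec$power[sel]
  if (length(f) < 8) abort("Spectrum does not cover the fit range.")
  if (any(p <= 0)) abort("Non-positive power inside the fit range; log undefined.")
  lf <- log10(f)
  lp <- log10(p)

  ap_fit <- function(keep) {
    co <- coef(lm(lp[keep] ~ lf[keep]))
    c(offset = unname(co[1]), exponent = unname(-co[2]))
  }
  ap0 <- ap_fit(rep(TRUE, length(f)))
  resid0 <- pmax(lp - (ap0["offset"] - ap0["exponent"] * lf), 0)
  thr <- quantile(resid0, 0.025)
  ap1 <- ap_fit(resid0 <= thr)

  sd_bounds <- peak_width_hz / (2 * sqrt(2 * log(2)))   # FWHM -> Gaussian SD
  flat <- lp - (ap1["offset"] - ap1["exponent"] * lf)
  # the detection threshold is frozen at the initial flattened spectrum's
  # scale; recomputing it after each subtraction would chase ever-smaller
  # noise wiggles
  height_min <- max(peak_threshold_sd * sd(flat), min_peak_height)
  peaks <- tibble(center_hz = numeric(), height_log10 = numeric(),
                  sd_hz = numeric())
  for (k in seq_len(max_peaks)) {
    i <- which.max(flat)
    h <- flat[i]
    if (h < height_min || h <= 0) break
    # half-height extent as the width guess
    above <- flat >= h / 2
    run <- which(above)
    j0 <- i; while (j0 > 1 && above[j0 - 1]) j0 <- j0 - 1
    j1 <- i; while (j1 < length(f) && above[j1 + 1]) j1 <- j1 + 1
    sd_guess <- max(min((f[j1] - f[j0]) / 2.355, sd_bounds[2]), sd_bounds[1])
    obj <- function(par) sum((flat - gaussian_log(f, par[1], par[2], par[3]))^2)
    fit <- optim(c(f[i], h, sd_guess), obj, method = "L-BFGS-B",
                 lower = c(max(f[i] - 2 * sd_guess, f[1]), 0.5 * h, sd_bounds[1]),
                 upper = c(min(f[i] + 2 * sd_guess, f[length(f)]), 1.5 * h,
                           sd_bounds[2]))
    # edge guard: a "peak" hugging the fit-range boundary is an aperiodic
    # misfit artifact, not periodic structure; it is neither kept nor
    # subtracted (its support would otherwise distort the offset strongly)
    at_edge <- fit$par[1] - fit$par[3] < f[1] ||
      fit$par[1] + fit$par[3] > f[length(f)]
    if (!at_edge && fit$par[2] >= height_min) {
      peaks <- bind_rows(peaks, tibble(center_hz = fit$par[1],
                                       height_log10 = fit$par[2],
                                       sd_hz = fit$par[3]))
      flat <- flat - gaussian_log(f, fit$par[1], fit$par[2], fit$par[3])
    } else {
      # flatten just the offending bin so iteration can move on
      flat[i] <- 0
    }
  }

  lp_nopk <- lp - peaks_model(f, peaks)
  co <- coef(lm(lp_nopk ~ lf))
  offset <- unname(co[1]); exponent <- unname(-co[2])

  fpos <- spec$freq_hz > 0
  model_lin <- numeric(nrow(spec))
  model_lin[fpos] <- 10^(offset - exponent * log10(spec$freq_hz[fpos]))
  residual <- spec
  residual$power <- pmax(spec$power - model_lin, 0)
  residual$power[!fpos] <- 0

  structure(
    list(offset = offset, exponent = exponent, fit_range_hz = fit_range_hz,
         peaks = mutate(peaks, width_hz = .data$sd_hz * 2 * sqrt(2 * log(2))),
         residual = residual, aperiodic_power = {
           m <- spec; m$power <- model_lin; m
         }),
    class = "aperiodic_fit"
  )
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> offset %.3f, exponent %.3f (fit %g-%g Hz), %d peak%s\n",
              x$offset, x$exponent, x$fit_range_hz[1], x$fit_range_hz[2],
              nrow(x$peaks), if (nrow(x$peaks) == 1) "" else "s"))
  if (nrow(x$peaks) > 0) print(x$peaks)
  invisible(x)
}

#' Evaluate the fitted aperiodic model
#'
#' @param fit an [fit_aperiodic()] result.
#' @param freq_hz frequencies at which to evaluate, Hz (must be positive).
#' @return linear-scale model power at `freq_hz`.
#' @export
aperiodic_model <- function(fit, freq_hz) {
  10^(fit$offset - fit$exponent * log10(freq_hz))
}

#' Canonical frequency bands
#'
#' Slow (0.1-1 Hz), delta (1-4 Hz), theta (4-12 Hz), beta (15-25 Hz) and
#' gamma (30-100 Hz). Note the deliberate gaps at 12-15 and 25-30 Hz.
#'
#' @return a tibble with columns `band`, `lo_hz`, `hi_hz`.
#' @export
hippo_bands <- function() {
  tibble(band = c("slow", "delta", "theta", "beta", "gamma"),
         lo_hz = c(0.1, 1, 4, 15, 30),
         hi_hz = c(1, 4, 12, 25, 100))
}

# trapezoidal AUC of a spectrum between lo and hi, interpolating at the edges
spec_auc <- function(freq_hz, power, lo, hi) {
  if (hi <= freq_hz[1] || lo >= freq_hz[length(freq_hz)]) return(0)
  lo <- max(lo, freq_hz[1]); hi <- min(hi, freq_hz[length(freq_hz)])
  inside <- freq_hz > lo & freq_hz < hi
  fgrid <- c(lo, freq_hz[inside], hi)
  pgrid <- approx(freq_hz, power, xout = fgrid, rule = 2)$y
  sum(diff(fgrid) * (head(pgrid, -1) + pgrid[-1]) / 2)
}

#' Absolute and normalized band powers with band ratios
#'
#' Integrates a (typically peak-only residual) spectrum over each band by the
#' trapezoid rule, normalizes by the integral over `norm_range_hz`, and
#' computes the theta/delta, beta/theta and (theta+beta)/(slow+delta) ratios
#' from the normalized values. Ratios whose denominator is zero are returned
#' as `NA` and flagged.
#'
#' @param spec a spectrum tibble (`freq_hz`, `power`), e.g. the `residual` of
#'   an [fit_aperiodic()].
#' @param bands band definition tibble, as [hippo_bands()].
#' @param norm_range_hz normalization range (0.1-100 Hz for LFP; 0.1-300 Hz
#'   for synaptic currents).
#' @return a `band_power_report`: a tibble (`band`, `lo_hz`, `hi_hz`,
#'   `abs_power`, `norm_power`) with a `ratios` tibble and the normalization
#'   range as attributes. Retrieve the ratios with [band_ratios()].
#' @export
band_powers <- function(spec, bands = hippo_bands(),
                        norm_range_hz = c(0.1, 100)) {
  total <- spec_auc(spec$freq_hz, spec$power, norm_range_hz[1], norm_range_hz[2])
  if (total <= 0) abort("Zero total power over the normalization range.")
  out <- bands |>
    mutate(abs_power = map_dbl(seq_len(nrow(bands)), function(i)
             spec_auc(spec$freq_hz, spec$power, bands$lo_hz[i], bands$hi_hz[i])),
           norm_power = .data$abs_power / total)
  np <- function(b) {
    v <- out$norm_power[out$band == b]
    if (length(v) == 0) NA_real_ else v
  }
  safe_ratio <- function(num, den) if (!is.na(den) && den > 0) num / den else NA_real_
  ratios <- tibble(
    ratio = c("theta_delta", "beta_theta", "thetabeta_slowdelta"),
    value = c(safe_ratio(np("theta"), np("delta")),
              safe_ratio(np("beta"), np("theta")),
              safe_ratio(np("theta") + np("beta"), np("slow") + np("delta"))))
  structure(out, ratios = ratios, norm_range_hz = norm_range_hz,
            class = c("band_power_report", class(out)))
}

#' @rdname band_powers
#' @param report a `band_power_report`.
#' @export
band_ratios <- function(report) attr(report, "ratios")
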