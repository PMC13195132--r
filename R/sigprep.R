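#' Signal conditioning
#'
#' Shared preprocessing for all analyses: mains notch removal, anti-aliased
#' downsampling, Butterworth band filtering (optionally zero-phase), and
#' per-sweep mean subtraction. Filters are Butterworth IIR designs from the
#' `signal` package; zero-phase application is forward-backward with
#' odd-symmetric edge padding so that epoch boundaries are not corrupted by
#' filter transients.
#'
#' @name sigprep
NULL

# forward-backward IIR with odd-symmetric padding (3x the denominator length,
# capped at n-1) to suppress edge transients
filtfilt_pad <- function(filt, x, npad = NULL) {
  nf <- max(length(filt$a), length(filt$b))
  if (is.null(npad)) npad <- 3L * 10L * nf
  npad <- min(npad, length(x) - 1L)
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L, by = -1L)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - npad, by = -1L)]
  xe <- c(pre, x, post)
  y <- signal::filter(filt, xe)
  y <- rev(as.numeric(signal::filter(filt, rev(as.numeric(y)))))
  y[seq(npad + 1L, npad + length(x))]
}

apply_per_channel <- function(ts, f) {
  if (is.matrix(ts$data)) {
    ts_with_data(ts, apply(ts$data, 2, f))
  } else {
    ts_with_data(ts, f(ts$data))
  }
}

#' Remove mains interference
#'
#' Applies a second-order Butterworth band-stop filter at each mains frequency
#' (fundamental and harmonics). The stop band is narrow (default 2 Hz at
#' -3 dB) so that physiological bands are spared.
#'
#' @param ts an [new_ts()] signal.
#' @param freqs_hz mains components to remove, Hz.
#' @param order filter order per notch.
#' @param width_hz -3 dB width of each notch, Hz.
#' @return the filtered `ephys_ts`.
#' @export
notch_mains <- function(ts, freqs_hz = c(50, 100, 150, 250), order = 2,
                        width_hz = 2) {
  nyq <- ts$rate_hz / 2
  if (any(freqs_hz >= nyq)) {
    abort(sprintf("Notch frequency at or above Nyquist (%g Hz).", nyq))
  }
  npad <- round(3 * ts$rate_hz / width_hz)   # narrow notch: long transients
  f <- function(x) {
    for (f0 in freqs_hz) {
      filt <- signal::butter(order, c(f0 - width_hz / 2, f0 + width_hz / 2) / nyq,
                             type = "stop")
      x <- filtfilt_pad(filt, x, npad)
    }
    x
  }
  apply_per_channel(ts, f)
}

#' Downsample with FIR anti-aliasing
#'
#' Applies a linear-phase FIR low-pass at the target Nyquist before taking
#' every `rate/target`-th sample. Only integer decimation factors are
#' supported; the rates used throughout (20 kHz to 2 kHz, 2 kHz to 250 Hz)
#' are integer ratios.
#'
#' @param ts an [new_ts()] signal.
#' @param target_rate_hz output rate, must divide the input rate.
#' @return the decimated `ephys_ts`.
#' @export
downsample <- function(ts, target_rate_hz = 2000) {
  if (target_rate_hz > ts$rate_hz) abort("Upsampling is not supported.")
  if (target_rate_hz == ts$rate_hz) return(ts)
  q <- ts$rate_hz / target_rate_hz
  if (abs(q - round(q)) > 1e-9) {
    abort("`target_rate_hz` must be an integer divisor of the sampling rate.")
  }
  q <- as.integer(round(q))
  ntap <- 30L * q + 1L          # linear-phase FIR, cutoff at 80% of new Nyquist
  h <- signal::fir1(ntap - 1L, (0.8 / q), type = "low")
  f <- function(x) {
    xf <- stats::filter(c(x, numeric((ntap - 1L) / 2L)), h, sides = 1)
    xf <- as.numeric(xf)[-seq_len((ntap - 1L) / 2L)]  # compensate group delay
    xf[is.na(xf)] <- 0
    xf[seq(1L, length(x), by = q)]
  }
  out <- apply_per_channel(ts, f)
  out$rate_hz <- target_rate_hz
  out
}

# Butterworth band-pass as second-order sections: analog prototype poles,
# band transform, bilinear transform, conjugate pairing. Direct high-order
# polynomial forms are numerically unstable for narrow bands at low
# normalized frequency (e.g. 1-4 Hz at 2 kHz), biquad cascades are not.
butter_bp_sos <- function(lo, hi, fs, order = 4) {
  w1 <- 2 * fs * tan(pi * lo / fs)          # prewarped analog corners
  w2 <- 2 * fs * tan(pi * hi / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # LHP poles
  spoles <- c()
  for (p in proto) {
    d <- sqrt((bw * p)^2 - 4 * w0^2)
    spoles <- c(spoles, (bw * p + d) / 2, (bw * p - d) / 2)
  }
  zp <- (2 * fs + spoles) / (2 * fs - spoles)      # bilinear
  # order poles into conjugate pairs
  upper <- zp[Im(zp) >= 0]
  upper <- upper[order(Mod(upper))]
  sections <- map(seq_along(upper), function(i) {
    p <- upper[i]
    a <- c(1, -2 * Re(p), Mod(p)^2)
    b <- c(1, 0, -1)                                # zeros at z = +1 and -1
    list(b = b, a = a)
  })
  # normalize overall gain to 1 at the geometric center frequency
  zc <- exp(1i * 2 * pi * sqrt(lo * hi) / fs)
  h <- prod(map_dbl(sections, function(s) {
    Mod(sum(s$b * zc^(0:-2)) / sum(s$a * zc^(0:-2)))
  }))
  g <- h^(1 / length(sections))
  map(sections, function(s) list(b = s$b / g, a = s$a))
}

#' Butterworth band filtering
#'
#' Applied as a cascade of second-order sections for numerical stability at
#' low normalized corner frequencies.
#'
#' @param ts an [new_ts()] signal.
#' @param lo,hi band corners in Hz; `0 < lo < hi < Nyquist`.
#' @param order Butterworth order.
#' @param zero_phase apply forward-backward for zero group delay (default);
#'   otherwise a single causal pass.
#' @return the filtered `ephys_ts`.
#' @export
bandpass <- function(ts, lo, hi, order = 4, zero_phase = TRUE) {
  nyq <- ts$rate_hz / 2
  if (!(lo > 0 && lo < hi && hi < nyq)) {
    abort(sprintf("Band corners must satisfy 0 < lo < hi < Nyquist (%g Hz).", nyq))
  }
  sos <- butter_bp_sos(lo, hi, ts$rate_hz, order)
  npad <- round(2 * ts$rate_hz / lo)     # edge padding spans the slow corner
  f <- function(x) {
    for (s in sos) {
      filt <- signal::Arma(b = s$b, a = s$a)
      x <- if (zero_phase) filtfilt_pad(filt, x, npad)
           else as.numeric(signal::filter(filt, x))
    }
    x
  }
  apply_per_channel(ts, f)
}

#' Low-pass / high-pass Butterworth
#'
#' @inheritParams bandpass
#' @param corner_hz cutoff frequency, Hz.
#' @param type `"low"` or `"high"`.
#' @export
butter_filter <- function(ts, corner_hz, type = c("low", "high"), order = 4,
                          zero_phase = TRUE) {
  type <- match.arg(type)
  nyq <- ts$rate_hz / 2
  if (corner_hz <= 0 || corner_hz >= nyq) abort("Corner outside (0, Nyquist).")
  filt <- signal::butter(order, corner_hz / nyq, type = type)
  f <- if (zero_phase) function(x) filtfilt_pad(filt, x)
       else function(x) as.numeric(signal::filter(filt, x))
  apply_per_channel(ts, f)
}

#' Subtract the sweep mean
#'
#' Removes slow drift offsets by subtracting the mean of each sweep (channel).
#'
#' @param ts an [new_ts()] signal.
#' @return the demeaned `ephys_ts`; each channel has mean zero.
#' @export
demean_sweep <- function(ts) {
  apply_per_channel(ts, function(x) x - mean(x))
}
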