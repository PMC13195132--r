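#' Uniformly sampled signal
#'
#' `ephys_ts` is the package's carrier for raw and filtered signals: a numeric
#' vector (one channel) or a samples-by-channels matrix, together with the
#' sampling rate, physical units and the time of the first sample. All times in
#' the package are seconds from recording start and all intervals are half-open
#' `[start, end)`.
#'
#' @param data numeric vector, or matrix with one column per channel.
#' @param rate_hz sampling rate in samples per second.
#' @param units physical units of the samples (e.g. `"uV"`, `"pA"`, `"cm/s"`).
#' @param t0_s time of the first sample, seconds.
#' @param channel_shank optional integer vector mapping each channel to a shank.
#'
#' @return an `ephys_ts` object.
#' @export
#' @examples
#' ts <- new_ts(sin(2 * pi * 8 * seq(0, 1, by = 1 / 500)), 500, units = "uV")
#' ts_duration(ts)
new_ts <- function(data, rate_hz, units = "", t0_s = 0, channel_shank = NULL) {
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    abort("`rate_hz` must be a single positive number.")
  }
  if (is.matrix(data)) {
    if (!is.null(channel_shank) && length(channel_shank) != ncol(data)) {
      abort("`channel_shank` must have one entry per channel.")
    }
  } else {
    data <- as.numeric(data)
  }
  structure(
    list(data = data, rate_hz = rate_hz, units = units, t0_s = t0_s,
         channel_shank = channel_shank),
    class = "ephys_ts"
  )
}

#' @export
print.ephys_ts <- function(x, ...) {
  nch <- ts_n_channels(x)
  cat(sprintf("<ephys_ts> %d channel%s, %d samples @ %g Hz (%.3f s)%s\n",
              nch, if (nch > 1) "s" else "", ts_n(x), x$rate_hz,
              ts_duration(x),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Basic accessors for `ephys_ts`
#'
#' @param ts an [new_ts()] object.
#' @return `ts_n()` the number of samples per channel, `ts_n_channels()` the
#'   channel count, `ts_duration()` the duration in seconds, `ts_times()` the
#'   vector of sample times and `ts_channel()` one channel as a single-channel
#'   `ephys_ts`.
#' @export
ts_n <- function(ts) if (is.matrix(ts$data)) nrow(ts$data) else length(ts$data)

#' @rdname ts_n
#' @export
ts_n_channels <- function(ts) if (is.matrix(ts$data)) ncol(ts$data) else 1L

#' @rdname ts_n
#' @export
ts_duration <- function(ts) ts_n(ts) / ts$rate_hz

#' @rdname ts_n
#' @export
ts_times <- function(ts) ts$t0_s + (seq_len(ts_n(ts)) - 1L) / ts$rate_hz

#' @rdname ts_n
#' @param i channel index (1-based).
#' @export
ts_channel <- function(ts, i) {
  stopifnot(i >= 1, i <= ts_n_channels(ts))
  dat <- if (is.matrix(ts$data)) ts$data[, i] else ts$data
  new_ts(dat, ts$rate_hz, ts$units, ts$t0_s)
}

ts_with_data <- function(ts, data) {
  out <- ts
  out$data <- data
  out
}

#' @export
as_tibble.ephys_ts <- function(x, ...) {
  if (is.matrix(x$data)) {
    colnames(x$data) <- paste0("ch", seq_len(ncol(x$data)))
    tibble(time_s = ts_times(x), as_tibble(x$data))
  } else {
    tibble(time_s = ts_times(x), value = x$data)
  }
}
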