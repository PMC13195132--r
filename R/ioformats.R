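#' On-disk formats
#'
#' Raw signals travel as flat little-endian int16 binary with a JSON sidecar
#' carrying the scaling and layout (the acquisition convention: signals
#' "sampled at 20 kHz and digitized as 16-bit signed integers"); all event,
#' spike and epoch tables are CSV. Round-trips are lossless up to one
#' quantization step for signals and printed precision for tables.
#'
#' @name ioformats
NULL

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a signal as int16 binary + JSON sidecar
#'
#' `write_signal()` quantizes to 16-bit integers (channel-interleaved for
#' multichannel data) and writes `<path>` plus `<path>.json` holding
#' `rate_hz`, `n_channels`, `dtype`, `units_per_bit`, `units`, `t0_s`,
#' `n_samples` and the channel-to-shank map. `read_signal()` reverses it.
#'
#' @param ts an [new_ts()] signal.
#' @param path output file (binary payload; sidecar gets `.json` appended).
#' @param units_per_bit quantization step; default scales the peak to ~32000.
#' @return `write_signal()` the path, invisibly; `read_signal()` an
#'   `ephys_ts` in physical units.
#' @export
write_signal <- function(ts, path, units_per_bit = NULL) {
  x <- if (is.matrix(ts$data)) ts$data else matrix(ts$data, ncol = 1)
  if (is.null(units_per_bit)) {
    peak <- max(abs(x), 1e-12)
    units_per_bit <- peak / 32000
  }
  q <- round(t(x) / units_per_bit)               # interleave channels
  if (any(abs(q) > 32767)) abort("Quantization overflow; increase `units_per_bit`.")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(q), con, size = 2L, endian = "little")
  meta <- list(rate_hz = ts$rate_hz, n_channels = ncol(x), dtype = "int16",
               units_per_bit = units_per_bit, units = ts$units,
               t0_s = ts$t0_s, n_samples = nrow(x),
               channel_shank = ts$channel_shank)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_signal
#' @param meta metadata list; read from the JSON sidecar when `NULL`.
#' @export
read_signal <- function(path, meta = NULL) {
  if (is.null(meta)) {
    sp <- sidecar_path(path)
    if (!file.exists(sp)) abort(sprintf("No metadata: sidecar '%s' missing.", sp))
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  }
  for (field in c("rate_hz", "n_channels", "dtype", "units_per_bit")) {
    if (is.null(meta[[field]])) {
      abort(sprintf("Signal metadata is missing required field '%s'.", field))
    }
  }
  if (meta$dtype != "int16") abort("Only dtype 'int16' is supported.")
  nbytes <- file.size(path)
  frame_bytes <- 2L * meta$n_channels
  if (nbytes %% frame_bytes != 0) {
    abort(sprintf(
      "Truncated signal file: %d bytes is not a multiple of the %d-byte frame (%d channels x int16).",
      nbytes, frame_bytes, meta$n_channels))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nbytes / 2L, size = 2L, signed = TRUE,
                 endian = "little")
  x <- t(matrix(raw, nrow = meta$n_channels)) * meta$units_per_bit
  if (ncol(x) == 1L) x <- drop(x)
  new_ts(x, meta$rate_hz, units = meta$units %||% "", t0_s = meta$t0_s %||% 0,
         channel_shank = if (length(meta$channel_shank)) meta$channel_shank)
}

#' Read a sorted spike table
#'
#' CSV with header columns `unit_id` and `time_s` (additional columns are
#' preserved). Times must be non-negative; non-monotone times within a unit
#' trigger a warning and a stable sort.
#'
#' @param path CSV file.
#' @return a tibble (`unit_id`, `time_s`, ...), ordered by unit then time.
#' @export
read_spike_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("unit_id", "time_s") %in% names(tab))) {
    abort("Spike table must have columns 'unit_id' and 'time_s'.")
  }
  if (nrow(tab) == 0) return(tab)
  if (any(tab$time_s < 0)) abort("Spike times must be non-negative.")
  mono <- tab |>
    group_by(.data$unit_id) |>
    summarise(ok = !is.unsorted(.data$time_s), .groups = "drop")
  if (!all(mono$ok)) {
    warn("Non-monotone spike times within a unit; applying a stable sort.")
  }
  arrange(tab, .data$unit_id, .data$time_s)
}

#' Write an event/feature table as CSV
#'
#' One row per event with all computed features, full precision.
#'
#' @param events a data frame (events, epochs, units, ...).
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_event_table <- function(events, path) {
  readr::write_csv(as_tibble(events), path, progress = FALSE)
  invisible(path)
}
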