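#' Analysis configuration
#'
#' Every tunable parameter of the pipeline has a named key and a documented
#' default; mode presets pin the mode-specific constants (Welch geometry,
#' normalization range, epoch bands). Modes: `anesthetized_lfp` (glass
#' electrode LFP), `anesthetized_psc` (voltage-clamp synaptic currents with
#' simultaneous LFP), `awake_probe` (silicon-probe multichannel recording
#' with sorted units and treadmill speed).
#'
#' @param mode analysis mode.
#' @param seed RNG seed used by every stochastic stage.
#' @return nested config list.
#' @export
default_config <- function(mode = c("anesthetized_lfp", "anesthetized_psc",
                                    "awake_probe"), seed = 1) {
  mode <- match.arg(mode)
  welch <- switch(mode,
    anesthetized_psc = list(window_s = 2, overlap_frac = 0.9, step_hz = 0.5),
    list(window_s = 10, overlap_frac = 0.5, step_hz = 0.1))
  norm_range <- if (mode == "anesthetized_psc") c(0.1, 300) else c(0.1, 100)
  list(
    mode = mode,
    seed = seed,
    prep = list(notch_freqs_hz = c(50, 100, 150, 250), notch_order = 2,
                notch_width_hz = 2, analysis_rate_hz = 2000,
                bandpass_hz = c(0.1, 300), bandpass_order = 4),
    welch = welch,
    aperiodic = list(fit_range_hz = c(1, 100), peak_threshold_sd = 2,
                     max_peaks = 6, peak_width_hz = c(0.5, 12)),
    bands = list(norm_range_hz = norm_range),
    psc = list(percentiles = c(1, 5, 10, 15, 20, 25), smooth_ms = 2.5,
               min_phase_events = 10),
    epochs = list(min_cycles = 2, wavelet_cycles = 6, threshold_pct = 0.95),
    state = list(window_s = 1.6, step_s = 0.8, nw = 3, td_thresh = 2,
                 run_speed = 5, rest_speed = 1, min_dur_s = 2),
    units = list(acg_lag_ms = 50, acg_bin_ms = 1, burst_isi_ms = 5,
                 burst_min_spikes = 3, min_acg_peak = 10),
    swr = list(ripple_band_hz = c(100, 250), control_band_hz = c(250, 400),
               sd_mult = 3, duration_ms = c(15, 150), min_specificity = 4,
               smooth_sigma_ms = 4),
    pv = list(phase_range_deg = c(203, 339), n_bins = 8, min_spikes = 10)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a YAML analysis config
#'
#' Keys present in the file override the mode preset from
#' [default_config()]; everything else keeps its documented default.
#'
#' @param path YAML file with at least a `mode` key.
#' @return full config list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$mode)) abort("Config must declare `mode`.")
  merge_config(default_config(y$mode, seed = y$seed %||% 1), y)
}

prep_lfp <- function(ts, cfg) {
  ts |>
    notch_mains(cfg$prep$notch_freqs_hz, cfg$prep$notch_order,
                cfg$prep$notch_width_hz) |>
    downsample(cfg$prep$analysis_rate_hz) |>
    bandpass(cfg$prep$bandpass_hz[1], cfg$prep$bandpass_hz[2],
             cfg$prep$bandpass_order)
}

spectral_report <- function(ts, cfg) {
  spec <- welch_psd(ts, cfg$welch$window_s, cfg$welch$overlap_frac,
                    cfg$welch$step_hz)
  spec <- repair_line_bins(spec, cfg$prep$notch_freqs_hz)
  fit <- fit_aperiodic(spec, cfg$aperiodic$fit_range_hz,
                       cfg$aperiodic$peak_threshold_sd,
                       cfg$aperiodic$max_peaks, cfg$aperiodic$peak_width_hz)
  bp <- band_powers(fit$residual, hippo_bands(), cfg$bands$norm_range_hz)
  list(spectrum = spec, fit = fit, band_power = bp)
}

#' Run the full analysis pipeline
#'
#' Deterministic given `config` and its seed; emits every intermediate table
#' and a JSON manifest of all effective parameters and the package version
#' when `out_dir` is given.
#'
#' Inputs per mode: `anesthetized_lfp` needs `lfp` (an [new_ts()] or a
#' [write_signal()] path); `anesthetized_psc` additionally needs `sweep`
#' plus its `polarity`; `awake_probe` needs a multichannel `lfp`, `spikes`
#' (spike table or CSV path) and `speed`.
#'
#' @param config a [default_config()] / [read_config()] list.
#' @param inputs named list of inputs (see Details).
#' @param out_dir optional output directory for CSV tables + manifest.
#' @return named list of result tables/objects (invisible when writing).
#' @export
run_pipeline <- function(config, inputs, out_dir = NULL) {
  res <- switch(config$mode,
    anesthetized_lfp = pipeline_lfp(config, inputs),
    anesthetized_psc = pipeline_psc(config, inputs),
    awake_probe = pipeline_probe(config, inputs),
    abort("Unknown mode."))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(res$tables)) {
      write_event_table(res$tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    manifest <- list(
      package = "hippoephys",
      version = as.character(utils::packageVersion("hippoephys")),
      mode = config$mode,
      inputs = map(inputs, function(x)
        if (is.character(x)) x else paste0("<in-memory ", class(x)[1], ">")),
      parameters = config)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

resolve_signal <- function(x) if (is.character(x)) read_signal(x) else x
resolve_table <- function(x) if (is.character(x)) read_spike_table(x) else x

pipeline_lfp <- function(config, inputs) {
  lfp <- prep_lfp(resolve_signal(inputs$lfp), config)
  sr <- spectral_report(lfp, config)
  tables <- list(
    spectrum = as_tibble(sr$spectrum),
    aperiodic = glance(sr$fit),
    peaks = tidy(sr$fit),
    band_power = as_tibble(sr$band_power),
    band_ratios = band_ratios(sr$band_power))
  list(tables = tables, objects = sr)
}

pipeline_psc <- function(config, inputs) {
  polarity <- inputs$polarity %||% "inward"
  sweep <- resolve_signal(inputs$sweep) |>
    notch_mains(config$prep$notch_freqs_hz, config$prep$notch_order,
                config$prep$notch_width_hz) |>
    downsample(config$prep$analysis_rate_hz) |>
    demean_sweep()
  events <- detect_psc(sweep, polarity = polarity)
  stats <- event_stats(events, ts_duration(sweep))
  charge <- charge_transfer(sweep)
  sr <- spectral_report(sweep, config)
  tables <- list(
    events = events,
    event_stats = mutate(stats, charge_nas = charge),
    band_power = as_tibble(sr$band_power),
    band_ratios = band_ratios(sr$band_power))
  objects <- list(sweep = sweep, spectral = sr)
  if (!is.null(inputs$lfp)) {
    lfp <- prep_lfp(resolve_signal(inputs$lfp), config)
    pl_rows <- list()
    ep_all <- list()
    for (band in c("delta", "theta")) {
      eps <- detect_osc_epochs(lfp, band,
                               min_cycles = config$epochs$min_cycles,
                               n_cycles = config$epochs$wavelet_cycles,
                               percentile = config$epochs$threshold_pct)
      band_hz <- if (band == "delta") c(1, 4) else c(4, 12)
      ph <- instantaneous_phase(bandpass(lfp, band_hz[1], band_hz[2]))
      pl <- phase_lock_cell(sweep, ph, eps, polarity,
                            percentiles = config$psc$percentiles,
                            min_events = config$psc$min_phase_events)
      pl_rows[[band]] <- mutate(as_tibble(pl), band = band,
                                mean_R = attr(pl, "mean_R"))
      ep_all[[band]] <- as_tibble(eps)
    }
    tables$epochs <- bind_rows(ep_all)
    tables$phase_lock <- bind_rows(pl_rows)
  }
  list(tables = tables, objects = objects)
}

pipeline_probe <- function(config, inputs) {
  raw <- resolve_signal(inputs$lfp)
  spikes <- resolve_table(inputs$spikes)
  speed <- resolve_signal(inputs$speed)
  chans <- select_pyramidal_channel(raw)
  ch <- chans$channel[1]
  lfp <- prep_lfp(ts_channel(raw, ch), config)
  sr <- spectral_report(lfp, config)
  segs_rr <- run_rest_segments(speed, config$state$run_speed,
                               config$state$rest_speed, config$state$min_dur_s)
  segs_td <- theta_state_segments(lfp, speed, config$state$window_s,
                                  config$state$step_s, config$state$nw,
                                  config$state$td_thresh,
                                  config$state$run_speed,
                                  config$state$rest_speed,
                                  config$state$min_dur_s)
  ripples <- detect_swr(lfp, config$swr$ripple_band_hz,
                        config$swr$control_band_hz, config$swr$sd_mult,
                        config$swr$duration_ms, config$swr$min_specificity,
                        config$swr$smooth_sigma_ms)
  total_time <- ts_duration(lfp)
  units <- unit_table(spikes, total_time, inputs$waveforms,
                      inputs$waveform_rate_hz %||% 20000,
                      config$units$burst_isi_ms)
  theta_segs <- filter(segs_td, .data$label == "theta")
  nontheta <- filter(segs_td, .data$label == "non_theta")
  pv <- NULL
  if (nrow(ripples) > 0 && nrow(nontheta) > 0) {
    ctrl <- sample_control_periods(nontheta, ripples, seed = config$seed)
    pv <- bind_rows(map(units$unit_id, function(id) {
      st <- sort(spikes$time_s[spikes$unit_id == id])
      m <- swr_modulation(st, ripples, ctrl, config$pv$n_bins)
      tp <- theta_phase_pref(st, theta_segs, lfp,
                             min_spikes = config$pv$min_spikes)
      tibble(unit_id = id, single_peaked = m$single_peaked,
             baseline_rate_hz = m$baseline_rate_hz,
             preferred_phase_deg = tp$preferred_phase_deg,
             theta_rayleigh_p = tp$rayleigh_p,
             is_pv_basket = classify_pv_basket(m$single_peaked,
                                               tp$preferred_phase_deg,
                                               config$pv$phase_range_deg))
    }))
  }
  tables <- list(
    channels = chans,
    band_power = as_tibble(sr$band_power),
    band_ratios = band_ratios(sr$band_power),
    run_rest = segs_rr,
    theta_states = segs_td,
    ripples = as_tibble(ripples),
    units = units)
  if (!is.null(pv)) tables$pv_basket <- pv
  list(tables = tables,
       objects = list(lfp = lfp, spectral = sr, ripples = ripples))
}
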