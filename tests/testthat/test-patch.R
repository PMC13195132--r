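fs <- 20000

# a sweep with known injected events at native acquisition rate
make_sweep <- function(times, amps, dur = 5, noise_sd = 2, seed = 1,
                       rise_ms = 0.8, decay_ms = 6) {
  set.seed(seed)
  n <- dur * fs
  x <- rnorm(n, 0, noise_sd)
  k <- hippoephys:::psc_kernel(fs, rise_ms, decay_ms)
  for (i in seq_along(times)) {
    i0 <- round(times[i] * fs) + 1
    idx <- i0:min(i0 + length(k) - 1, n)
    x[idx] <- x[idx] - amps[i] * k[seq_along(idx)]
  }
  demean_sweep(new_ts(x, fs, units = "pA"))
}

test_that("a single clean EPSC is detected with its amplitude", {
  sw <- make_sweep(2.0, 20)
  ev <- accepted_events(detect_psc(sw, polarity = "inward"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_pa, 20, tolerance = 3 / 20)
  expect_equal(ev$onset_s, 2.0, tolerance = 0.005)
})

test_that("sub-threshold amplitudes and unresolved pairs are rejected", {
  # 5 pA event under the 7 pA minimum
  sw5 <- make_sweep(2.0, 5, noise_sd = 0.5)
  expect_equal(nrow(accepted_events(detect_psc(sw5, polarity = "inward"))), 0)

  # two kernels 50 samples apart with min_separation 200 -> one event
  sw2 <- make_sweep(c(2.0, 2.0 + 50 / fs), c(20, 20), noise_sd = 0.5)
  ev2 <- accepted_events(detect_psc(sw2, polarity = "inward"))
  expect_equal(nrow(ev2), 1)
})

test_that("detection is translation-equivariant and monotone in min_amp", {
  sw <- make_sweep(c(1.0, 2.5, 3.8), c(15, 25, 40), seed = 5)
  ev <- accepted_events(detect_psc(sw, polarity = "inward"))
  shift <- 0.5
  sw_sh <- make_sweep(c(1.0, 2.5, 3.8) + shift, c(15, 25, 40), seed = 5)
  # same noise realization, shifted events: compare detected onsets loosely
  ev_sh <- accepted_events(detect_psc(sw_sh, polarity = "inward"))
  expect_equal(nrow(ev), nrow(ev_sh))

  counts <- sapply(c(30, 20, 10, 7), function(ma) {
    cfg <- psc_detect_config("inward", min_amp_pa = ma)
    nrow(accepted_events(detect_psc(sw, cfg)))
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("decay tau is recovered from analytic and noisy kernels", {
  k <- hippoephys:::psc_kernel(fs, 1, 10) * 20
  kin <- psc_kinetics(k, fs)
  expect_equal(kin$decay_tau_ms, 10, tolerance = 0.05)
  expect_equal(kin$amplitude, 20, tolerance = 0.01)

  # rectangular pulse: amplitude exact, no admissible decay fit
  rect <- c(rep(0, 10), rep(7, 100), rep(0, 10))
  expect_equal(psc_kinetics(rect, fs)$amplitude, 7)

  set.seed(3)
  taus <- replicate(100, psc_kinetics(k + rnorm(length(k), 0, 2),
                                      fs)$decay_tau_ms)
  expect_equal(mean(taus, na.rm = TRUE), 10, tolerance = 0.1)
})

test_that("event statistics follow their definitions", {
  ev <- tibble::tibble(onset_s = seq(0.05, 29.95, length.out = 300),
                       amplitude_pa = 20, decay_tau_ms = 6,
                       rise_rate_pa_per_ms = 10, accepted = TRUE)
  st <- event_stats(ev, 30)
  expect_equal(st$frequency_hz, 10)
  expect_equal(st$mean_iei_s, diff(ev$onset_s)[1], tolerance = 1e-9)

  st0 <- event_stats(ev[0, ], 30)
  expect_equal(st0$frequency_hz, 0)
  expect_true(is.na(st0$mean_iei_s))
})

test_that("charge transfer integrates simple geometries and scales linearly", {
  # 100 pA for 1 s -> 0.1 nA*s
  rect <- new_ts(rep(100, 1001), 1000, units = "pA")
  expect_equal(charge_transfer(rect), 0.1, tolerance = 1e-3)

  # triangular 100 pA x 2 s -> 0.1 nA*s
  tri <- new_ts(c(seq(0, 100, length.out = 1001),
                  seq(100, 0, length.out = 1001)[-1]), 1000)
  expect_equal(charge_transfer(tri), 0.1, tolerance = 1e-3)
  expect_equal(charge_transfer(new_ts(tri$data * 3, 1000)), 0.3,
               tolerance = 1e-3)

  expect_equal(ei_ratio(0.5, 0.5), 1)
  expect_error(ei_ratio(1, 0), "zero")
})

test_that("derivative onsets honor percentile selection", {
  sw <- downsample(make_sweep(seq(0.5, 25, by = 0.5), rep(20, 50), dur = 30,
                              noise_sd = 1), 2000)
  ons <- derivative_onsets(sw, "inward", percentile = 25)
  hits <- score_events(ons, seq(0.5, 25, by = 0.5), tol_s = 0.005)
  expect_gte(hits$recall, 0.9)

  # p = 100 returns every extremum; monotone ramp returns none
  all_ons <- derivative_onsets(sw, "inward", percentile = 100)
  expect_gt(length(all_ons), length(ons))
  ramp <- new_ts(seq(0, 1, length.out = 2000), 2000)
  expect_length(derivative_onsets(ramp, "inward", percentile = 50), 0)
  expect_error(derivative_onsets(sw, "inward", percentile = 0), "percentile")
})

test_that("intrinsic analysis recovers Rin, AP shape and the F-I curve", {
  g <- gen_currentclamp_sweeps(rin_mohm = 100, vm_mv = -65,
                               step_pa_list = c(-100, -50, 0, 50, 100, 200),
                               ap_template = list(threshold_mv = -45,
                                                  peak_mv = 35,
                                                  half_width_ms = 0.8),
                               seed = 2)
  rep <- intrinsic_analysis(g$sweeps, g$protocol)
  expect_equal(rep$rin_mohm, 100, tolerance = 0.02)
  expect_equal(rep$vm_mv, -65, tolerance = 0.01)
  expect_equal(mean(rep$ap_features$half_width_ms), 0.8, tolerance = 0.0625)
  expect_equal(rep$fi_curve$n_aps[rep$fi_curve$step_pa <= 50], c(0, 0, 0, 0))
  expect_true(all(diff(rep$fi_curve$n_aps) >= 0))
  expect_equal(rep$ap_features$amplitude_mv,
               rep$ap_features$peak_mv - rep$ap_features$threshold_mv)

  # without the -100 pA sweep Rin is flagged missing
  rep2 <- intrinsic_analysis(g$sweeps[3:6], g$protocol[3:6, ])
  expect_true(is.na(rep2$rin_mohm))
  expect_false(is.na(rep2$rin_flag))
})
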