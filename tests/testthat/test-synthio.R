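test_that("generators are bit-identical for a fixed seed and leave the RNG alone", {
  set.seed(99)
  before <- .Random.seed
  a <- gen_lfp(lfp_spec(5, 1000, 0, 1.5, seed = 7))
  expect_identical(.Random.seed, before)
  b <- gen_lfp(lfp_spec(5, 1000, 0, 1.5, seed = 7))
  expect_identical(a$ts$data, b$ts$data)

  s1 <- gen_spike_train(spike_train_spec(duration_s = 60, seed = 3))
  s2 <- gen_spike_train(spike_train_spec(duration_s = 60, seed = 3))
  expect_identical(s1$spike_times, s2$spike_times)
})

test_that("LFP generator produces the requested aperiodic slope", {
  # white-noise identity case
  g0 <- gen_lfp(lfp_spec(60, 1000, 0, 0, seed = 1))
  sp0 <- welch_psd(g0$ts, 2, 0.5, 0.5)
  fit0 <- fit_aperiodic(sp0, c(1, 100))
  expect_lt(abs(fit0$exponent), 0.1)

  # chi = 2 recovered within 0.1
  g2 <- gen_lfp(lfp_spec(60, 1000, 0, 2, seed = 1))
  sp2 <- welch_psd(g2$ts, 2, 0.5, 0.5)
  fit2 <- fit_aperiodic(sp2, c(1, 100))
  expect_equal(fit2$exponent, 2, tolerance = 0.05)
  expect_equal(fit2$offset, 0, tolerance = 0.1)

  # Parseval: band-integrated PSD matches the variance within 5%
  expect_equal(sum(sp2$power) * attr(sp2, "step_hz") / var(g2$ts$data), 1,
               tolerance = 0.05)
})

test_that("an injected oscillation dominates the aperiodic residual", {
  g <- gen_lfp(lfp_spec(30, 1000, 0, 1,
                        oscillations = data.frame(freq_hz = 8, amp = 1,
                                                  bandwidth_hz = 0.5),
                        seed = 2))
  sp <- welch_psd(g$ts, 2, 0.5, 0.5)
  fit <- fit_aperiodic(sp, c(1, 100))
  resid <- dplyr::filter(fit$residual, freq_hz >= 1, freq_hz <= 100)
  pk_freq <- resid$freq_hz[which.max(resid$power)]
  expect_gte(pk_freq, 4)
  expect_lte(pk_freq, 12)
})

test_that("LFP generator rejects sub-Nyquist rates", {
  expect_error(lfp_spec(1, 100, oscillations = data.frame(
    freq_hz = 80, amp = 1, bandwidth_hz = 0)), "Nyquist")
})

test_that("PSC sweeps honor rate, locking, and degenerate cases", {
  g0 <- gen_psc_sweep(psc_sweep_spec(duration_s = 5, rate_hz = 2000,
                                     event_rate_hz = 0, seed = 1))
  expect_equal(nrow(g0$truth$events), 0)
  expect_lt(max(abs(g0$ts$data)), 6 * 2)   # noise + drift only

  gi <- gen_psc_sweep(psc_sweep_spec(duration_s = 10, rate_hz = 2000,
                                     event_rate_hz = 5, seed = 2,
                                     locking = list(carrier_freq_hz = 8,
                                                    kappa = Inf,
                                                    preferred_phase_rad = 1)))
  expect_true(all(gi$truth$events$phase_rad == 1))

  gk <- gen_psc_sweep(psc_sweep_spec(duration_s = 60, rate_hz = 2000,
                                     event_rate_hz = 10, seed = 3,
                                     locking = list(carrier_freq_hz = 8,
                                                    kappa = 2,
                                                    preferred_phase_rad = 1)))
  cs <- circ_stats(gk$truth$events$phase_rad)
  expect_gt(nrow(gk$truth$events), 300)
  expect_lt(abs(circ_stats(gk$truth$events$phase_rad)$circ_mean - 1),
            5 * pi / 180)
  expect_error(psc_sweep_spec(event_rate_hz = -1))
})

test_that("spike trains respect refractoriness and burst design", {
  s0 <- gen_spike_train(spike_train_spec(duration_s = 300, base_rate_hz = 2,
                                         burst_rate_hz = 0, seed = 1))
  expect_gt(length(s0$spike_times), 100)
  expect_true(all(diff(s0$spike_times) * 1000 >= 2))
  br0 <- detect_bursts(s0$spike_times, total_time_s = 300)
  expect_equal(nrow(br0$bursts), 0)

  # Poisson-count check on designed bursts
  sb <- gen_spike_train(spike_train_spec(duration_s = 600, base_rate_hz = 1,
                                         burst_rate_hz = 0.1,
                                         spikes_per_burst = c("3" = 1),
                                         intra_burst_isi_ms = 3, seed = 2))
  br <- detect_bursts(sb$spike_times, total_time_s = 600)
  expect_gt(nrow(br$bursts), 60 - 3 * sqrt(60))
  expect_lt(nrow(br$bursts), 60 + 3 * sqrt(60))

  # theta modulation shows up as circular non-uniformity at 8 Hz
  st <- gen_spike_train(spike_train_spec(duration_s = 120, base_rate_hz = 5,
                                         burst_rate_hz = 0,
                                         theta_mod = list(freq_hz = 8,
                                                          depth = 1,
                                                          preferred_phase_rad = 0),
                                         seed = 3))
  ph <- (2 * pi * 8 * st$spike_times) %% (2 * pi)
  expect_lt(rayleigh_test(ph)$p_value, 0.05)
})

test_that("speed traces reproduce block structure", {
  sp <- gen_speed_trace(data.frame(duration_s = c(5, 5),
                                   mean_speed = c(10, 0)), seed = 1)
  expect_equal(sp$ts$rate_hz, 50)
  expect_equal(ts_n(sp$ts), 500)
  expect_equal(mean(sp$ts$data[1:250]), 10, tolerance = 0.2)
  expect_lt(mean(sp$ts$data[251:500]), 0.5)
  expect_equal(sp$truth$state_blocks$label, c("running", "resting"))
  expect_error(gen_speed_trace(data.frame(duration_s = 1, mean_speed = -2)),
               "Negative")
})

test_that("current-clamp sweeps obey Ohm's law and carry the AP template", {
  g <- gen_currentclamp_sweeps(rin_mohm = 100, vm_mv = -65,
                               step_pa_list = c(-100, 0, 200), seed = 1)
  fs <- g$sweeps[[1]]$rate_hz
  hyp <- g$sweeps[[1]]$data
  ss <- mean(hyp[round(0.6 * fs):round(0.69 * fs)])
  expect_equal(ss - (-65), -10, tolerance = 0.3)       # -100 pA x 100 MOhm

  flat <- g$sweeps[[2]]$data
  expect_equal(mean(flat), -65, tolerance = 0.1)
  expect_lt(diff(range(flat)), 1.5)

  expect_equal(g$protocol$n_aps, c(0, 0, 15))
})
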