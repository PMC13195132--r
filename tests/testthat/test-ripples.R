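ripple_trace <- function(seed, n = 20, snr = 4, dur_s = 60) {
  gen_lfp(lfp_spec(dur_s, 2000, 1, 2, seed = seed,
                   ripples = list(n = n, freq_hz = 180, duration_ms = 60,
                                  snr = snr)))
}

test_that("the ripple-rich channel is selected per shank", {
  mats <- sapply(1:4, function(i) {
    if (i == 3) ripple_trace(30, n = 10, snr = 8, dur_s = 10)$ts$data
    else gen_lfp(lfp_spec(10, 2000, 1, 2, seed = 20 + i))$ts$data
  })
  lfp <- new_ts(mats, 2000, channel_shank = c(1, 1, 2, 2))
  sel <- select_pyramidal_channel(lfp)
  expect_equal(sel$channel[sel$shank == 2], 3L)

  # identical channels tie to the lowest index with a warning
  same <- new_ts(cbind(mats[, 1], mats[, 1]), 2000, channel_shank = c(1, 1))
  expect_warning(sel2 <- select_pyramidal_channel(same), "tied")
  expect_equal(sel2$channel, 1L)

  single <- new_ts(cbind(mats[, 1]), 2000, channel_shank = 1)
  expect_equal(select_pyramidal_channel(single)$channel, 1L)
})

test_that("injected ripples are recovered with high recall and precision", {
  stats <- lapply(1:3, function(s) {
    g <- ripple_trace(s)
    det <- detect_swr(g$ts)
    sc <- score_ripples(det, g$truth$ripple_windows)
    dur_err <- mean(det$duration_ms[vapply(det$peak_s, function(p)
      any(p > g$truth$ripple_windows$start_s &
            p < g$truth$ripple_windows$end_s), logical(1))]) - 60
    list(sc = sc, dur_err = dur_err, det = det)
  })
  expect_gte(mean(sapply(stats, function(s) s$sc$recall)), 0.9)
  expect_gte(mean(sapply(stats, function(s) s$sc$precision)), 0.9)
  expect_lt(abs(mean(sapply(stats, function(s) s$dur_err))), 10)
  det <- stats[[1]]$det
  expect_true(all(det$duration_ms >= 15))
  expect_true(all(det$specificity_ratio >= 4))
  expect_true(all(det$start_s < det$peak_s & det$peak_s < det$end_s))
  expect_true(all(det$start_s[-1] >= det$end_s[-nrow(det)]))  # non-overlap
})

test_that("broadband transients and too-short bursts are rejected", {
  g <- gen_lfp(lfp_spec(30, 2000, 1, 2, seed = 9))
  x <- g$ts$data
  set.seed(1)
  for (st in c(5, 15, 25)) {
    i <- round(st * 2000) + (1:120)
    x[i] <- x[i] + rnorm(120, 0, 40)      # flat 60 ms broadband transient
  }
  expect_equal(nrow(detect_swr(new_ts(x, 2000))), 0)

  # 10 ms ripple burst (at the usual SNR) fails the duration criterion
  y <- g$ts$data
  tt <- seq(0, 0.010, by = 1 / 2000)
  for (st in c(6, 16, 26)) {
    i <- round(st * 2000) + seq_along(tt)
    y[i] <- y[i] + 0.8 * sin(2 * pi * 180 * tt)
  }
  det <- detect_swr(new_ts(y, 2000))
  hits <- vapply(c(6, 16, 26), function(s)
    any(det$peak_s > s - 0.05 & det$peak_s < s + 0.06), logical(1))
  expect_false(any(hits))

  expect_error(detect_swr(new_ts(rnorm(1000), 500)), "control band")
})

test_that("detection is scale-invariant and monotone in the SD multiplier", {
  g <- ripple_trace(4)
  d1 <- detect_swr(g$ts)
  d2 <- detect_swr(ts_with <- new_ts(g$ts$data * 7.3, 2000))
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1$start_s, d2$start_s, tolerance = 1e-9)

  counts <- sapply(c(2, 3, 5), function(m)
    nrow(detect_swr(g$ts, sd_mult = m)))
  expect_true(all(diff(counts) <= 0))
})

test_that("recall grows with envelope SNR", {
  rec <- sapply(c(2, 4, 8), function(snr) {
    g <- ripple_trace(6, snr = snr, dur_s = 40)
    score_ripples(detect_swr(g$ts), g$truth$ripple_windows)$recall
  })
  expect_true(all(diff(rec) >= 0))
})

test_that("peri-SWR histograms distinguish peak-locked from Poisson units", {
  g <- ripple_trace(12, n = 30)
  rip <- detect_swr(g$ts)
  expect_gt(nrow(rip), 20)
  ctrl <- sample_control_periods(tibble::tibble(start_s = 0.5, end_s = 59.5),
                                 rip, seed = 2)
  expect_equal(nrow(ctrl), nrow(rip))

  # unit firing only at SWR peaks
  locked <- sort(unlist(lapply(rip$peak_s, function(p) p + rnorm(6, 0, 0.004))))
  m <- swr_modulation(locked, rip, ctrl)
  expect_true(m$single_peaked)
  expect_equal(which.max(m$histogram$count) %in% c(4, 5), TRUE)

  # homogeneous Poisson unit: flat, almost never single-peaked
  set.seed(5)
  flat_flags <- replicate(20, {
    u <- sort(runif(1200, 0, 60))
    swr_modulation(u, rip, ctrl)$single_peaked
  })
  expect_gte(mean(!flat_flags), 0.9)

  silent <- swr_modulation(numeric(0), rip, ctrl)
  expect_false(silent$single_peaked)
  expect_true(all(silent$histogram$count == 0))
})

test_that("theta phase preference uses trough-referenced degrees", {
  fs <- 2000
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  lfp <- new_ts(cos(2 * pi * 8 * tt), fs)
  segs <- tibble::tibble(start_s = 1, end_s = 59)
  # spikes at troughs: cos phase pi -> 0 degrees trough-referenced
  troughs <- (seq(9, 470) + 0.5) / 8
  tp <- theta_phase_pref(troughs, segs, lfp)
  expect_true(tp$preferred_phase_deg < 15 || tp$preferred_phase_deg > 345)
  # spikes at peaks -> 180 degrees
  peaks <- seq(9, 470) / 8
  tp2 <- theta_phase_pref(peaks, segs, lfp)
  expect_equal(tp2$preferred_phase_deg, 180, tolerance = 0.05)

  too_few <- theta_phase_pref(troughs[1:5], segs, lfp)
  expect_true(is.na(too_few$preferred_phase_deg))
  expect_equal(nrow(tp$histogram), 20)     # 18-degree bins
})

test_that("a synthetic unit locked at 270 degrees is recovered and classified", {
  g <- gen_lfp(lfp_spec(60, 2000, 0, 1.5,
                        oscillations = data.frame(freq_hz = 8, amp = 3,
                                                  bandwidth_hz = 0.3),
                        seed = 14))
  lfp <- g$ts
  ph <- instantaneous_phase(bandpass(lfp, 4, 12))
  # trough-referenced 270 deg corresponds to analytic phase 90 deg
  set.seed(6)
  cand <- sort(runif(20000, 0, 60))
  ci <- floor(cand * 2000) + 1
  keep <- runif(20000) < exp(3 * cos(ph$data[ci] - pi / 2)) / exp(3)
  st <- cand[keep]
  segs <- tibble::tibble(start_s = 1, end_s = 59)
  tp <- theta_phase_pref(st, segs, lfp)
  expect_equal(tp$preferred_phase_deg, 270, tolerance = 10 / 270)
  expect_lt(tp$rayleigh_p, 0.05)

  expect_true(classify_pv_basket(TRUE, 270))
  expect_false(classify_pv_basket(TRUE, 100))
  expect_false(classify_pv_basket(FALSE, 270))
  expect_false(classify_pv_basket(TRUE, NA_real_))
})
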