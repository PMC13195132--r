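test_that("spike width is trough-to-peak and rejects malformed waveforms", {
  rate <- 20000
  tt <- seq(0, 2, by = 1000 / rate)            # ms grid
  wf <- -exp(-(tt - 1.0)^2 / 0.005) + 0.5 * exp(-(tt - 1.6)^2 / 0.02)
  expect_equal(spike_width(wf, rate), 0.6, tolerance = 0.05)

  narrow <- -exp(-(tt - 1.0)^2 / 0.005) + 0.5 * exp(-(tt - 1.3)^2 / 0.01)
  expect_equal(spike_width(narrow, rate), 0.3, tolerance = 0.05)

  expect_true(is.na(spike_width(rev(wf), rate)))  # reversed: no honest peak
  expect_true(is.na(spike_width(c(1, 0.5, 0.2), rate)))
})

test_that("ACG first moment separates tonic from bursty firing", {
  set.seed(1)
  pois <- cumsum(rexp(3000, 5))
  acg <- acg_first_moment(pois)
  expect_equal(acg$first_moment_ms, 25, tolerance = 1 / 25)  # flat ACG
  expect_gte(acg$peak_count, 10)

  # pairs at 3 ms: mass concentrated at short lags
  bursty <- as.vector(vapply(seq(0, 299), function(i) c(i, i + 0.003),
                             numeric(2)))
  acg_b <- acg_first_moment(bursty)
  expect_lt(acg_b$first_moment_ms, 10)

  sparse <- c(0, 10, 20, 30, 40)
  expect_lt(acg_first_moment(sparse)$peak_count, 10)
})

test_that("classification matches the strict-inequality truth table on a grid", {
  widths <- seq(0.1, 1.2, length.out = 100)
  fms <- seq(1, 45, length.out = 100)
  grid <- expand.grid(width_ms = widths, first_moment_ms = fms)
  got <- classify_unit(grid$width_ms, grid$first_moment_ms)
  want <- apply(grid, 1, function(r) {
    if (r[1] > 0.5 && r[2] < 25) "pyramidal"
    else if (r[1] < 0.5 && r[2] > 20) "fs_interneuron"
    else "unclassified"
  })
  expect_equal(got, unname(want))

  # explicit boundary and example cases
  expect_equal(classify_unit(0.6, 20), "pyramidal")
  expect_equal(classify_unit(0.4, 30), "fs_interneuron")
  expect_equal(classify_unit(0.6, 30), "unclassified")
  expect_equal(classify_unit(0.5, 10), "unclassified")
  expect_equal(classify_unit(NA_real_, 10), "excluded")
})

test_that("firing-rate categories use class-specific cutpoints", {
  expect_equal(rate_category(0.5, "pyramidal"), "low")
  expect_equal(rate_category(3, "pyramidal"), "medium")
  expect_equal(rate_category(6, "pyramidal"), "high")
  expect_equal(rate_category(10, "fs_interneuron"), "low")
  expect_equal(rate_category(30, "fs_interneuron"), "medium")
  expect_equal(rate_category(45, "fs_interneuron"), "high")
  expect_true(is.na(rate_category(1, "unclassified")))
})

test_that("burst arithmetic matches hand-computed values exactly", {
  # ISI sequence [3,3,200,3,200] ms -> 6 spikes, one 3-spike burst
  st <- cumsum(c(0, 3, 3, 200, 3, 200)) / 1000
  br <- detect_bursts(st, total_time_s = 10)
  expect_equal(nrow(br$bursts), 1)
  expect_equal(br$bursts$n_spikes, 3L)
  expect_equal(br$burst_index, 0.5)
  expect_equal(br$burst_event_rate_hz, 0.1)

  # pairs only: no burst at min_spikes = 3
  st2 <- cumsum(c(0, 3, 200, 3, 200)) / 1000
  expect_equal(nrow(detect_bursts(st2, total_time_s = 10)$bursts), 0)

  # all ISIs short: one maximal burst containing every spike
  st3 <- cumsum(c(0, 3, 3, 3, 3)) / 1000
  br3 <- detect_bursts(st3, total_time_s = 10)
  expect_equal(nrow(br3$bursts), 1)
  expect_equal(br3$bursts$n_spikes, 5L)
  expect_equal(br3$burst_index, 1)

  expect_error(detect_bursts(c(2, 1), total_time_s = 10), "sorted")
})

test_that("bursting spike count is monotone in the ISI threshold", {
  g <- gen_spike_train(spike_train_spec(duration_s = 300, base_rate_hz = 3,
                                        burst_rate_hz = 0.2,
                                        spikes_per_burst = c("3" = 0.5,
                                                             "4" = 0.3,
                                                             "5" = 0.2),
                                        intra_burst_isi_ms = 3, seed = 9))
  counts <- sapply(c(5, 10, 15), function(th)
    sum(detect_bursts(g$spike_times, isi_thresh_ms = th,
                      total_time_s = 300)$bursts$n_spikes))
  expect_true(all(diff(counts) >= 0))
  bi <- detect_bursts(g$spike_times, total_time_s = 300)$burst_index
  expect_gte(bi, 0)
  expect_lte(bi, 1)
})

test_that("ISI distributions report the designed sub-5 ms fraction", {
  st <- cumsum(rep(0.003, 100))
  d <- isi_distribution(st)
  expect_equal(d$cum_frac_5ms, 1)

  st2 <- cumsum(rep(0.050, 100))
  d2 <- isi_distribution(st2)
  expect_equal(sum(d2$histogram$count), 0)
  expect_equal(d2$cum_frac_5ms, 0)

  g <- gen_spike_train(spike_train_spec(duration_s = 600, base_rate_hz = 1,
                                        burst_rate_hz = 0.2,
                                        spikes_per_burst = c("3" = 1),
                                        intra_burst_isi_ms = 3, seed = 10))
  d3 <- isi_distribution(g$spike_times)
  # designed fraction: each burst contributes 2 short ISIs
  n_burst <- nrow(g$truth$burst_windows)
  expected <- 2 * n_burst / (length(g$spike_times) - 1)
  expect_equal(d3$cum_frac_5ms, expected, tolerance = 3 * sqrt(expected / 500) + 0.01)
})

test_that("unit_table assembles metrics, labels and burst stats", {
  g1 <- gen_spike_train(spike_train_spec(duration_s = 300, base_rate_hz = 6,
                                         burst_rate_hz = 0.3, seed = 11))
  g2 <- gen_spike_train(spike_train_spec(duration_s = 300, base_rate_hz = 30,
                                         burst_rate_hz = 0, seed = 12))
  spikes <- dplyr::bind_rows(
    tibble::tibble(unit_id = 1, time_s = g1$spike_times),
    tibble::tibble(unit_id = 2, time_s = g2$spike_times))
  tt <- seq(0, 2, by = 0.05)
  wf_py <- -exp(-(tt - 0.5)^2 / 0.02) + 0.45 * exp(-(tt - 1.25)^2 / 0.08)
  wf_fs <- -exp(-(tt - 0.5)^2 / 0.01) + 0.5 * exp(-(tt - 0.85)^2 / 0.03)
  ut <- unit_table(spikes, 300, waveforms = list("1" = wf_py, "2" = wf_fs))
  expect_equal(nrow(ut), 2)
  expect_equal(ut$label[1], "pyramidal")
  expect_equal(ut$label[2], "fs_interneuron")
  expect_gt(ut$burst_index[1], 0)
  # a 30 Hz tonic unit only rarely strings three sub-5 ms intervals together
  expect_lt(ut$burst_index[2], 0.05)
  expect_gt(ut$burst_index[1], ut$burst_index[2])
})
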