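test_that("a sustained high-SNR theta oscillation is one near-complete epoch", {
  g <- gen_lfp(lfp_spec(10, 1000, 0, 1.5,
                        oscillations = data.frame(freq_hz = 8, amp = 2,
                                                  bandwidth_hz = 0),
                        seed = 1))
  ep <- detect_osc_epochs(g$ts, "theta")
  expect_gte(epoch_coverage(ep, 10), 0.95)
  expect_true(all(ep$mean_freq_hz >= 4 & ep$mean_freq_hz <= 12))
  expect_true(all(ep$n_cycles >= 2))
})

test_that("pure 1/f noise yields little theta-epoch coverage", {
  fc <- sapply(1:10, function(s) {
    g <- gen_lfp(lfp_spec(10, 1000, 0, 1.5, seed = 100 + s))
    epoch_coverage(detect_osc_epochs(g$ts, "theta"), 10)
  })
  expect_lt(mean(fc), 0.10)
})

test_that("a 1.5-cycle burst does not become an epoch of its own", {
  detected <- sapply(1:10, function(s) {
    g <- gen_lfp(lfp_spec(10, 1000, 0, 1.5, seed = 200 + s))
    x <- g$ts$data
    tt <- seq(0, 1.5 / 8, by = 1 / 1000)
    x[5000 + seq_along(tt)] <- x[5000 + seq_along(tt)] + 2 * sin(2 * pi * 8 * tt)
    ep <- detect_osc_epochs(new_ts(x, 1000), "theta")
    # an epoch attributable to the burst would be an ~8 Hz episode inside
    # the burst's wavelet-smeared neighborhood
    any(ep$start_s >= 5.0 - 0.28 & ep$end_s <= 5.1875 + 0.28 &
          abs(ep$mean_freq_hz - 8) <= 1)
  })
  expect_equal(sum(detected), 0)
})

test_that("epochs are disjoint, sorted, and duty cycle grows with amplitude", {
  cov <- sapply(c(0.3, 0.8, 2), function(a) {
    g <- gen_lfp(lfp_spec(10, 1000, 0, 1.5,
                          oscillations = data.frame(freq_hz = 8, amp = a,
                                                    bandwidth_hz = 0.3),
                          seed = 5))
    ep <- detect_osc_epochs(g$ts, "theta")
    if (nrow(ep) > 1) {
      expect_true(all(diff(ep$start_s) > 0))
      expect_true(all(ep$start_s[-1] >= ep$end_s[-nrow(ep)]))
    }
    epoch_coverage(ep, 10)
  })
  expect_true(all(diff(cov) >= 0))
  g <- gen_lfp(lfp_spec(5, 1000, 0, 1, seed = 1))
  expect_error(detect_osc_epochs(g$ts, c(0.1, 4)), "grid")
})

test_that("run/rest segmentation applies thresholds and the 2 s minimum", {
  sp <- gen_speed_trace(data.frame(duration_s = 20, mean_speed = 10), seed = 1)
  seg <- run_rest_segments(sp$ts)
  expect_equal(seg$label, "running")

  # a 1.5 s bout between rests is discarded
  sp2 <- gen_speed_trace(data.frame(duration_s = c(5, 1.5, 5),
                                    mean_speed = c(0, 10, 0)), seed = 2)
  seg2 <- run_rest_segments(sp2$ts)
  expect_false("running" %in% seg2$label)

  # ambiguous 3 cm/s block is excluded from both states
  sp3 <- gen_speed_trace(data.frame(duration_s = 10, mean_speed = 3), seed = 3)
  expect_equal(run_rest_segments(sp3$ts)$label, "ambiguous")

  # alternating blocks recovered within one sample-and-hold step
  sp4 <- gen_speed_trace(data.frame(duration_s = c(5, 5, 5, 5),
                                    mean_speed = c(10, 0, 10, 0)), seed = 4)
  seg4 <- run_rest_segments(sp4$ts)
  expect_equal(seg4$label, c("running", "resting", "running", "resting"))
  expect_equal(seg4$start_s, c(0, 5, 10, 15), tolerance = 0.05)

  expect_error(run_rest_segments(new_ts(c(-1, 1), 50)), "Negative")
})

test_that("T/D-plus-speed segmentation labels theta and non-theta states", {
  theta_lfp <- gen_lfp(lfp_spec(20, 2000, 0, 1.5,
                                oscillations = data.frame(freq_hz = 8, amp = 3,
                                                          bandwidth_hz = 0),
                                seed = 2))$ts
  run_speed <- gen_speed_trace(data.frame(duration_s = 20, mean_speed = 10),
                               seed = 3)$ts
  seg <- theta_state_segments(theta_lfp, run_speed)
  expect_equal(seg$label[which.max(seg$end_s - seg$start_s)], "theta")
  expect_gt(sum((seg$end_s - seg$start_s)[seg$label == "theta"]), 18)

  slow_lfp <- gen_lfp(lfp_spec(20, 2000, 0, 1.5,
                               oscillations = data.frame(freq_hz = 3, amp = 3,
                                                         bandwidth_hz = 0),
                               seed = 2))$ts
  rest_speed <- gen_speed_trace(data.frame(duration_s = 20, mean_speed = 0),
                                seed = 3)$ts
  seg2 <- theta_state_segments(slow_lfp, rest_speed)
  expect_gt(sum((seg2$end_s - seg2$start_s)[seg2$label == "non_theta"]), 18)

  # high T/D with intermediate speed is ambiguous
  amb_speed <- gen_speed_trace(data.frame(duration_s = 20, mean_speed = 3),
                               noise_sd = 0.1, seed = 3)$ts
  seg3 <- theta_state_segments(theta_lfp, amb_speed)
  expect_equal(unique(seg3$label), "ambiguous")

  # labels partition the timeline with no overlap
  expect_equal(seg$start_s[-1], seg$end_s[-nrow(seg)])
  expect_error(theta_state_segments(theta_lfp,
                                    gen_speed_trace(data.frame(duration_s = 5,
                                                               mean_speed = 1),
                                                    seed = 1)$ts),
               "cover")
})
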