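test_that("10-ms rolling mean smooths with a centered 21-sample window at 2000 Hz", {
  const <- channel_trace(rep(3, 100), fs = 2000, units = "m/s^2")
  expect_equal(rolling_mean(const, 10)$samples, rep(3, 100))
  # unit impulse spreads into a plateau of 1/21 over 21 samples
  imp <- channel_trace(c(rep(0, 50), 1, rep(0, 50)), fs = 2000, units = "m/s^2")
  sm <- rolling_mean(imp, 10)$samples
  expect_equal(sm[41:61], rep(1 / 21, 21), tolerance = 1e-12)
  expect_equal(sm[40], 0)
  expect_equal(sm[62], 0)
  # a linear ramp is unchanged in the interior
  ramp <- channel_trace(seq_len(200), fs = 2000, units = "m/s^2")
  expect_equal(rolling_mean(ramp, 10)$samples[20:180],
               seq_len(200)[20:180], tolerance = 1e-9)
})

test_that("gravity calibration solves the two-point equations", {
  cal <- calibrate_gravity(rep(1, 100), rep(-1, 100))
  expect_equal(cal$gain, 9.81)
  expect_equal(cal$offset, 0)
  cal2 <- calibrate_gravity(rep(2, 100), rep(0, 100))
  expect_equal(cal2$gain, 9.81)
  expect_equal(cal2$offset, 1)
  expect_error(calibrate_gravity(rep(0, 10), rep(0, 10)), "swapped")
})

test_that("foot strikes are recovered from synthetic trials and scale-robust", {
  cfg <- one_muscle_config(n_subjects = 1, seed = 5, n_cycles = 8)
  set.seed(5)
  g <- generate_running_trial(NULL, "control", cfg)
  ev <- detect_foot_strikes(g$trial$channels$foot,
                            stride_freq_hint = cfg$stride_frequency)
  expect_length(ev$times, length(g$truth$strike_idx))
  expect_true(all(abs(ev$times - g$truth$strike_idx) <= 0.005 * cfg$fs))
  # doubling the amplitude leaves the MAD-based detection unchanged
  doubled <- g$trial$channels$foot
  doubled$samples <- 2 * doubled$samples
  ev2 <- detect_foot_strikes(doubled, stride_freq_hint = cfg$stride_frequency)
  expect_equal(ev2$times, ev$times)
  expect_error(detect_foot_strikes(
    channel_trace(rep(1, 5000), fs = 2000, units = "m/s^2")), "no foot-strike")
})

test_that("flight-phase baselining recovers the vertical sensor offset", {
  fs <- 2000
  # stance pulses with flight plateaus displaced to 0.3
  t <- seq(0, 4, by = 1 / fs)
  u <- t %% 0.5
  v <- ifelse(u < 0.3, 20 * sin(pi * u / 0.3)^2, 0) + 0.3
  tr <- channel_trace(v, fs = fs, units = "m/s^2")
  ev <- event_set("foot_strikes", times = as.integer(round(seq(0, 3.5, 0.5) * fs)))
  off <- vertical_baseline_flight(tr, ev)
  expect_equal(off, 0.3, tolerance = 1e-6)
  tr2 <- tr; tr2$samples <- tr2$samples - off
  expect_equal(vertical_baseline_flight(tr2, ev), 0, tolerance = 1e-6)
  # degenerate constant trace: offset is the constant
  const <- channel_trace(rep(5, fs), fs = fs, units = "m/s^2")
  ev2 <- event_set("foot_strikes", times = c(0L, 500L, 1000L))
  expect_equal(vertical_baseline_flight(const, ev2), 5)
})

test_that("fore-aft offsets follow the per-mode definitions", {
  fs <- 1000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  a <- 3.2
  sine <- channel_trace(a * sin(2 * pi * t / 0.5), fs = fs, units = "m/s^2")
  ev <- event_set("foot_strikes", times = as.integer(seq(0, 2000, 500)[1:4]))
  expect_equal(horizontal_offset(sine, ev, "cycle_mean"), 0, tolerance = 1e-6)
  expect_equal(horizontal_offset(sine, ev, "step_peaks"), a, tolerance = 1e-4)
  expect_equal(horizontal_offset(sine, ev, "step_minima"), -a, tolerance = 1e-4)
  expect_error(horizontal_offset(sine, event_set("foot_strikes", times = 0L),
                                 "cycle_mean"), "complete cycle")
})

test_that("step statistics report per-step peaks, means and half-step means", {
  fs <- 1000
  n <- 1000
  vert <- channel_trace(rep(9.31, n), fs = fs, units = "m/s^2")
  t <- (seq_len(n) - 1) / fs
  a <- 2.5
  # full sine period per 0.5-s step: second-half mean = 2A/pi
  fa <- channel_trace(-a * sin(2 * pi * t / 0.5), fs = fs, units = "m/s^2")
  ev <- event_set("foot_strikes", times = c(0L, 500L))
  st <- step_stats(vert, fa, ev)
  expect_equal(nrow(st), 1L)
  expect_equal(st$mean_vertical, 9.31)
  expect_equal(st$peak_positive_vertical, 9.31)
  expect_equal(st$mean_fore_aft, 0, tolerance = 1e-2)
  expect_equal(st$mean_fore_aft_second_half, 2 * a / pi, tolerance = 1e-2)
  # adding a constant shifts whole-step means linearly
  fa_b <- fa; fa_b$samples <- fa_b$samples + 1.5
  st_b <- step_stats(vert, fa_b, ev)
  expect_equal(st_b$mean_fore_aft, st$mean_fore_aft + 1.5, tolerance = 1e-9)
})

test_that("step means are invariant to constant shift plus re-baselining", {
  cfg <- one_muscle_config(n_subjects = 1, seed = 21, n_cycles = 6)
  set.seed(21)
  g <- generate_running_trial(NULL, "control", cfg)
  vert <- rolling_mean(g$trial$channels$neck_vertical, 10)
  ev <- detect_foot_strikes(g$trial$channels$foot, cfg$stride_frequency)
  base1 <- vertical_baseline_flight(vert, ev)
  shifted <- vert; shifted$samples <- shifted$samples + 4.2
  base2 <- vertical_baseline_flight(shifted, ev)
  expect_equal(base2 - base1, 4.2, tolerance = 1e-9)
})

test_that("tilt correction is the cosine of the lean angle", {
  expect_equal(tilt_correction(0)$factor, 1)
  expect_equal(round(tilt_correction(28)$factor, 3), 0.883)
  expect_equal(tilt_correction(60)$factor, 0.5)
  expect_error(tilt_correction(95), "90")
})
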