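test_that("quiet-standing baseline finds the standing force level", {
  fs <- 2000
  const <- channel_trace(rep(723, 3 * fs), fs = fs, units = "N")
  expect_equal(body_weight_baseline(const), 723)
  # m = 73.7 kg at g = 9.81 stands at 723.0 N
  expect_equal(round(73.7 * 9.81, 1), 723.0)
  # a moving segment is ignored in favour of the quiet one
  x <- c(rep(723, 2 * fs), 723 + 400 * sin(seq(0, 8 * pi, length.out = fs)))
  expect_equal(body_weight_baseline(channel_trace(x, fs = fs, units = "N")),
               723, tolerance = 1e-6)
  wob <- channel_trace(723 + 300 * sin(seq(0, 60 * pi, length.out = 2 * fs)),
                       fs = fs, units = "N")
  expect_error(body_weight_baseline(wob), "quiet")
})

test_that("added-gravity standing baseline includes the applied force", {
  cfg <- noiseless_config(n_subjects = 1, seed = 3)
  sub <- fixed_subject(73.7, cfg)
  set.seed(3)
  g <- generate_jump_trial(sub, "jump_gravity", cfg)
  w <- body_weight_baseline(g$trial$channels$force_z)
  expect_equal(w, 73.7 * 9.81 + 270, tolerance = 1e-6)
})

test_that("jump phases are recovered within 5 ms of ground truth", {
  cfg <- synthetic_config(n_subjects = 1, seed = 13)
  sub <- fixed_subject(73.7, cfg)
  set.seed(13)
  for (cond in c("jump_control", "jump_gravity")) {
    g <- generate_jump_trial(sub, cond, cfg)
    force <- g$trial$channels$force_z
    w <- body_weight_baseline(force)
    ph <- detect_jump_phases(force, w)
    tol <- 0.005 * cfg$fs
    expect_lt(abs(ph$onset - g$truth$onset), tol)
    expect_lt(abs(ph$takeoff - g$truth$takeoff), tol)
    expect_lt(abs(ph$landing - g$truth$landing), tol)
    # flight duration matches truth within 2 samples
    expect_lte(abs((ph$landing - ph$takeoff) -
                     (g$truth$landing - g$truth$takeoff)), 2L)
  }
  flat <- channel_trace(rep(723, 2.5 * cfg$fs), fs = cfg$fs, units = "N")
  expect_error(detect_jump_phases(flat, 723), "onset")
})

test_that("impulse-momentum kinetics match hand values and invariants", {
  fs <- 2000
  w <- 723
  # force == weight: zero impulse and velocity
  eq <- channel_trace(rep(w, 3 * fs), fs = fs, units = "N")
  ph <- event_set("jump_phases", onset = 1000L, takeoff = 3000L, landing = 4000L)
  kin <- com_kinematics(eq, 73.7, w, ph)
  expect_equal(kin$net_impulse, 0)
  expect_equal(kin$takeoff_velocity, 0)
  # rectangular net pulse: 500 N for 0.3 s -> 150 N*s
  x <- rep(w, 3 * fs)
  x[1001:(1000 + 0.3 * fs)] <- w + 500
  rect <- channel_trace(x, fs = fs, units = "N")
  ph2 <- event_set("jump_phases", onset = 1000L, takeoff = 1000L + 600L,
                   landing = 4000L)
  kin2 <- com_kinematics(rect, 73.7, w, ph2)
  expect_equal(kin2$net_impulse, 150, tolerance = 1e-2)
  # synthetic maximal jump at the printed group means
  cfg <- noiseless_config(n_subjects = 1, seed = 17)
  sub <- fixed_subject(73.7, cfg)
  set.seed(17)
  g <- generate_jump_trial(sub, "jump_control", cfg)
  force <- g$trial$channels$force_z
  wj <- body_weight_baseline(force)
  phj <- detect_jump_phases(force, wj)
  kj <- com_kinematics(force, 73.7, wj, phj)
  expect_equal(kj$net_impulse, 203.7, tolerance = 0.005 * 203.7)
  expect_equal(kj$takeoff_velocity, 203.7 / 73.7, tolerance = 0.005 * 2.764)
  expect_equal(kj$jump_height, (203.7 / 73.7)^2 / (2 * 9.81), tolerance = 0.01)
})

test_that("impulse, velocity and flight-time height are mutually consistent", {
  cfg <- synthetic_config(n_subjects = 1, seed = 29)
  set.seed(29)
  for (cond in c("jump_control", "jump_gravity", "jump_mass")) {
    sub <- fixed_subject(70 + 5 * runif(1), cfg)
    g <- generate_jump_trial(sub, cond, cfg)
    force <- g$trial$channels$force_z
    w <- body_weight_baseline(force)
    ph <- detect_jump_phases(force, w)
    mass <- g$truth$mass
    kin <- com_kinematics(force, mass, w, ph)
    expect_lt(abs(kin$net_impulse - mass * kin$takeoff_velocity) /
                kin$net_impulse, 1e-3)
    expect_lt(abs(kin$jump_height_flight - kin$jump_height) / kin$jump_height,
              0.03)
  }
})

test_that("a constant applied force cancels when the effective weight rises with it", {
  fs <- 2000
  x <- rep(723, fs)
  x[200:400] <- 723 + 300
  f1 <- channel_trace(x, fs = fs, units = "N")
  f2 <- channel_trace(x + 270, fs = fs, units = "N")
  ph <- event_set("jump_phases", onset = 100L, takeoff = 500L, landing = 800L)
  k1 <- com_kinematics(f1, 73.7, 723, ph)
  k2 <- com_kinematics(f2, 73.7, 723 + 270, ph)
  expect_equal(k1$com_acceleration, k2$com_acceleration, tolerance = 1e-12)
})

test_that("percent impulse changes reproduce the printed group arithmetic", {
  expect_equal(impulse_change(203.7, 159.5)$percent_change, 21.7)
  expect_equal(impulse_change(100, 100)$percent_change, 0)
  ch <- impulse_change(203.7, 210.5)
  expect_equal(ch$percent_change, -3.3)
  expect_equal(round(ch$percent_magnitude), 3)
  expect_error(impulse_change(0, 100), "> 0")
})

test_that("effort series tabulates impulses by nominal effort", {
  efforts <- rep(c(0.10, 0.25, 0.50, 0.75, 0.90), each = 4)
  imps <- 200 * efforts + rnorm(20, 0, 1)
  tab <- effort_series(efforts, imps)
  expect_equal(nrow(tab), 20L)
  means <- tapply(tab$net_impulse, tab$effort, mean)
  expect_true(all(diff(means) > 0))
  expect_error(effort_series(rep(0.5, 4), 1:4), "2 effort")
})
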