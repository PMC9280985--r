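test_that("EMG generation is AM of a unit-mean-rectified carrier", {
  cfg <- synthetic_config(background_noise_pct = 0)
  set.seed(1)
  zero <- generate_emg_channel(rep(0, 5000), cfg)
  expect_equal(zero$samples, rep(0, 5000))
  # per-trace carrier normalization makes the rectified mean equal the
  # envelope exactly for constant envelopes
  set.seed(2)
  c1 <- generate_emg_channel(rep(5, 20000), cfg)
  set.seed(3)
  c2 <- generate_emg_channel(rep(10, 20000), cfg)
  expect_equal(mean(abs(c2$samples)) / mean(abs(c1$samples)), 2,
               tolerance = 1e-9)
  expect_equal(mean(abs(c1$samples)), 0.05 * cfg$mvc_volts, tolerance = 1e-9)
  expect_error(generate_emg_channel(c(-1, 1), cfg), "non-negative")
})

test_that("identical seeds reproduce identical traces and studies", {
  cfg <- synthetic_config(n_subjects = 2, seed = 9, n_cycles = 4)
  set.seed(5); a <- generate_emg_channel(rep(3, 4000), cfg)
  set.seed(5); b <- generate_emg_channel(rep(3, 4000), cfg)
  expect_identical(a$samples, b$samples)
  s1 <- generate_study(cfg, conditions = "control")
  s2 <- generate_study(cfg, conditions = "control")
  expect_identical(s1$subjects$S02$trials$control$channels$splenius_capitis$samples,
                   s2$subjects$S02$trials$control$channels$splenius_capitis$samples)
  expect_identical(s1$subjects$S01$params$body_mass,
                   s2$subjects$S01$params$body_mass)
})

test_that("running trials carry evenly spaced strikes and flight at zero", {
  cfg <- noiseless_config(n_subjects = 1, seed = 41, n_cycles = 20)
  sub <- fixed_subject(73.7, cfg)
  set.seed(41)
  g <- generate_running_trial(sub, "control", cfg)
  idx <- g$truth$strike_idx
  expect_length(idx, 21L)
  expect_equal(diff(idx), rep(round(cfg$fs / 1.4), 20), tolerance = 1)
  # flight samples of the vertical channel sit at zero proper acceleration
  vert <- g$trial$channels$neck_vertical$samples
  step <- round(cfg$fs / (2 * 1.4))
  contact <- round(cfg$fs * cfg$duty_factor / 1.4)
  flight <- unlist(lapply(idx[1:10], function(s)
    (s + contact + 2):(s + step - 2)))
  expect_lt(max(abs(vert[flight + 1])), 1e-9)
  expect_error(generate_running_trial(sub, "jump_control", cfg), "running")
})

test_that("condition multipliers scale envelopes exactly", {
  cfg <- noiseless_config(n_subjects = 1, seed = 43, n_cycles = 6)
  sub <- fixed_subject(73.7, cfg)
  set.seed(43)
  gc <- generate_running_trial(sub, "control", cfg)
  set.seed(44)
  gf <- generate_running_trial(sub, "forward_pull", cfg)
  expect_equal(gf$truth$multipliers[["sternohyoid"]], 3.63)
  expect_equal(gf$truth$env_means[["sternohyoid"]] /
                 gc$truth$env_means[["sternohyoid"]], 3.63, tolerance = 1e-9)
  # noiseless rectified means inherit the ratio up to carrier statistics
  rf <- mean(abs(gf$trial$channels$sternohyoid$samples))
  rc <- mean(abs(gc$trial$channels$sternohyoid$samples))
  expect_equal(rf / rc, 3.63, tolerance = 0.05 * 3.63)
})

test_that("jump force curves hit the target impulse and phase structure", {
  cfg <- noiseless_config(n_subjects = 1, seed = 47)
  sub <- fixed_subject(73.7, cfg)
  set.seed(47)
  g <- generate_jump_trial(sub, "jump_control", cfg)
  force <- g$trial$channels$force_z$samples
  w <- g$truth$effective_weight
  win <- (g$truth$onset + 1L):(g$truth$takeoff + 1L)
  j_meas <- pracma::trapz(seq_along(win) / cfg$fs, force[win] - w)
  expect_lt(abs(j_meas - g$truth$net_impulse) / g$truth$net_impulse, 0.005)
  expect_equal(g$truth$takeoff_velocity, 203.7 / 73.7, tolerance = 1e-9)
  expect_equal(g$truth$net_impulse, 203.7, tolerance = 1e-9)
  # degenerate jump: flat at body weight, no flight
  cfg0 <- noiseless_config(n_subjects = 1,
                           jump = list(depth_frac = 0,
                                       target_net_impulse = c(
                                         jump_control = 0, jump_gravity = 0,
                                         jump_mass = 0)))
  expect_error(generate_jump_trial(sub, "jump_control", cfg0), NA)
  set.seed(48)
  g0 <- generate_jump_trial(sub, "jump_control", cfg0)
  expect_equal(unique(g0$trial$channels$force_z$samples), 73.7 * 9.81)
  expect_error(detect_jump_phases(g0$trial$channels$force_z, 73.7 * 9.81),
               "onset")
})

test_that("unreachable jump targets are rejected", {
  # a 20-ms push would demand an implausible peak force
  cfg <- noiseless_config(n_subjects = 1, jump = list(push_s = 0.02))
  sub <- fixed_subject(73.7, cfg)
  expect_error({set.seed(1); generate_jump_trial(sub, "jump_control", cfg)},
               "unreachable")
})

test_that("MVC and rest references are constructed as specified", {
  cfg <- synthetic_config(n_subjects = 1, seed = 51)
  sub <- fixed_subject(73.7, cfg)
  set.seed(51)
  refs <- generate_mvc_and_rest(sub, cfg)
  expect_length(refs$mvc_flexion, 4L)
  expect_length(refs$mvc_extension, 4L)
  n_trials <- length(refs$mvc_flexion) + length(refs$mvc_extension) + 1L
  expect_equal(n_trials, 9L)
  # rest channels carry background noise only
  rest_rect <- mean(abs(refs$rest$channels$sternohyoid$samples))
  noise_sd <- cfg$background_noise_pct / 100 * cfg$mvc_volts
  expect_equal(rest_rect, noise_sd * sqrt(2 / pi), tolerance = 0.05)
  # noiseless MVC trials share the construction amplitude exactly
  cfg0 <- noiseless_config(n_subjects = 1)
  set.seed(52)
  refs0 <- generate_mvc_and_rest(sub, cfg0)
  amps <- vapply(refs0$mvc_flexion, function(tr)
    mean(abs(tr$channels$sternohyoid$samples)), numeric(1))
  expect_equal(amps, rep(cfg0$mvc_volts, 4), tolerance = 1e-9)
  expect_equal(max(abs(refs0$rest$channels$sternohyoid$samples)), 0)
})

test_that("availability masks propagate to the manifest", {
  cfg <- synthetic_config(n_subjects = 3, seed = 53, n_cycles = 4)
  st <- generate_study(cfg, conditions = "control",
                       drop_muscles = list(S02 = "masseter"))
  expect_false("masseter" %in% st$subjects$S02$muscles)
  expect_true("masseter" %in% st$subjects$S01$muscles)
  expect_equal(st$manifest$muscles$S02, setdiff(MUSCLES, "masseter"))
})
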