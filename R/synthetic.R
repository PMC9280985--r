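# Synthetic multi-subject study generator.
#
# Generates running, jumping, MVC and rest trials with known ground truth:
# EMG channels are a band-limited Gaussian carrier amplitude-modulated by a
# stride- or jump-phase-locked activation envelope (%MVC) plus additive
# background noise, so the expected mean rectified amplitude is
# proportional to the envelope; accelerometer channels carry stride-
# periodic proper acceleration with flight phases; jump force-time curves
# are built so the net impulse over the detected push-off window equals the
# configured target exactly (the push amplitude is solved for by linearity).
# Per-muscle, per-condition effect multipliers scale the whole envelope, so
# the true integrated-activity ratio between a manipulation and its control
# equals the configured multiplier.

FLEXOR_MUSCLES <- c("sternohyoid", "sternocleidomastoid", "masseter")

default_envelopes <- function() {
  env <- function(tonic, phases, amps, width = 0.06)
    list(tonic = tonic, burst_phases = phases, burst_amps = amps,
         burst_widths = rep_len(width, length(phases)))
  list(
    sternohyoid         = env(1.0, c(0.20, 0.70), c(3.0, 2.5)),
    sternocleidomastoid = env(1.0, c(0.20, 0.70), c(2.5, 3.5)),
    masseter            = env(0.8, c(0.25, 0.75), c(1.5, 1.5), 0.08),
    levator_scapulae    = env(1.2, c(0.02, 0.52), c(3.5, 4.5), 0.05),
    upper_trapezius     = env(1.5, c(0.95, 0.45), c(4.0, 4.0), 0.05),
    splenius_capitis    = env(1.2, c(0.95, 0.45), c(4.0, 4.0), 0.05),
    semispinalis_r      = env(1.5, c(0.95, 0.45), c(5.0, 5.0), 0.05),
    semispinalis_l      = env(1.5, c(0.95, 0.45), c(5.0, 5.0), 0.05)
  )
}

#' Default per-muscle, per-condition effect multipliers
#'
#' Ships the group-mean activation ratios of the running force
#' manipulations (added head mass; forward and rearward pulls, alone and
#' with added head mass) as the generator's true effect sizes, so recovery
#' tests of the full pipeline are one command. Jump-condition multipliers
#' default to 1 (the study's null result for maximal jumps).
#'
#' @return data frame: one row per muscle, one column per condition.
#' @export
default_effect_multipliers <- function() {
  df <- data.frame(
    muscle = MUSCLES,
    control = 1,
    head_mass          = c(1.24, 1.30, 0.71, 1.21, 1.26, 1.10, 1.07, 1.10),
    forward_pull       = c(3.63, 2.74, 1.53, 1.78, 1.23, 1.50, 1.33, 1.29),
    forward_pull_mass  = c(3.74, 2.65, 0.84, 1.96, 2.03, 2.08, 1.37, 1.68),
    rearward_pull      = c(2.27, 1.72, 1.17, 2.15, 1.96, 2.01, 1.82, 1.80),
    rearward_pull_mass = c(2.32, 1.59, 0.77, 2.18, 1.91, 2.13, 1.84, 1.87),
    jump_control = 1, jump_gravity = 1, jump_mass = 1, jump_submax = 1
  )
  rownames(df) <- df$muscle
  df
}

#' Synthetic study configuration
#'
#' Collects every tunable of the generator with study-condition defaults:
#' 16 subjects, 2000 Hz sampling, 20 locomotor cycles per running trial,
#' 4.5 kg added head mass, 175 N horizontal pull, a 270 N added downward
#' force for added-gravity jumps, and jump net impulses of 203.7 / 159.5 /
#' 210.5 N*s (control / added gravity / added head mass, for a 73.7 kg
#' subject; impulses scale with body mass).
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed; a fixed seed reproduces the study exactly.
#' @param fs sampling frequency, Hz.
#' @param stride_frequency nominal stride frequency, Hz.
#' @param n_cycles locomotor cycles recorded per running trial.
#' @param duty_factor stance fraction of the stride cycle (per foot).
#' @param emg_carrier_band EMG carrier band edges in Hz (clamped below the
#'   Nyquist frequency).
#' @param background_noise_pct additive EMG background noise SD, as %MVC.
#' @param mvc_volts nominal (post-amplifier) MVC amplitude in volts;
#'   per-subject, per-muscle values jitter around it.
#' @param body_mass_mean,body_mass_sd subject body mass distribution, kg.
#' @param head_added_mass added head mass, kg.
#' @param pull_force applied horizontal force, N.
#' @param envelopes per-muscle stride envelope specs (tonic %MVC, burst
#'   phases in cycle fractions, burst widths, burst amplitudes %MVC).
#' @param multipliers per-muscle, per-condition effect multipliers (see
#'   [default_effect_multipliers]).
#' @param accel accelerometer construction parameters (per-condition mean
#'   vertical stance acceleration and fore-aft amplitudes/biases, m/s^2).
#' @param jump jump construction parameters (quiet, unweighting, push and
#'   takeoff-drop durations in s; unweighting depth as a fraction of
#'   effective weight; per-condition target net impulses N*s at the
#'   reference 73.7 kg body mass; applied gravity force N; effort-curve
#'   exponent b such that integrated EMG ~ exp(b * impulse)).
#' @param n_jumps maximal-effort jumps per condition.
#' @param submax_efforts nominal effort fractions of the graded jumps.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 16L, seed = 1L, fs = 2000,
                             stride_frequency = 1.4, n_cycles = 20L,
                             duty_factor = 0.38,
                             emg_carrier_band = c(20, 400),
                             background_noise_pct = 0.25,
                             mvc_volts = 1.0,
                             body_mass_mean = 73.7, body_mass_sd = 7.3,
                             head_added_mass = 4.5, pull_force = 175,
                             envelopes = default_envelopes(),
                             multipliers = default_effect_multipliers(),
                             accel = list(), jump = list(),
                             n_jumps = 4L,
                             submax_efforts = c(0.10, 0.25, 0.50, 0.75, 0.90)) {
  if (duty_factor <= 0 || duty_factor >= 1)
    stop("duty_factor must lie in (0, 1)", call. = FALSE)
  for (m in names(envelopes)) {
    e <- envelopes[[m]]
    if (any(e$burst_phases < 0 | e$burst_phases >= 1))
      stop("burst phases must lie in [0, 1)", call. = FALSE)
    if (e$tonic < 0 || any(e$burst_amps < 0))
      stop("envelope amplitudes must be non-negative", call. = FALSE)
  }
  mult_cols <- setdiff(colnames(multipliers), "muscle")
  if (any(as.matrix(multipliers[mult_cols]) <= 0))
    stop("effect multipliers must be > 0", call. = FALSE)
  accel_def <- list(
    vertical_mean = c(control = 9.31, head_mass = 9.11, forward_pull = 10.10,
                      forward_pull_mass = 9.58, rearward_pull = 9.58,
                      rearward_pull_mass = 8.88),
    # control/head-mass fore-aft: zero-mean sine whose second-half (step)
    # mean matches the observed accelerating-portion mean
    fa_second_half_mean = c(control = 2.27, head_mass = 2.05),
    # pull trials: one-signed wave whose whole-step mean matches Table-4
    # style means; peaks (forward) / minima (rearward) sit at true zero
    fa_pull_mean = c(forward_pull = -6.09, forward_pull_mass = -5.75,
                     rearward_pull = 6.65, rearward_pull_mass = 5.67),
    sensor_offset_sd = 0.5, noise_sd = 0.15,
    foot_spike_amp = 40, foot_spike_ms = 10, foot_noise_sd = 0.5)
  jump_def <- list(
    quiet_s = 1.2, unweight_s = 0.35, push_s = 0.30, drop_s = 0.06,
    depth_frac = 0.6,
    target_net_impulse = c(jump_control = 203.7, jump_gravity = 159.5,
                           jump_mass = 210.5),
    impulse_jitter_frac = 0.02,
    applied_gravity_force = 270, force_noise_sd = 3,
    landing_s = 0.15, tail_s = 0.4, ref_mass = 73.7,
    tonic = 0.5, push_amp = 20, flight_amp = 10, landing_amp = 15,
    effort_b = 0.012)
  accel <- utils::modifyList(accel_def, accel)
  jump <- utils::modifyList(jump_def, jump)
  # zero impulse with zero countermovement depth is the allowed degenerate
  # standing "jump"; negative targets are invalid
  if (any(jump$target_net_impulse < 0))
    stop("target net impulses must be >= 0", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed), fs = fs,
    stride_frequency = stride_frequency, n_cycles = as.integer(n_cycles),
    duty_factor = duty_factor, emg_carrier_band = emg_carrier_band,
    background_noise_pct = background_noise_pct, mvc_volts = mvc_volts,
    body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd,
    head_added_mass = head_added_mass, pull_force = pull_force,
    envelopes = envelopes, multipliers = multipliers,
    accel = accel, jump = jump, n_jumps = as.integer(n_jumps),
    submax_efforts = submax_efforts), class = "synthetic_config")
}

condition_multiplier <- function(config, muscle, condition) {
  config$multipliers[muscle, condition]
}

# Band-limited unit-mean-rectified carrier. The carrier is white Gaussian
# noise band-pass filtered (zero-phase) and scaled so mean(|carrier|) = 1,
# making the mean rectified amplitude of envelope * carrier equal the
# envelope exactly on average.
emg_carrier <- function(n, fs, band) {
  hi <- min(band[2L], 0.45 * fs)
  bf <- signal::butter(4, c(band[1L], hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  m <- mean(abs(x))
  if (m > 0) x / m else x
}

#' Generate a synthetic EMG channel
#'
#' Amplitude-modulates a band-limited zero-mean carrier (scaled to unit
#' mean rectified amplitude) with the given %MVC envelope and adds white
#' background noise. Uses the current RNG state; wrap with [set.seed] (or
#' generate through [generate_study]) for reproducibility.
#'
#' @param envelope_pct non-negative envelope in %MVC, one value per sample.
#' @param config a [synthetic_config].
#' @param mvc_volts amplitude in volts corresponding to 100 %MVC.
#' @param noise_sd_volts background noise SD in volts (defaults to the
#'   configured %MVC noise level scaled by `mvc_volts`).
#' @return an EMG [channel_trace] in volts.
#' @export
generate_emg_channel <- function(envelope_pct, config, mvc_volts = config$mvc_volts,
                                 noise_sd_volts = NULL) {
  if (any(envelope_pct < 0))
    stop("envelope must be non-negative", call. = FALSE)
  n <- length(envelope_pct)
  noise_sd_volts <- noise_sd_volts %||%
    (config$background_noise_pct / 100 * mvc_volts)
  x <- envelope_pct / 100 * mvc_volts * emg_carrier(n, config$fs, config$emg_carrier_band)
  if (noise_sd_volts > 0) x <- x + stats::rnorm(n, 0, noise_sd_volts)
  channel_trace(x, fs = config$fs, units = "V")
}

# Stride-phase envelope in %MVC: tonic level plus wrapped-Gaussian bursts.
stride_envelope <- function(phase, spec) {
  env <- rep.int(spec$tonic, length(phase))
  for (k in seq_along(spec$burst_phases)) {
    d <- abs(phase - spec$burst_phases[k])
    d <- pmin(d, 1 - d)  # wrapped distance on the cycle circle
    env <- env + spec$burst_amps[k] * exp(-0.5 * (d / spec$burst_widths[k])^2)
  }
  env
}

# Per-subject latent parameters, drawn once per subject.
draw_subject <- function(config, id) {
  muscles <- names(config$envelopes)
  list(
    id = id,
    body_mass = max(50, stats::rnorm(1, config$body_mass_mean, config$body_mass_sd)),
    stride_frequency = config$stride_frequency * stats::runif(1, 0.95, 1.05),
    mvc_volts = stats::setNames(
      config$mvc_volts * exp(stats::rnorm(length(muscles), 0, 0.2)), muscles),
    amp_scale = stats::setNames(
      exp(stats::rnorm(length(muscles), 0, 0.1)), muscles)
  )
}

#' Generate one synthetic running trial
#'
#' Builds the 8 EMG channels (stride-phase envelopes scaled by the
#' condition's effect multiplier and the subject's amplitude scale), the
#' foot accelerometer (one sharp transient per stride at each right-foot
#' strike), and the neck vertical/fore-aft accelerometers (stance pulses
#' with flight phases at zero proper acceleration; per-condition fore-aft
#' wave shapes and biases; a random per-trial sensor offset that the
#' analysis must remove by baselining).
#'
#' @param subject subject parameter list from the study generator (or
#'   `NULL` to draw one from the current RNG state).
#' @param condition one of the running conditions.
#' @param config a [synthetic_config].
#' @return list with elements `trial` and `truth` (strike indices, true
#'   multipliers, sensor offsets, envelope means).
#' @export
generate_running_trial <- function(subject = NULL, condition, config) {
  if (!condition %in% RUN_CONDITIONS)
    stop("unknown running condition: ", condition, call. = FALSE)
  if (is.null(subject)) subject <- draw_subject(config, "S01")
  fs <- config$fs
  f_stride <- subject$stride_frequency
  lead <- 0.5
  dur <- lead + config$n_cycles / f_stride + 0.5
  n <- round(dur * fs)
  t <- (seq_len(n) - 1L) / fs
  strike_times <- lead + (0:config$n_cycles) / f_stride
  strike_idx <- round(strike_times * fs)  # 0-based
  phase <- ((t - lead) * f_stride) %% 1

  muscles <- names(config$envelopes)
  channels <- list()
  env_means <- numeric(0)
  for (m in muscles) {
    mult <- condition_multiplier(config, m, condition) * subject$amp_scale[[m]]
    env <- mult * stride_envelope(phase, config$envelopes[[m]])
    channels[[m]] <- generate_emg_channel(env, config, subject$mvc_volts[[m]])
    env_means[[m]] <- mean(env)
  }

  acc <- config$accel
  spike_half <- max(1L, round(acc$foot_spike_ms / 1000 * fs / 2))
  foot <- stats::rnorm(n, 0, acc$foot_noise_sd)
  for (s in strike_idx) {
    i <- s + 1L
    for (k in (-spike_half):spike_half) {
      j <- i + k
      if (j >= 1L && j <= n)
        foot[j] <- foot[j] + acc$foot_spike_amp * (1 - abs(k) / (spike_half + 1L))
    }
  }
  channels$foot <- channel_trace(foot, fs = fs, units = "m/s^2")

  # Steps: two per stride; stance occupies duty_factor of the stride.
  step_period <- 1 / (2 * f_stride)
  u <- (t - lead) %% step_period
  contact <- config$duty_factor / f_stride
  vmean <- acc$vertical_mean[[condition]]
  amp_v <- 2 * step_period * vmean / contact
  vert <- ifelse(u < contact, amp_v * sin(pi * u / contact)^2, 0)
  off_v <- stats::rnorm(1, 0, acc$sensor_offset_sd)
  channels$neck_vertical <- channel_trace(
    vert + off_v + stats::rnorm(n, 0, acc$noise_sd), fs = fs, units = "m/s^2")

  if (condition %in% c("control", "head_mass")) {
    a_fa <- acc$fa_second_half_mean[[condition]] * pi / 2
    fa <- -a_fa * sin(2 * pi * u / step_period)
  } else {
    m_fa <- acc$fa_pull_mean[[condition]]
    # One-signed wave with mean m_fa: mean(1 - cos) over a period is 1, so
    # the per-step peaks (forward pull, m_fa < 0) or minima (rearward,
    # m_fa > 0) sit exactly at true zero, matching the baselining rule.
    fa <- m_fa * (1 - cos(2 * pi * u / step_period))
  }
  off_h <- stats::rnorm(1, 0, acc$sensor_offset_sd)
  channels$neck_fore_aft <- channel_trace(
    fa + off_h + stats::rnorm(n, 0, acc$noise_sd), fs = fs, units = "m/s^2")

  applied <- if (condition %in% c("forward_pull", "rearward_pull",
                                  "forward_pull_mass", "rearward_pull_mass"))
    config$pull_force else 0
  head_mass <- if (condition %in% c("head_mass", "forward_pull_mass",
                                    "rearward_pull_mass"))
    config$head_added_mass else 0

  tr <- trial(subject$id, condition, channels, subject$body_mass,
              head_added_mass = head_mass, applied_force = applied)
  truth <- list(
    strike_idx = strike_idx,
    multipliers = stats::setNames(
      vapply(muscles, condition_multiplier, numeric(1),
             config = config, condition = condition), muscles),
    env_means = env_means,
    vertical_offset = off_v, fore_aft_offset = off_h,
    vertical_mean = vmean)
  list(trial = tr, truth = truth)
}

# Noise-free jump force curve. Returns the samples plus analytic phase
# bookkeeping. `push_amp` is the push peak above effective weight.
jump_force_curve <- function(w_eff, push_amp, t_flight, jp, fs) {
  seg <- function(dur, f) f((seq_len(round(dur * fs)) - 0.5) / fs / dur)
  quiet <- rep(w_eff, round(jp$quiet_s * fs))
  unweight <- seg(jp$unweight_s, function(v)
    w_eff - jp$depth_frac * w_eff * sin(pi * v)^2)
  push <- seg(jp$push_s, function(v) w_eff + push_amp * sin(pi * v)^2)
  drop <- seg(jp$drop_s, function(v) w_eff * cos(pi * v / 2)^2)
  flight <- rep(0, round(t_flight * fs))
  landing <- seg(jp$landing_s, function(v) w_eff + 1.5 * w_eff * sin(pi * v)^2)
  tail <- rep(w_eff, round(jp$tail_s * fs))
  c(quiet, unweight, push, drop, flight, landing, tail)
}

# Impulse of (F - w_eff) over the analysis window [onset, takeoff] defined
# by the detection rules, computed on a noise-free curve.
analysis_window_impulse <- function(force, w_eff, fs) {
  tr <- channel_trace(force, fs = fs, units = "N")
  ph <- detect_jump_phases(tr, w_eff)
  trapz_uniform(force[(ph$onset + 1L):(ph$takeoff + 1L)] - w_eff, 1 / fs)
}

#' Generate one synthetic countermovement-jump trial
#'
#' Builds a force-time curve (quiet standing at the effective weight, a
#' smooth unweighting dip, a propulsion peak, a fast drop through takeoff,
#' flight, and a landing spike) whose net impulse over the analysis window
#' [detected onset, takeoff] equals the per-condition target exactly on the
#' noise-free curve: the window impulse is affine in the push amplitude, so
#' the amplitude is solved from two evaluations. Flight time is set to
#' 2 v_takeoff / g. EMG envelopes are locked to the jump phases (push and
#' landing bursts for extensors, flight activity for flexors) and scaled by
#' the condition multiplier.
#'
#' @param subject subject parameter list (or `NULL` to draw one).
#' @param condition `"jump_control"`, `"jump_gravity"`, `"jump_mass"` or
#'   `"jump_submax"`.
#' @param config a [synthetic_config].
#' @param effort effort fraction for `jump_submax` (ignored otherwise).
#' @return list with `trial` and `truth` (target impulse, takeoff velocity,
#'   analytic onset/takeoff/landing indices, effective weight, multipliers).
#' @export
generate_jump_trial <- function(subject = NULL, condition, config, effort = 1) {
  if (!condition %in% JUMP_CONDITIONS)
    stop("unknown jump condition: ", condition, call. = FALSE)
  if (is.null(subject)) subject <- draw_subject(config, "S01")
  jp <- config$jump
  fs <- config$fs
  head_mass <- if (condition == "jump_mass") config$head_added_mass else 0
  mass <- subject$body_mass + head_mass
  applied <- if (condition == "jump_gravity") jp$applied_gravity_force else 0
  w_eff <- mass * G_ACCEL + applied

  j_nominal <- if (condition == "jump_submax")
    effort * jp$target_net_impulse[["jump_control"]]
  else jp$target_net_impulse[[condition]]
  j_target <- j_nominal * subject$body_mass / jp$ref_mass
  if (jp$impulse_jitter_frac > 0)
    j_target <- j_target * exp(stats::rnorm(1, 0, jp$impulse_jitter_frac))

  degenerate <- jp$depth_frac == 0 && j_nominal == 0
  if (degenerate) {
    n <- round((jp$quiet_s + jp$tail_s) * fs)
    force <- rep(w_eff, n)
    truth_phases <- NULL
    v_to <- 0
  } else {
    v_to <- j_target / mass
    t_flight <- 2 * v_to / G_ACCEL
    j0 <- analysis_window_impulse(
      jump_force_curve(w_eff, 0, t_flight, jp, fs), w_eff, fs)
    j1 <- analysis_window_impulse(
      jump_force_curve(w_eff, 1, t_flight, jp, fs), w_eff, fs)
    push_amp <- (j_target - j0) / (j1 - j0)
    # reject pushes that would demand an implausible peak force (> 8x the
    # effective weight) or a negative amplitude
    if (!is.finite(push_amp) || push_amp <= 0 || push_amp > 8 * w_eff)
      stop("target impulse unreachable for the configured jump durations",
           call. = FALSE)
    force <- jump_force_curve(w_eff, push_amp, t_flight, jp, fs)
    ph <- detect_jump_phases(channel_trace(force, fs = fs, units = "N"), w_eff)
    truth_phases <- ph
  }
  n <- length(force)
  t <- (seq_len(n) - 1L) / fs
  noisy <- force + stats::rnorm(n, 0, jp$force_noise_sd)

  muscles <- names(config$envelopes)
  channels <- list(force_z = channel_trace(noisy, fs = fs, units = "N"))
  if (!degenerate) {
    t_on <- truth_phases$onset / fs
    t_to <- truth_phases$takeoff / fs
    t_ld <- truth_phases$landing / fs
    t_push_peak <- jp$quiet_s + jp$unweight_s + jp$push_s / 2
    t_flight_mid <- (t_to + t_ld) / 2
    bump <- function(center, width, amp) amp * exp(-0.5 * ((t - center) / width)^2)
    for (m in muscles) {
      mult <- condition_multiplier(config, m, condition) * subject$amp_scale[[m]]
      scale_eff <- if (condition == "jump_submax" || effort < 1)
        exp(jp$effort_b * (j_target - jp$target_net_impulse[["jump_control"]] *
                             subject$body_mass / jp$ref_mass))
      else 1
      env <- if (m %in% FLEXOR_MUSCLES) {
        jp$tonic + bump(t_flight_mid, (t_ld - t_to) / 4, jp$flight_amp) +
          bump(t_ld, 0.08, jp$landing_amp / 2)
      } else {
        jp$tonic + bump(t_push_peak, 0.15, jp$push_amp) +
          bump(t_ld, 0.08, jp$landing_amp)
      }
      env <- env * scale_eff * mult
      channels[[m]] <- generate_emg_channel(env, config, subject$mvc_volts[[m]])
    }
  } else {
    for (m in muscles)
      channels[[m]] <- generate_emg_channel(rep(jp$tonic, n), config,
                                            subject$mvc_volts[[m]])
  }

  tr <- trial(subject$id, condition, channels, subject$body_mass,
              head_added_mass = head_mass, applied_force = applied,
              effort = if (condition == "jump_submax") effort else NA_real_)
  truth <- list(
    net_impulse = if (degenerate) 0 else j_target,
    takeoff_velocity = v_to,
    effective_weight = w_eff, mass = mass,
    onset = if (degenerate) NA_integer_ else truth_phases$onset,
    takeoff = if (degenerate) NA_integer_ else truth_phases$takeoff,
    landing = if (degenerate) NA_integer_ else truth_phases$landing,
    multipliers = stats::setNames(
      vapply(muscles, condition_multiplier, numeric(1),
             config = config, condition = condition), muscles))
  list(trial = tr, truth = truth)
}

#' Generate MVC and rest reference trials for one subject
#'
#' Four maximum-voluntary-contraction trials per direction (flexion
#' activates the ventral strap muscles and masseter at the 100 %MVC
#' reference amplitude, extension the dorsal muscles) plus one rest trial
#' whose channels carry background noise only.
#'
#' @param subject subject parameter list (or `NULL` to draw one).
#' @param config a [synthetic_config].
#' @param n_mvc MVC trials per direction.
#' @param mvc_s,rest_s trial durations in seconds.
#' @return named list: `mvc_flexion` and `mvc_extension` (lists of trials)
#'   and `rest` (one trial).
#' @export
generate_mvc_and_rest <- function(subject = NULL, config, n_mvc = 4L,
                                  mvc_s = 3, rest_s = 10) {
  if (is.null(subject)) subject <- draw_subject(config, "S01")
  muscles <- names(config$envelopes)
  make <- function(condition, dur, level_fun) {
    n <- round(dur * config$fs)
    channels <- lapply(muscles, function(m)
      generate_emg_channel(rep(level_fun(m), n), config, subject$mvc_volts[[m]]))
    names(channels) <- muscles
    trial(subject$id, condition, channels, subject$body_mass)
  }
  flex <- lapply(seq_len(n_mvc), function(i)
    make("mvc_flexion", mvc_s,
         function(m) if (m %in% FLEXOR_MUSCLES) 100 else 10))
  ext <- lapply(seq_len(n_mvc), function(i)
    make("mvc_extension", mvc_s,
         function(m) if (m %in% FLEXOR_MUSCLES) 10 else 100))
  rest <- make("rest", rest_s, function(m) 0)
  list(mvc_flexion = flex, mvc_extension = ext, rest = rest)
}

#' Generate a full synthetic study
#'
#' Draws per-subject parameters (body mass, preferred stride frequency,
#' per-muscle MVC amplitude and envelope scale) and generates every
#' requested condition plus the MVC/rest references, deterministically
#' under the configured seed. Optionally writes the study as trial bundles
#' plus a YAML manifest and ground-truth JSON.
#'
#' @param config a [synthetic_config].
#' @param conditions conditions to generate (default: all running and
#'   maximal-jump conditions plus graded submaximal jumps).
#' @param mvc include MVC/rest reference trials.
#' @param out_dir if non-`NULL`, directory to write the study tree to.
#' @param drop_muscles optional named list (subject id -> muscle names)
#'   emulating discarded electrodes; masked muscles are excluded from the
#'   manifest availability mask.
#' @return object of class `synthetic_study`: list with `config`,
#'   `subjects` (each with `params`, `trials`, `truth`, `muscles`), and
#'   `manifest`.
#' @export
generate_study <- function(config = synthetic_config(),
                           conditions = c(RUN_CONDITIONS,
                                          "jump_control", "jump_gravity",
                                          "jump_mass", "jump_submax"),
                           mvc = TRUE, out_dir = NULL, drop_muscles = list()) {
  set.seed(config$seed)
  muscles <- names(config$envelopes)
  subjects <- vector("list", config$n_subjects)
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  for (i in seq_len(config$n_subjects)) {
    sub <- draw_subject(config, ids[i])
    trials <- list()
    truth <- list()
    for (cond in conditions) {
      if (cond %in% RUN_CONDITIONS) {
        g <- generate_running_trial(sub, cond, config)
        trials[[cond]] <- g$trial
        truth[[cond]] <- g$truth
      } else if (cond %in% c("jump_control", "jump_gravity", "jump_mass")) {
        gs <- lapply(seq_len(config$n_jumps), function(k)
          generate_jump_trial(sub, cond, config))
        trials[[cond]] <- lapply(gs, `[[`, "trial")
        truth[[cond]] <- lapply(gs, `[[`, "truth")
      } else if (cond == "jump_submax") {
        gs <- list()
        for (e in config$submax_efforts)
          for (k in seq_len(config$n_jumps))
            gs[[length(gs) + 1L]] <- generate_jump_trial(sub, "jump_submax",
                                                         config, effort = e)
        trials[[cond]] <- lapply(gs, `[[`, "trial")
        truth[[cond]] <- lapply(gs, `[[`, "truth")
      } else stop("unknown condition: ", cond, call. = FALSE)
    }
    if (mvc) {
      refs <- generate_mvc_and_rest(sub, config)
      trials <- c(trials, refs)
    }
    avail <- setdiff(muscles, drop_muscles[[ids[i]]] %||% character(0))
    subjects[[i]] <- list(params = sub, trials = trials, truth = truth,
                          muscles = avail)
  }
  names(subjects) <- ids
  manifest <- list(
    subjects = ids,
    muscles = stats::setNames(lapply(subjects, `[[`, "muscles"), ids))
  study <- structure(list(config = config, subjects = subjects,
                          manifest = manifest),
                     class = "synthetic_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  conds <- names(x$subjects[[1L]]$trials)
  cat(sprintf("<synthetic_study> %d subjects, conditions: %s\n",
              length(x$subjects), paste(conds, collapse = ", ")))
  invisible(x)
}

#' Write a generated study to disk
#'
#' One trial bundle per recording under `dir/<subject>/`, ground truth as
#' JSON under `dir/truth/`, and a YAML manifest at `dir/manifest.yaml`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  trials_index <- list()
  for (id in names(study$subjects)) {
    sdir <- file.path(dir, id)
    dir.create(sdir, showWarnings = FALSE)
    sub <- study$subjects[[id]]
    idx <- list()
    for (cond in names(sub$trials)) {
      trs <- sub$trials[[cond]]
      if (inherits(trs, "nc_trial")) trs <- list(trs)
      stems <- character(length(trs))
      for (k in seq_along(trs)) {
        rel <- file.path(id, sprintf("%s_%02d", cond, k))
        write_trial(trs[[k]], file.path(dir, rel))
        stems[k] <- rel  # manifest paths are relative to the study root
      }
      idx[[cond]] <- stems
    }
    trials_index[[id]] <- idx
    jsonlite::write_json(sub$truth, file.path(dir, "truth", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  manifest <- study$manifest
  manifest$trials <- trials_index
  write_manifest(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a study written by [write_study] back into memory
#'
#' @param dir study directory.
#' @return a list shaped like a `synthetic_study` (without ground truth).
#' @export
read_study <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.yaml"))
  subjects <- lapply(manifest$subjects, function(id) {
    idx <- manifest$trials[[id]]
    trials <- lapply(names(idx), function(cond) {
      stems <- file.path(dir, idx[[cond]])
      trs <- lapply(stems, read_trial)
      # running and rest conditions hold a single trial, not a list
      if (cond %in% c(RUN_CONDITIONS, "rest")) trs[[1L]] else trs
    })
    names(trials) <- names(idx)
    list(trials = trials, muscles = manifest$muscles[[id]])
  })
  names(subjects) <- manifest$subjects
  structure(list(config = NULL, subjects = subjects, manifest = manifest),
            class = "synthetic_study")
}
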