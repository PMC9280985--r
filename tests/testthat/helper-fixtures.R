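# Shared fixtures. Studies are generated once per test run and cached;
# sizes are kept small for unit tests (acceptance tests build their own
# studies at the full study design).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small running study: 4 subjects, 8 cycles, two conditions.
small_run_study <- function() {
  cached("small_run", {
    cfg <- synthetic_config(n_subjects = 4, seed = 101, n_cycles = 8)
    generate_study(cfg, conditions = c("control", "forward_pull"))
  })
}

# Small jump study: 3 subjects, 2 jumps per condition.
small_jump_study <- function() {
  cached("small_jump", {
    cfg <- synthetic_config(n_subjects = 3, seed = 202, n_jumps = 2)
    generate_study(cfg, conditions = c("jump_control", "jump_gravity",
                                       "jump_mass"))
  })
}

# A noiseless config for exactness checks.
noiseless_config <- function(..., jump = list(), accel = list()) {
  synthetic_config(
    background_noise_pct = 0,
    accel = utils::modifyList(list(noise_sd = 0, sensor_offset_sd = 0,
                                   foot_noise_sd = 0), accel),
    jump = utils::modifyList(list(force_noise_sd = 0,
                                  impulse_jitter_frac = 0), jump),
    ...)
}

# Single-muscle config: cheap trials when only events/kinematics matter.
one_muscle_config <- function(...) {
  synthetic_config(envelopes = default_envelopes()["sternohyoid"], ...)
}

# Brute-force one-tailed signed-rank p-value by enumerating all 2^n sign
# assignments (the independent oracle for the exact Wilcoxon path).
enum_signed_rank_p <- function(control, manipulation,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  d <- manipulation - control
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  if (direction == "greater") mean(w_all >= w_obs) else mean(w_all <= w_obs)
}

# A constructed subject with fixed parameters (no population jitter).
fixed_subject <- function(body_mass = 73.7, config) {
  muscles <- names(config$envelopes)
  list(id = "SX", body_mass = body_mass,
       stride_frequency = config$stride_frequency,
       mvc_volts = stats::setNames(rep(config$mvc_volts, length(muscles)),
                                   muscles),
       amp_scale = stats::setNames(rep(1, length(muscles)), muscles))
}
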