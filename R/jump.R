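# Force-plate countermovement-jump kinetics via the impulse-momentum
# method: the center-of-mass acceleration is (F - effective weight) / mass,
# velocity is its running trapezoidal integral from movement onset, the net
# impulse is the integral of (F - effective weight) over the push-off, and
# takeoff velocity and jump height follow from it. g = 9.81 m/s^2
# throughout. In added-gravity trials the elastic-band force is part of the
# standing baseline, so "effective weight" absorbs it and the kinematics
# are unchanged by construction.

#' Quiet-standing body-weight baseline
#'
#' Finds the quietest window (minimum rolling standard deviation) of
#' duration `quiet_window_s` and returns the mean force there. In
#' added-gravity trials the baseline includes the applied downward force,
#' giving the effective weight.
#'
#' @param force_trace vertical force [channel_trace] in newtons.
#' @param quiet_window_s window duration in seconds (default 1).
#' @param max_sd largest admissible rolling SD (N) for a window to count as
#'   quiet standing.
#' @return effective weight in newtons.
#' @export
body_weight_baseline <- function(force_trace, quiet_window_s = 1, max_sd = 50) {
  x <- force_trace$samples
  w <- round(quiet_window_s * force_trace$fs)
  n <- length(x)
  if (n < w) stop("trace shorter than the quiet window", call. = FALSE)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  starts <- seq_len(n - w + 1L)
  s1 <- cs[starts + w] - cs[starts]
  s2 <- cs2[starts + w] - cs2[starts]
  v <- pmax((s2 - s1^2 / w) / (w - 1L), 0)
  i <- which.min(v)
  if (sqrt(v[i]) > max_sd)
    stop("no quiet standing segment found", call. = FALSE)
  s1[i] / w
}

#' Detect countermovement-jump phases
#'
#' \describe{
#'   \item{onset}{first sample of a sustained (>= `sustain_ms`) drop of the
#'     force below `onset_frac` of the effective weight - the start of the
#'     unweighting countermovement. With `literal_10pct = TRUE` the onset is
#'     instead the first crossing below 10% of the effective weight, i.e.
#'     essentially takeoff; the sustained-unweighting definition is the
#'     default because unweighting starts near body weight.}
#'   \item{takeoff}{first sample after onset with force below
#'     `takeoff_threshold_n` (10 N absolute, robust to plate noise).}
#'   \item{landing}{first sample after takeoff with force back above 10% of
#'     the effective weight.}
#' }
#'
#' @param force_trace vertical force [channel_trace].
#' @param body_weight effective weight in newtons (see
#'   [body_weight_baseline]).
#' @param onset_frac onset threshold as a fraction of effective weight.
#' @param sustain_ms debounce: the force must stay below the onset
#'   threshold this long.
#' @param takeoff_threshold_n absolute takeoff threshold in newtons.
#' @param literal_10pct use the literal force < 10% of body weight onset.
#' @return a jump-phase [event_set] (0-based indices).
#' @export
detect_jump_phases <- function(force_trace, body_weight, onset_frac = 0.9,
                               sustain_ms = 50, takeoff_threshold_n = 10,
                               literal_10pct = FALSE) {
  x <- force_trace$samples
  fs <- force_trace$fs
  n <- length(x)
  onset_thr <- if (literal_10pct) 0.1 * body_weight else onset_frac * body_weight
  below <- x < onset_thr
  need <- max(1L, round(sustain_ms * fs / 1000))
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  ok <- which(run$values & run$lengths >= need)
  if (length(ok) == 0L)
    stop("no countermovement onset detected", call. = FALSE)
  onset <- starts[ok[1L]]
  takeoff <- which(x < takeoff_threshold_n & seq_len(n) > onset)[1L]
  if (is.na(takeoff))
    stop("no takeoff detected: force never approaches zero", call. = FALSE)
  landing <- which(x >= 0.1 * body_weight & seq_len(n) > takeoff)[1L]
  if (is.na(landing))
    stop("no landing detected after takeoff", call. = FALSE)
  event_set("jump_phases", onset = onset - 1L, takeoff = takeoff - 1L,
            landing = landing - 1L, n_samples = n)
}

#' Center-of-mass kinetics of a countermovement jump
#'
#' Impulse-momentum analysis at the native sampling rate (trapezoidal
#' integration, no resampling): a(t) = (F(t) - W_eff) / m, v(t) the
#' cumulative integral of a from onset, net impulse the integral of
#' (F - W_eff) over [onset, takeoff], takeoff velocity v(takeoff), and
#' jump height v^2 / 2g. The flight-time height g t_f^2 / 8 is reported as
#' a cross-check.
#'
#' @param force_trace vertical force [channel_trace].
#' @param mass subject (plus harness) mass in kg.
#' @param effective_weight quiet-standing baseline in newtons.
#' @param phases jump-phase [event_set].
#' @return object of class `jump_kinetics`.
#' @export
com_kinematics <- function(force_trace, mass, effective_weight, phases) {
  if (mass <= 0) stop("mass must be > 0", call. = FALSE)
  if (phases$kind != "jump_phases")
    stop("phases must be a jump-phase event set", call. = FALSE)
  fs <- force_trace$fs
  x <- force_trace$samples
  i_on <- phases$onset + 1L
  i_to <- phases$takeoff + 1L
  i_ld <- phases$landing + 1L
  net <- x - effective_weight
  accel <- net / mass
  a_win <- accel[i_on:i_ld]
  v_win <- pracma::cumtrapz(a_win) / fs
  net_impulse <- trapz_uniform(net[i_on:i_to], 1 / fs)
  takeoff_velocity <- v_win[i_to - i_on + 1L]
  if (is.finite(takeoff_velocity) && takeoff_velocity < 0)
    warning("negative takeoff velocity: phases likely mis-detected")
  jump_height <- takeoff_velocity^2 / (2 * G_ACCEL)
  t_flight <- (phases$landing - phases$takeoff) / fs
  structure(
    list(body_weight = effective_weight, mass = mass,
         onset = phases$onset, takeoff = phases$takeoff,
         landing = phases$landing, fs = fs,
         net_impulse = net_impulse,
         com_acceleration = a_win, com_velocity = as.numeric(v_win),
         takeoff_velocity = takeoff_velocity,
         jump_height = jump_height,
         flight_time = t_flight,
         jump_height_flight = G_ACCEL * t_flight^2 / 8),
    class = "jump_kinetics")
}

#' @export
print.jump_kinetics <- function(x, ...) {
  cat(sprintf(
    "<jump_kinetics> W_eff %.1f N, m %.1f kg | J %.1f N*s, v_to %.3f m/s, h %.3f m (flight-time h %.3f m)\n",
    x$body_weight, x$mass, x$net_impulse, x$takeoff_velocity,
    x$jump_height, x$jump_height_flight))
  invisible(x)
}

#' Percent change in group-mean net impulse
#'
#' `100 * (mean_control - mean_manipulation) / mean_control`, rounded to
#' one decimal. Positive values are reductions. The signed change and its
#' magnitude are both returned so a decrease and an increase of the same
#' size are distinguishable.
#'
#' @param control_impulses,manip_impulses net impulses (N*s) by group.
#' @return list with `percent_change` (signed, one decimal) and
#'   `percent_magnitude`.
#' @export
impulse_change <- function(control_impulses, manip_impulses) {
  mc <- mean(control_impulses)
  mm <- mean(manip_impulses)
  if (!is.finite(mc) || mc <= 0)
    stop("control mean impulse must be > 0", call. = FALSE)
  pc <- round(100 * (mc - mm) / mc, 1)
  list(percent_change = pc, percent_magnitude = abs(pc))
}

#' Net impulses of graded-effort jumps
#'
#' Tabulates per-trial net impulses keyed by nominal effort for the
#' downstream EMG-versus-impulse regression.
#'
#' @param efforts numeric vector of nominal effort fractions (e.g. 0.10,
#'   0.25, ..., 1 for maximal).
#' @param impulses matching net impulses in N*s.
#' @return data frame with columns `effort` and `net_impulse`.
#' @export
effort_series <- function(efforts, impulses) {
  if (length(efforts) != length(impulses))
    stop("efforts and impulses must match in length", call. = FALSE)
  if (length(unique(efforts)) < 2L)
    stop("at least 2 effort levels are required", call. = FALSE)
  data.frame(effort = efforts, net_impulse = impulses)
}
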