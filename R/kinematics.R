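# Accelerometer processing for running trials: 10-ms smoothing, two-point
# gravity calibration, foot-strike detection, flight-phase vertical
# baselining, mode-dependent fore-aft offsets, per-step peak/mean
# statistics, and the cosine tilt correction.
#
# Accelerometer traces represent proper acceleration: an axis reads ~g when
# static and vertical, and ~0 in flight. All traces are smoothed before
# baselining and peak extraction (single-sample noise minima would
# otherwise define the flight baseline).

G_ACCEL <- 9.81  # m/s^2

#' Rolling-mean smoothing of a channel
#'
#' Centered moving average over `window_ms` (default 10 ms; 21 samples at
#' 2000 Hz once centered). Window edges shrink at the trace boundaries.
#'
#' @param trace a [channel_trace] or numeric vector (then `fs` is required).
#' @param window_ms window length in milliseconds.
#' @param fs sampling rate, only for plain numeric input.
#' @return smoothed input of the same type.
#' @export
rolling_mean <- function(trace, window_ms = 10, fs = NULL) {
  if (inherits(trace, "channel_trace")) {
    w <- round(window_ms * trace$fs / 1000)
    trace$samples <- rolling_mean_samples(trace$samples, w)
    trace
  } else {
    if (is.null(fs)) stop("fs required for numeric input", call. = FALSE)
    rolling_mean_samples(trace, round(window_ms * fs / 1000))
  }
}

#' Two-point gravity calibration of an accelerometer axis
#'
#' From two static recordings with the axis vertical in opposite
#' orientations (+g and -g): gain = 2g / (mean_up - mean_down) in
#' m s^-2 / V and offset = the midpoint voltage.
#'
#' @param static_up,static_down numeric vectors or [channel_trace]s of the
#'   static recordings.
#' @return list with `gain` (m s^-2 per volt) and `offset` (volts).
#' @export
calibrate_gravity <- function(static_up, static_down) {
  up <- if (inherits(static_up, "channel_trace")) static_up$samples else static_up
  dn <- if (inherits(static_down, "channel_trace")) static_down$samples else static_down
  mu <- mean(up); md <- mean(dn)
  if (mu <= md)
    stop("static recordings look swapped: mean(up) must exceed mean(down)",
         call. = FALSE)
  list(gain = 2 * G_ACCEL / (mu - md), offset = (mu + md) / 2)
}

#' Detect foot strikes from the foot accelerometer
#'
#' Foot strikes produce one sharp transient per stride. Candidate peaks are
#' local maxima exceeding median + k * MAD of the trace (MAD-based so the
#' threshold is amplitude-scale-robust); peaks closer than half the
#' expected stride period to an already accepted, larger peak are dropped
#' (refractory period `0.5 / stride_freq_hint`).
#'
#' @param foot_trace [channel_trace] of the foot accelerometer.
#' @param stride_freq_hint expected stride frequency in Hz.
#' @param k MAD multiplier for the detection threshold.
#' @return a foot-strike [event_set] (0-based indices).
#' @export
detect_foot_strikes <- function(foot_trace, stride_freq_hint = 1.4, k = 6) {
  x <- foot_trace$samples
  fs <- foot_trace$fs
  thr <- stats::median(x) + k * stats::mad(x)
  n <- length(x)
  if (n < 3L) stop("trace too short for strike detection", call. = FALSE)
  is_peak <- c(FALSE, x[2:(n - 1L)] > x[1:(n - 2L)] &
                 x[2:(n - 1L)] >= x[3:n], FALSE) & (x > thr)
  cand <- which(is_peak)
  if (length(cand) == 0L)
    stop("no foot-strike transients detected", call. = FALSE)
  refractory <- round(0.5 * fs / stride_freq_hint)
  keep <- logical(length(cand))
  ord <- order(x[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - taken) >= refractory)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  event_set("foot_strikes", times = sort(cand[keep]) - 1L, n_samples = n)
}

#' Flight-phase baseline of the vertical neck accelerometer
#'
#' During the flight phase of each stride the vertical proper acceleration
#' is zero, so the per-stride minima of the smoothed trace estimate the
#' sensor's zero-offset. The offset is the mean of those per-stride minima.
#'
#' @param vert_trace smoothed vertical [channel_trace].
#' @param events foot-strike [event_set] with at least 2 strikes.
#' @return offset in the trace units (subtract before peak/mean extraction).
#' @export
vertical_baseline_flight <- function(vert_trace, events) {
  windows <- segment_cycles(events, max_cycles = .Machine$integer.max)
  if (length(windows) < 1L)
    stop("need at least 2 strikes for flight baselining", call. = FALSE)
  mins <- vapply(windows, function(w)
    min(vert_trace$samples[(w[1L] + 1L):w[2L]]), numeric(1))
  mean(mins)
}

#' Fore-aft accelerometer offset
#'
#' Mode-dependent zero-offset for the horizontal (fore-aft) axis:
#' \describe{
#'   \item{`cycle_mean`}{mean over an integral number of locomotor cycles
#'     (control and added-head-mass trials, where braking and propulsion
#'     cancel over a cycle).}
#'   \item{`step_peaks`}{mean of the per-step maxima (forward-pull trials,
#'     where the runner never accelerates forward, so the per-step peaks
#'     mark zero).}
#'   \item{`step_minima`}{mean of the per-step minima (rearward-pull
#'     trials, the mirror case).}
#' }
#'
#' @param fa_trace smoothed fore-aft [channel_trace].
#' @param events step (or stride) [event_set] delimiting the windows.
#' @param mode offset definition, see above.
#' @return offset in trace units.
#' @export
horizontal_offset <- function(fa_trace,
                              events,
                              mode = c("cycle_mean", "step_peaks", "step_minima")) {
  mode <- match.arg(mode)
  ts <- events$times
  if (length(ts) < 2L)
    stop("need at least one complete cycle", call. = FALSE)
  if (mode == "cycle_mean") {
    return(mean(fa_trace$samples[(ts[1L] + 1L):ts[length(ts)]]))
  }
  windows <- segment_cycles(events, max_cycles = .Machine$integer.max)
  ext <- vapply(windows, function(w) {
    y <- fa_trace$samples[(w[1L] + 1L):w[2L]]
    if (mode == "step_peaks") max(y) else min(y)
  }, numeric(1))
  mean(ext)
}

#' Split stride events into step events
#'
#' A stride (right-foot strike to right-foot strike) contains two steps;
#' the contralateral footfall is approximated by the temporal midpoint of
#' each stride window.
#'
#' @param events foot-strike [event_set] (right foot, one per stride).
#' @return a foot-strike [event_set] with the midpoints inserted.
#' @export
stride_to_steps <- function(events) {
  ts <- events$times
  if (length(ts) < 2L) return(events)
  mids <- floor((ts[-length(ts)] + ts[-1L]) / 2)
  event_set("foot_strikes", times = sort(c(ts, mids)))
}

#' Per-step acceleration statistics
#'
#' For each step window (successive events): peak positive and negative
#' values and the mean over the whole step plus the first and second half
#' (split at the temporal midpoint), for the baselined vertical and
#' fore-aft traces.
#'
#' @param vert_trace,fa_trace baselined, smoothed [channel_trace]s.
#' @param events step [event_set] (see [stride_to_steps]).
#' @return data frame with one row per step.
#' @export
step_stats <- function(vert_trace, fa_trace, events) {
  windows <- segment_cycles(events, max_cycles = .Machine$integer.max)
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    mid <- w[1L] + (w[2L] - w[1L]) %/% 2L
    v <- vert_trace$samples[(w[1L] + 1L):w[2L]]
    h <- fa_trace$samples[(w[1L] + 1L):w[2L]]
    h1 <- fa_trace$samples[(w[1L] + 1L):mid]
    h2 <- fa_trace$samples[(mid + 1L):w[2L]]
    v1 <- vert_trace$samples[(w[1L] + 1L):mid]
    v2 <- vert_trace$samples[(mid + 1L):w[2L]]
    data.frame(
      step_index = i,
      peak_positive_vertical = max(v), peak_negative_vertical = min(v),
      mean_vertical = mean(v),
      mean_vertical_first_half = mean(v1), mean_vertical_second_half = mean(v2),
      peak_positive_fore_aft = max(h), peak_negative_fore_aft = min(h),
      mean_fore_aft = mean(h),
      mean_fore_aft_first_half = mean(h1), mean_fore_aft_second_half = mean(h2)
    )
  })
  do.call(rbind, rows)
}

#' Cosine tilt correction for a leaned accelerometer
#'
#' A sensor tilted by `angle_deg` from the measured axis underestimates the
#' true acceleration by the cosine of the lean (e.g. cos 28 deg = 0.883, at
#' most a 12% underestimate for the largest lean observed). The corrected
#' value is measured / factor. Not applied by default in the pipeline; the
#' underestimate is reported instead.
#'
#' @param angle_deg lean angle in degrees, |angle| < 90.
#' @return list with `lean_angle` (degrees) and `factor` (cosine).
#' @export
tilt_correction <- function(angle_deg) {
  if (!is.numeric(angle_deg) || abs(angle_deg) >= 90)
    stop("lean angle must satisfy |angle| < 90 degrees", call. = FALSE)
  list(lean_angle = angle_deg, factor = cos(angle_deg * pi / 180))
}
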