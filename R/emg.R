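# EMG processing: rectification, background correction, MVC normalization,
# cycle segmentation, per-cycle integration, time-normalized binning, and
# ensemble averaging.
#
# The processing chain mirrors standard surface-EMG practice: the raw EMG is
# rectified; the resting background level (mean of the 500 smallest
# rectified samples of a supported-head rest recording) is subtracted and
# the result clipped at zero; amplitudes are expressed in %MVC against a
# per-subject reference taken as the mean over MVC trials of the maximum of
# a 250-ms moving average of the rectified trace.

#' Full-wave rectification
#'
#' @param trace a [channel_trace] (EMG, volts) or numeric vector.
#' @return same type as the input with samples replaced by their absolute
#'   values. Idempotent.
#' @export
rectify <- function(trace) {
  if (inherits(trace, "channel_trace")) {
    trace$samples <- abs(trace$samples)
    trace
  } else {
    abs(trace)
  }
}

#' Resting background level of a rectified EMG channel
#'
#' The background is the mean of the `n_lowest` smallest rectified samples
#' of a rest recording (subject lying prone or supine, head supported).
#'
#' @param rest rectified rest recording ([channel_trace] or numeric).
#' @param n_lowest number of lowest samples averaged (default 500).
#' @return background level in volts.
#' @export
estimate_background <- function(rest, n_lowest = 500L) {
  x <- if (inherits(rest, "channel_trace")) rest$samples else rest
  if (length(x) < n_lowest)
    stop(sprintf("rest recording shorter than %d samples", n_lowest),
         call. = FALSE)
  mean(sort(x, partial = n_lowest)[seq_len(n_lowest)])
}

#' Subtract the resting background from a rectified trace
#'
#' Pointwise `max(sample - background, 0)`: negative activation is
#' physically meaningless, so the difference is clipped at zero.
#'
#' @param trace rectified EMG ([channel_trace] or numeric).
#' @param background background level in volts (>= 0).
#' @return same type as the input.
#' @export
subtract_background <- function(trace, background) {
  if (!is.numeric(background) || length(background) != 1L || background < 0)
    stop("background must be a single non-negative number", call. = FALSE)
  if (inherits(trace, "channel_trace")) {
    trace$samples <- pmax(trace$samples - background, 0)
    trace
  } else {
    pmax(trace - background, 0)
  }
}

#' MVC normalization reference
#'
#' For each maximum-voluntary-contraction trial the rectified,
#' background-subtracted trace is smoothed with a centered moving average
#' (default 250 ms) and its maximum taken; the reference is the mean of the
#' per-trial maxima. Smoothing avoids a single-sample noise spike defining
#' the 100 %MVC level.
#'
#' @param mvc_traces list of rectified, background-subtracted
#'   [channel_trace] objects (typically 4 trials; at least 1).
#' @param window_ms smoothing window in milliseconds.
#' @return reference amplitude in volts.
#' @export
mvc_reference <- function(mvc_traces, window_ms = 250) {
  if (inherits(mvc_traces, "channel_trace")) mvc_traces <- list(mvc_traces)
  if (length(mvc_traces) == 0L)
    stop("at least one MVC trial is required", call. = FALSE)
  maxima <- vapply(mvc_traces, function(tr) {
    w <- max(1L, round(window_ms * tr$fs / 1000))
    max(rolling_mean_samples(tr$samples, w))
  }, numeric(1))
  mean(maxima)
}

#' Normalize an EMG trace to %MVC
#'
#' `100 * max(rectified - background, 0) / reference`.
#'
#' @param trace rectified EMG [channel_trace].
#' @param background resting background level, volts.
#' @param reference MVC reference amplitude, volts (> 0).
#' @return object of class `normalized_activation`: a [channel_trace] in
#'   %MVC carrying `background` and `mvc_reference` attributes.
#' @export
normalize_emg <- function(trace, background, reference) {
  if (!is.numeric(reference) || length(reference) != 1L || reference <= 0)
    stop("MVC reference must be > 0", call. = FALSE)
  corrected <- subtract_background(trace, background)
  corrected$samples <- 100 * corrected$samples / reference
  corrected$units <- "V"  # stored as %MVC; units tag retained for plumbing
  structure(c(unclass(corrected),
              list(background = background, mvc_reference = reference)),
            class = c("normalized_activation", "channel_trace"))
}

#' Segment a running trial into locomotor cycles
#'
#' Cycles are the half-open windows between successive right-foot strikes,
#' `[strike_i, strike_{i+1})`, capped at `max_cycles` (20, the number of
#' cycles recorded per trial).
#'
#' @param events a foot-strike [event_set].
#' @param max_cycles cap on the number of cycles returned.
#' @return list of integer windows `c(start, end)` (0-based, half-open).
#' @export
segment_cycles <- function(events, max_cycles = 20L) {
  if (events$kind != "foot_strikes")
    stop("segment_cycles needs foot-strike events", call. = FALSE)
  ts <- events$times
  if (length(ts) < 2L)
    stop("at least 2 foot strikes are required to form a cycle", call. = FALSE)
  n <- min(length(ts) - 1L, max_cycles)
  lapply(seq_len(n), function(i) c(ts[i], ts[i + 1L]))
}

#' Integrated activation over a cycle window
#'
#' Trapezoidal integral of the %MVC series over the window duration, in
#' %MVC * s.
#'
#' @param activation a `normalized_activation` (or any [channel_trace]).
#' @param window integer `c(start, end)` window (0-based, half-open).
#' @return integral in %MVC * s.
#' @export
integrate_cycle <- function(activation, window) {
  n <- length(activation$samples)
  start <- window[1L]; end <- window[2L]
  if (end <= start) stop("empty cycle window", call. = FALSE)
  if (start < 0L || end > n) stop("cycle window outside series", call. = FALSE)
  y <- activation$samples[(start + 1L):end]
  trapz_uniform(y, 1 / activation$fs)
}

#' Time-normalize a window into bins
#'
#' Splits the window into `n_bins` contiguous spans of near-equal length
#' (any remainder samples go to the earliest bins) and averages the samples
#' within each span. 100 bins are used for running strides and 200 for
#' countermovement jumps.
#'
#' @param activation a [channel_trace] (typically `normalized_activation`).
#' @param window integer `c(start, end)` window (0-based, half-open).
#' @param n_bins number of bins.
#' @return numeric vector of length `n_bins`.
#' @export
bin_profile <- function(activation, window, n_bins = 100L) {
  start <- window[1L]; end <- window[2L]
  len <- end - start
  if (len < n_bins)
    stop("window shorter than the number of bins", call. = FALSE)
  y <- activation$samples[(start + 1L):end]
  base <- len %/% n_bins
  rem <- len %% n_bins
  sizes <- rep.int(base, n_bins) + c(rep.int(1L, rem), rep.int(0L, n_bins - rem))
  grp <- rep.int(seq_len(n_bins), sizes)
  as.numeric(tapply(y, grp, mean))
}

#' Ensemble average of binned profiles
#'
#' Per-bin mean and 95% confidence interval across units (cycles within a
#' subject, or subjects within the group), with the CI computed as
#' mean +/- t(0.975, n-1) * SE. The cycle-to-group hierarchy is: average a
#' subject's cycles first, then compute mean and CI across subjects.
#'
#' @param profiles list (or matrix, units in rows) of equal-length binned
#'   profiles.
#' @return object of class `ensemble_profile` with `bin_means`, `ci_low`,
#'   `ci_high`, `n_units`, and `ci_defined` (FALSE when fewer than 2 units).
#' @export
ensemble_average <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else do.call(rbind, profiles)
  n <- nrow(m)
  means <- colMeans(m)
  if (n >= 2L) {
    se <- apply(m, 2L, stats::sd) / sqrt(n)
    half <- stats::qt(0.975, df = n - 1L) * se
    ci_low <- means - half
    ci_high <- means + half
    ci_defined <- TRUE
  } else {
    ci_low <- ci_high <- rep(NA_real_, ncol(m))
    ci_defined <- FALSE
  }
  structure(list(n_bins = ncol(m), bin_means = means, ci_low = ci_low,
                 ci_high = ci_high, n_units = n, ci_defined = ci_defined),
            class = "ensemble_profile")
}

#' @export
print.ensemble_profile <- function(x, ...) {
  cat(sprintf("<ensemble_profile> %d bins, %d units; mean range [%.3g, %.3g] %%MVC\n",
              x$n_bins, x$n_units, min(x$bin_means), max(x$bin_means)))
  invisible(x)
}

#' Per-subject manipulation/control activation ratio
#'
#' Ratio of the mean per-cycle integrated activation during a manipulation
#' to that during the control condition, for one subject and muscle.
#' Subjects whose control mean is not positive have no defined ratio and
#' return `NA`.
#'
#' @param manip_integrals,control_integrals numeric vectors of per-cycle
#'   integrals (%MVC * s) from identically processed trials.
#' @return the ratio (scalar), or `NA` if the control mean is <= 0.
#' @export
activation_ratio <- function(manip_integrals, control_integrals) {
  mc <- mean(control_integrals)
  if (!is.finite(mc) || mc <= 0) return(NA_real_)
  mean(manip_integrals) / mc
}
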