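# Internal numeric helpers shared across modules.

#' Centered rolling mean with edge shrinkage
#'
#' Smooths a numeric vector with a centered moving average. The window is
#' forced to an odd number of samples so the average is symmetric about each
#' point; at the edges the window shrinks to whatever samples exist.
#'
#' @param x numeric vector.
#' @param width window width in samples (coerced to the nearest odd integer
#'   `2 * floor(width / 2) + 1`).
#' @return numeric vector of the same length as `x`.
#' @keywords internal
rolling_mean_samples <- function(x, width) {
  n <- length(x)
  if (n == 0L) stop("rolling_mean: empty input", call. = FALSE)
  half <- floor(width / 2)
  if (half == 0L) return(x)
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  lo <- pmax(idx - half, 1L)
  hi <- pmin(idx + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Trapezoidal integral with uniform spacing dt.
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
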