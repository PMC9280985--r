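# Paired nonparametric condition comparison and the EMG-effort fit.
#
# Each force manipulation is compared to its baseline with a paired,
# one-tailed Wilcoxon signed-rank test; the family of eight muscles is
# corrected with the Holm-Bonferroni step-down procedure at alpha = 0.05.

#' Paired one-tailed Wilcoxon signed-rank test
#'
#' Differences are manipulation - control; zero differences are dropped
#' (Wilcoxon's original treatment), absolute differences mid-ranked, and
#' W+ is the sum of ranks of the positive differences. For up to
#' `exact_max` effective pairs without ties the exact null distribution of
#' W+ is used; otherwise a normal approximation with tie correction and
#' continuity correction. The tail is one-sided in the stated direction
#' (`"greater"` means manipulation > control).
#'
#' @param control,manipulation paired numeric vectors.
#' @param direction alternative hypothesis: manipulation `"greater"` or
#'   `"less"` than control.
#' @param exact_max largest n for which the exact distribution is used.
#' @return object of class `wilcoxon_sr` with `n_effective`, `W_plus`,
#'   `p_one_tailed`, `direction`, `method`.
#' @export
wilcoxon_signed_rank <- function(control, manipulation,
                                 direction = c("greater", "less"),
                                 exact_max = 25L) {
  direction <- match.arg(direction)
  if (length(control) != length(manipulation) || length(control) < 1L)
    stop("need at least one pair of equal-length observations", call. = FALSE)
  d <- manipulation - control
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(n_effective = 0L, W_plus = 0, p_one_tailed = 1,
                          direction = direction, method = "degenerate",
                          all_zero = TRUE), class = "wilcoxon_sr"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0L
  if (!has_ties && n <= exact_max) {
    # Exact null distribution of the signed-rank sum.
    p <- if (direction == "greater") {
      stats::psignrank(w_plus - 1, n, lower.tail = FALSE)
    } else {
      stats::psignrank(w_plus, n)
    }
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    z <- if (direction == "greater") (w_plus - mu - 0.5) / sigma
         else (w_plus - mu + 0.5) / sigma
    p <- if (direction == "greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
    method <- "normal_approx"
  }
  structure(list(n_effective = n, W_plus = w_plus,
                 p_one_tailed = min(max(p, .Machine$double.xmin), 1),
                 direction = direction, method = method, all_zero = FALSE),
            class = "wilcoxon_sr")
}

#' @export
print.wilcoxon_sr <- function(x, ...) {
  cat(sprintf("<wilcoxon_sr> n = %d, W+ = %g, one-tailed (%s) p = %.4g [%s]\n",
              x$n_effective, x$W_plus, x$direction, x$p_one_tailed, x$method))
  invisible(x)
}

#' Holm-Bonferroni sequential correction
#'
#' Step-down familywise-error control: with the m raw p-values sorted
#' ascending, adjusted_(i) = max_{j <= i} min(1, (m - j + 1) p_(j)),
#' mapped back to the input order. Rejection flags use adjusted p < alpha.
#' The adjustment itself is computed with [stats::p.adjust].
#'
#' @param raw_p numeric vector of p-values in (0, 1].
#' @param alpha familywise error rate (default 0.05).
#' @return object of class `corrected_family` with `raw_p`, `adjusted_p`,
#'   `reject`, `m`, `alpha`.
#' @export
holm_bonferroni <- function(raw_p, alpha = 0.05) {
  if (any(!is.finite(raw_p)) || any(raw_p <= 0) || any(raw_p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  adj <- stats::p.adjust(raw_p, method = "holm")
  structure(list(raw_p = raw_p, adjusted_p = adj, reject = adj < alpha,
                 m = length(raw_p), alpha = alpha),
            class = "corrected_family")
}

#' @export
print.corrected_family <- function(x, ...) {
  cat(sprintf("<corrected_family> m = %d, alpha = %g, %d rejected\n",
              x$m, x$alpha, sum(x$reject)))
  invisible(x)
}

#' Per-muscle condition comparison table
#'
#' Summarizes per-subject paired activation measures for one force
#' manipulation: per muscle the number of subjects, mean and SD of the
#' manipulation/baseline ratios, and the Holm-adjusted one-tailed Wilcoxon
#' p-value of the paired measures. Muscles with fewer than 2 subjects are
#' flagged and excluded from testing; subjects with a non-positive
#' baseline are dropped from that muscle's row.
#'
#' @param baseline,manipulation named lists (by muscle) of per-subject
#'   measure vectors, identically ordered within a muscle.
#' @param direction one-tailed direction per muscle (recycled if scalar):
#'   `"greater"` tests manipulation > baseline.
#' @param alpha familywise alpha for Holm rejection flags.
#' @return data frame of class `condition_comparison` with one row per
#'   muscle: `muscle`, `n`, `ratio_mean`, `ratio_sd`, `p_raw`,
#'   `p_adjusted`, `reject`, `tested`.
#' @export
ratio_table <- function(baseline, manipulation, direction = "greater",
                        alpha = 0.05) {
  muscles <- names(baseline)
  direction <- rep_len(direction, length(muscles))
  rows <- lapply(seq_along(muscles), function(i) {
    m <- muscles[[i]]
    b <- baseline[[m]]
    x <- manipulation[[m]]
    ok <- is.finite(b) & is.finite(x) & b > 0
    b <- b[ok]; x <- x[ok]
    ratios <- x / b
    n <- length(ratios)
    tested <- n >= 2L
    p <- if (tested)
      wilcoxon_signed_rank(b, x, direction = direction[[i]])$p_one_tailed
    else NA_real_
    data.frame(muscle = m, n = n,
               ratio_mean = if (n) mean(ratios) else NA_real_,
               ratio_sd = if (n > 1L) stats::sd(ratios) else NA_real_,
               p_raw = p, tested = tested)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  out$reject <- NA
  if (any(out$tested)) {
    fam <- holm_bonferroni(out$p_raw[out$tested], alpha = alpha)
    out$p_adjusted[out$tested] <- fam$adjusted_p
    out$reject[out$tested] <- fam$reject
  }
  class(out) <- c("condition_comparison", "data.frame")
  out
}

#' Exponential fit of integrated EMG against jump impulse
#'
#' Nonlinear least squares for y = a exp(b x) on the untransformed scale
#' (matching a least-squares fit to y itself, which weights errors
#' differently from log-space regression), initialized from a log-linear
#' regression on the y > 0 points. Falls back to
#' [minpack.lm::nlsLM] and finally to the log-linear parameters (flagged)
#' if the optimizer does not converge.
#'
#' @param x jump net impulses (N*s).
#' @param y integrated EMG values.
#' @return object of class `exp_fit` with `a`, `b`, `rss`, `n`,
#'   `converged`.
#' @export
fit_exponential <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 (x, y) points", call. = FALSE)
  stopifnot_finite(x, "x")
  pos <- y > 0
  if (sum(pos) < 2L)
    stop("need at least 2 positive y values to initialize", call. = FALSE)
  init <- stats::coef(stats::lm(log(y[pos]) ~ x[pos]))
  start <- list(a = exp(init[[1L]]), b = init[[2L]])
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    stats::nls(y ~ a * exp(b * x), data = df, start = start,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * x), data = df, start = start),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    structure(list(a = cf[["a"]], b = cf[["b"]],
                   rss = sum(stats::resid(fit)^2), n = length(x),
                   converged = TRUE), class = "exp_fit")
  } else {
    a <- start$a; b <- start$b
    structure(list(a = a, b = b, rss = sum((y - a * exp(b * x))^2),
                   n = length(x), converged = FALSE), class = "exp_fit")
  }
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> y = %.4g * exp(%.4g x), rss = %.4g, n = %d%s\n",
              x$a, x$b, x$rss, x$n,
              if (x$converged) "" else " (log-linear fallback)"))
  invisible(x)
}
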