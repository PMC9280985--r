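ct <- function(x, fs = 1000) channel_trace(x, fs = fs)

test_that("rectification is the pointwise absolute value and idempotent", {
  tr <- ct(c(-1, 2, -3))
  expect_equal(rectify(tr)$samples, c(1, 2, 3))
  expect_equal(rectify(ct(rep(0, 5)))$samples, rep(0, 5))
  expect_equal(rectify(rectify(tr))$samples, rectify(tr)$samples)
  expect_equal(rectify(c(-2, 2)), c(2, 2))  # numeric path
})

test_that("background is the mean of the 500 lowest rectified samples", {
  expect_equal(estimate_background(ct(rep(0.2, 600))), 0.2)
  x <- c(rep(0.1, 500), rep(1, 700))
  expect_equal(estimate_background(ct(sample(x))), 0.1)
  expect_error(estimate_background(ct(rep(0.1, 499))), "shorter")
})

test_that("background subtraction clips at zero", {
  tr <- ct(c(0.5, 0.1))
  expect_equal(subtract_background(tr, 0.2)$samples, c(0.3, 0.0))
  expect_equal(subtract_background(tr, 0)$samples, tr$samples)
  expect_equal(subtract_background(ct(rep(0.2, 4)), 0.2)$samples, rep(0, 4))
  expect_error(subtract_background(tr, -0.1), "non-negative")
})

test_that("MVC reference averages per-trial smoothed maxima", {
  # constant traces: smoothing leaves them unchanged, maxima = the constants
  mk <- function(v) ct(rep(v, 2000))
  expect_equal(mvc_reference(list(mk(2), mk(2), mk(2), mk(2))), 2)
  expect_equal(mvc_reference(list(mk(1), mk(2), mk(3), mk(4))), 2.5)
  expect_equal(mvc_reference(list(mk(3))), 3)
  expect_error(mvc_reference(list()), "at least one")
})

test_that("normalization maps background to 0 and reference to 100 %MVC", {
  ref <- 0.5
  bg <- 0.05
  at_ref <- ct(rep(ref + bg, 100))
  expect_equal(normalize_emg(at_ref, bg, ref)$samples, rep(100, 100))
  at_bg <- ct(rep(bg, 100))
  expect_equal(normalize_emg(at_bg, bg, ref)$samples, rep(0, 100))
  expect_error(normalize_emg(at_bg, bg, 0), "> 0")
})

test_that("normalization is invariant to a common gain on trace and MVC", {
  set.seed(4)
  x <- abs(rnorm(1000))
  a1 <- normalize_emg(ct(x), 0.01, 0.8)
  a2 <- normalize_emg(ct(3 * x), 3 * 0.01, 3 * 0.8)
  expect_equal(a1$samples, a2$samples, tolerance = 1e-12)
})

test_that("cycle segmentation windows run strike-to-strike, capped at 20", {
  ev <- event_set("foot_strikes", times = c(0L, 1000L, 2000L))
  expect_equal(segment_cycles(ev), list(c(0L, 1000L), c(1000L, 2000L)))
  ev21 <- event_set("foot_strikes", times = seq(0L, by = 700L, length.out = 21L))
  expect_length(segment_cycles(ev21), 20L)
  ev25 <- event_set("foot_strikes", times = seq(0L, by = 700L, length.out = 25L))
  cyc <- segment_cycles(ev25)
  expect_length(cyc, 20L)
  expect_equal(cyc[[20L]], c(19L * 700L, 20L * 700L))
  expect_error(segment_cycles(event_set("foot_strikes", times = 5L)), "2 foot")
})

test_that("cycle integration is a trapezoidal %MVC*s integral", {
  fs <- 1000
  act <- channel_trace(rep(10, 700), fs = fs)
  expect_equal(integrate_cycle(act, c(0L, 700L)), 10 * 699 / fs)
  expect_equal(integrate_cycle(channel_trace(rep(0, 100), fs = fs), c(0L, 100L)), 0)
  # triangle peaking at 10 %MVC over 1 s has area 5 %MVC*s
  tt <- seq(0, 1, by = 1 / fs)
  tri <- channel_trace(10 * (1 - abs(tt - 0.5) / 0.5), fs = fs)
  expect_equal(integrate_cycle(tri, c(0L, length(tt))), 5, tolerance = 1e-3)
  expect_error(integrate_cycle(act, c(100L, 100L)), "empty")
})

test_that("binning splits remainders into the earliest bins", {
  act <- channel_trace(seq_len(200), fs = 1000)
  b <- bin_profile(act, c(0L, 200L), 100L)
  expect_equal(b, colMeans(matrix(1:200, nrow = 2)))
  # constant series stays constant
  expect_equal(bin_profile(channel_trace(rep(7, 205), fs = 1000),
                           c(0L, 205L), 100L), rep(7, 100))
  # 205 samples over 100 bins: first 5 bins of 3 samples, the rest of 2
  act205 <- channel_trace(seq_len(205), fs = 1000)
  b205 <- bin_profile(act205, c(0L, 205L), 100L)
  sizes <- c(rep(3, 5), rep(2, 95))
  ends <- cumsum(sizes)
  oracle <- vapply(seq_len(100), function(i)
    mean(seq_len(205)[(ends[i] - sizes[i] + 1):ends[i]]), numeric(1))
  expect_equal(b205, oracle)
  expect_error(bin_profile(act, c(0L, 50L), 100L), "shorter")
})

test_that("bin means conserve the window mean when bins divide evenly", {
  set.seed(9)
  for (rep in 1:5) {
    x <- rnorm(400)
    b <- bin_profile(channel_trace(x, fs = 1000), c(0L, 400L), 100L)
    expect_equal(mean(b), mean(x), tolerance = 1e-12)
  }
})

test_that("ensemble averages use the t-based 95% CI across units", {
  same <- ensemble_average(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$ci_low, same$bin_means)
  expect_equal(same$ci_high, same$bin_means)
  two <- ensemble_average(list(0, 2))
  # mean 1, CI = 1 +/- t(0.975, df = 1) * SE with SE = 1
  expect_equal(two$bin_means, 1)
  expect_equal(two$ci_high, 1 + qt(0.975, 1), tolerance = 1e-9)
  expect_equal(two$ci_low, 1 - qt(0.975, 1), tolerance = 1e-9)
  one <- ensemble_average(list(c(1, 2)))
  expect_false(one$ci_defined)
  expect_equal(one$bin_means, c(1, 2))
})

test_that("activation ratios are means of integrals, undefined for zero control", {
  expect_equal(activation_ratio(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(activation_ratio(c(4, 4), c(2, 2)), 2)
  expect_true(is.na(activation_ratio(c(1, 2), c(0, 0))))
})
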