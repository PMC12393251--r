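# Fixed-period sinusoid fitting, phase lags and symmetry angles.

test_that("noiseless sinusoids are interpolated exactly", {
  p <- seq(0, 12, 2)
  s <- position_series(p, 2 * cos(2 * pi * (p - 1.3) / 10.5) + 3)
  fit <- fit_fixed_period_sinusoid(s, weighting = "none")
  expect_equal(fit$amplitude, 2, tolerance = 1e-9)
  expect_equal(fit$peak_bp, 1.3, tolerance = 1e-9)
  expect_equal(fit$offset, 3, tolerance = 1e-9)
  expect_lt(fit$wrss, 1e-18)
  # a constant shift moves only the vertical offset
  s2 <- position_series(p, s$value + 5)
  fit2 <- fit_fixed_period_sinusoid(s2, weighting = "none")
  expect_equal(fit2$amplitude, fit$amplitude, tolerance = 1e-9)
  expect_equal(fit2$peak_bp, fit$peak_bp, tolerance = 1e-9)
  expect_equal(fit2$offset, 8, tolerance = 1e-9)
})

test_that("fitting is order-invariant and weight conventions agree", {
  p <- seq(0, 12, 2)
  set.seed(5)
  v <- cos(2 * pi * (p - 4) / 10.5) + rnorm(7, 0, 0.1)
  base <- fit_fixed_period_sinusoid(data.frame(position_bp = p, value = v),
                                    weighting = "none")
  shuf <- sample(7)
  refit <- fit_fixed_period_sinusoid(
    data.frame(position_bp = p[shuf], value = v[shuf]), weighting = "none")
  expect_equal(refit$peak_bp, base$peak_bp, tolerance = 1e-12)
  expect_equal(refit$amplitude, base$amplitude, tolerance = 1e-12)
  # equal spreads reduce the weighted fit to the unweighted one
  eq <- fit_fixed_period_sinusoid(
    data.frame(position_bp = p, value = v, sd = rep(0.3, 7)))
  expect_equal(eq$peak_bp, base$peak_bp, tolerance = 1e-12)
  # inverse-sd weighting is available as the alternative convention
  sdv <- seq(0.1, 0.7, 0.1)
  w1 <- fit_fixed_period_sinusoid(
    data.frame(position_bp = p, value = v, sd = sdv))
  w2 <- fit_fixed_period_sinusoid(
    data.frame(position_bp = p, value = v, sd = sdv),
    weighting = "inverse-sd")
  expect_false(isTRUE(all.equal(w1$peak_bp, w2$peak_bp)))
})

test_that("degenerate inputs are rejected", {
  p <- seq(0, 4, 2)
  expect_error(fit_fixed_period_sinusoid(
    data.frame(position_bp = p, value = p)), "underdetermined")
  p7 <- seq(0, 12, 2)
  expect_error(fit_fixed_period_sinusoid(
    data.frame(position_bp = p7, value = p7, sd = rep(0, 7))),
    "degenerate weights")
})

test_that("noisy peak positions are recovered without bias", {
  p <- seq(0, 12, 2)
  set.seed(11)
  err <- replicate(1000, {
    v <- cos(2 * pi * (p - 3.7) / 10.5) + 2 + rnorm(7, 0, 0.2)
    fit <- fit_fixed_period_sinusoid(data.frame(position_bp = p, value = v),
                                     weighting = "none")
    d <- (fit$peak_bp - 3.7) %% 10.5
    if (d > 5.25) d - 10.5 else d
  })
  expect_lt(abs(mean(err)), 0.1)
})

test_that("phase lags convert between bp and degrees", {
  mk <- function(peak, period = 10.5)
    structure(list(amplitude = 1, peak_bp = peak %% period, offset = 0,
                   period = period), class = "sine_fit")
  lag <- phase_lag(mk(1.3), mk(6.8))     # 5.5 bp apart
  expect_equal(lag$lag_bp, 5.5, tolerance = 1e-12)
  expect_equal(lag$lag_deg, 5.5 / 10.5 * 360, tolerance = 1e-12)
  expect_identical(lag$lag_deg_display, 189)
  expect_equal(phase_lag(mk(4), mk(4))$lag_bp, 0)
  expect_equal(phase_lag(mk(2), mk(2 + 10.5))$lag_bp, 0)
  # antisymmetry mod the period
  set.seed(3)
  for (k in 1:10) {
    a <- mk(runif(1, 0, 10.5)); b <- mk(runif(1, 0, 10.5))
    s <- (phase_lag(a, b)$lag_bp + phase_lag(b, a)$lag_bp) %% 10.5
    expect_lt(min(s, 10.5 - s), 1e-9)
  }
  expect_error(phase_lag(mk(1), mk(1, period = 10)), "incompatible")
})

test_that("repeat-unit symmetry angles match the helical period", {
  expect_equal(round(rotational_symmetry_angle(1, 10.5), 1), 34.3)
  expect_equal(round(rotational_symmetry_angle(2, 10.5), 1), 68.6)
  expect_equal(rotational_symmetry_angle(21, 10.5), 720)
  expect_error(rotational_symmetry_angle(0), "positive integer")
})
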