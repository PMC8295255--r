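lags_2s <- seq(0.033, 2, by = 0.033)

test_that("noiseless curves are recovered exactly", {
  y <- exp(-lags_2s / 0.2)
  f <- fit_curve(lags_2s, y, "exp", n_restarts = 5)
  expect_equal(f$tau, 0.2, tolerance = 1e-3)
  y2 <- 0.8 * exp(-lags_2s / 0.3) * cos(12 * lags_2s)
  f2 <- fit_curve(lags_2s, y2, "dosc", n_restarts = 20)
  expect_equal(f2$tau, 0.3, tolerance = 1e-2)
  expect_equal(unname(f2$params[["w"]]), 12, tolerance = 1e-2)
})

test_that("noisy exponential fits match the grid-search oracle", {
  set.seed(41)
  taus <- replicate(50, {
    y <- exp(-lags_2s / 0.2) + rnorm(length(lags_2s), sd = 0.05)
    fit_curve(lags_2s, y, "exp", n_restarts = 3)$tau
  })
  expect_lt(abs(median(taus) - 0.2) / 0.2, 0.10)
  # the optimizer should never do worse than a dense (a, tau) grid
  set.seed(42)
  for (i in 1:3) {
    y <- exp(-lags_2s / 0.2) + rnorm(length(lags_2s), sd = 0.05)
    f <- fit_curve(lags_2s, y, "exp", n_restarts = 5)
    g <- oracle_exp_grid(lags_2s, y)
    expect_lte(f$sse, g$sse + 1e-8)
    expect_equal(f$tau, g$tau, tolerance = 0.05)
  }
})

test_that("the extra sum-of-squares F statistic follows its definition", {
  fs <- structure(list(model = "exp", sse = 10, n_points = 50,
                       params = c(a = 1, tau = 0.2), tau = 0.2,
                       values = rep(1, 50)),
                  class = "timescale_fit")
  fc <- structure(list(model = "dosc", sse = 5, n_points = 50,
                       params = c(a = 1, tau = 0.2, w = 5, phi = 0),
                       tau = 0.2, values = rep(1, 50)),
                  class = "timescale_fit")
  out <- select_model(fs, fc, alpha = 0.05)
  expect_equal(out$f_stat, ((10 - 5) / 2) / (5 / 46), tolerance = 1e-12)
  expect_equal(out$f_stat, 23.0, tolerance = 1e-12)
  expect_equal(out$selected, "complex")
  expect_lt(out$f_p, 0.05)
})

test_that("a noiseless exponential selects the simple model", {
  y <- exp(-lags_2s / 0.25)
  out <- estimate_timescale(lags_2s, y, family = "stimulus", n_restarts = 5)
  expect_equal(out$selected, "simple")
  expect_equal(out$tau, 0.25, tolerance = 1e-3)
})

test_that("genuine damped oscillations are detected with high power", {
  set.seed(43)
  hits <- replicate(10, {
    y <- 0.3 * exp(-lags_2s / 0.3) * cos(10 * lags_2s) +
      rnorm(length(lags_2s), sd = 0.03)
    estimate_timescale(lags_2s, y, family = "response",
                       n_restarts = 10)$selected == "complex"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("tail-restricted fits behave as documented", {
  lags <- (1:30) * 0.033
  y <- exp(-lags / 0.25)
  full <- fit_intrinsic_tail(lags, y, min_lag_bins = 0, n_restarts = 20)
  tail5 <- fit_intrinsic_tail(lags, y, min_lag_bins = 5, n_restarts = 20)
  expect_equal(tail5$tau, full$tau, tolerance = 0.02)
  expect_equal(tail5$tau, 0.25, tolerance = 0.02)
  # min_lag_bins = 0 uses exactly the fit_curve points
  direct <- fit_curve(lags, y, "dosc_scaled", n_restarts = 20)
  expect_equal(full$n_points, direct$n_points)
  # a curve peaking at lag 2 bins, then decaying exponentially: the tail
  # fit ignores the peak and recovers the decay constant
  peak <- ifelse(lags <= 2 * 0.033, lags / (2 * 0.033),
                 exp(-(lags - 2 * 0.033) / 0.25))
  tl <- fit_intrinsic_tail(lags, peak, min_lag_bins = 5, n_restarts = 30)
  expect_lt(abs(tl$tau - 0.25) / 0.25, 0.10)
})

test_that("tau is scale-invariant in y and equivariant in time", {
  set.seed(47)
  y <- exp(-lags_2s / 0.15) + rnorm(length(lags_2s), sd = 0.02)
  f1 <- fit_curve(lags_2s, y, "exp", n_restarts = 5)
  f2 <- fit_curve(lags_2s, 0.5 * y, "exp", n_restarts = 5)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-4)
  f3 <- fit_curve(lags_2s * 3, y, "exp", n_restarts = 5)
  expect_equal(f3$tau, 3 * f1$tau, tolerance = 1e-3)
})

test_that("insufficient points are rejected", {
  expect_error(fit_curve(c(0.1, 0.2), c(1, 0.5), "dosc"), "fewer points")
  expect_error(fit_intrinsic_tail((1:6) * 0.033, rep(0.5, 6),
                                  min_lag_bins = 5),
               "beyond the lag cut")
})
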