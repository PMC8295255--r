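test_that("the common-slope model recovers noiseless parameters exactly", {
  x <- rep(seq(0.1, 1, length.out = 10), 2)
  g <- rep(c("A", "B"), each = 10)
  y <- 2 * x + ifelse(g == "B", 1, 0)
  fit <- suppressWarnings(ancova_fit(x, y, g))
  expect_equal(unname(fit$slope), 2, tolerance = 1e-10)
  expect_equal(unname(fit$intercepts["B"] - fit$intercepts["A"]), 1,
               tolerance = 1e-10)
  # single group, constant response
  f2 <- suppressWarnings(ancova_fit(seq(0, 1, length.out = 8), rep(3, 8),
                                    rep("only", 8)))
  expect_equal(unname(f2$slope), 0, tolerance = 1e-12)
  expect_equal(unname(f2$intercepts), 3, tolerance = 1e-12)
})

test_that("pooling maps merge areas before the fit", {
  x <- rep(seq(0.1, 0.9, length.out = 9), 4)
  g <- rep(c("V1", "LM", "LI", "LL"), each = 9)
  y <- 0.7 * x + ifelse(g == "V1", 0, 0.056)
  fit <- suppressWarnings(ancova_fit(x, y, g,
                    pooling = c(LM = "extrastriate", LI = "extrastriate",
                                LL = "extrastriate"),
                    baseline = "V1"))
  expect_equal(nrow(fit$contrasts), 1)
  expect_equal(unname(fit$contrasts[1, "Estimate"]), 0.056,
               tolerance = 1e-10)
})

test_that("ANCOVA estimates cover the truth at the expected rate", {
  set.seed(51)
  n_sim <- 300
  hits <- replicate(n_sim, {
    x <- rep(runif(18, 0.05, 0.6), 2)
    g <- rep(c("A", "B"), each = 18)
    y <- 0.7 * x + ifelse(g == "B", 0.05, 0) + rnorm(36, sd = 0.05)
    fit <- ancova_fit(x, y, g)
    abs(fit$slope - 0.7) <= 2 * fit$slope_se
  })
  expect_gte(mean(hits), 0.92)
})

test_that("Theil-Sen matches the pairwise-slope-median oracle", {
  set.seed(53)
  x <- runif(15); y <- 1.5 * x + rnorm(15, sd = 0.2)
  slopes <- c()
  for (i in 1:14) for (j in (i + 1):15) {
    if (x[j] != x[i]) slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
  }
  expect_equal(theil_sen(x, y), median(slopes), tolerance = 1e-12)
})

test_that("the robust fit resists a gross outlier where OLS does not", {
  set.seed(55)
  x <- 1:20
  y <- 2 * x + rnorm(20, sd = 0.3)
  y[20] <- y[20] + 10 * max(y)   # gross high-leverage outlier
  ts_fit <- robust_fit_bootstrap(x, y, B = 200, seed = 1)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_lt(abs(ts_fit$slope - 2) / 2, 0.05)
  expect_gt(abs(ols - 2) / 2, 0.20)
})

test_that("perfect lines give exact slopes and vanishing intervals", {
  x <- rep(seq(1, 5), 2)
  g <- rep(c("A", "B"), each = 5)
  y <- 0.5 * x + ifelse(g == "B", 2, 0)
  fit <- robust_fit_bootstrap(x, y, g, B = 200, seed = 2)
  expect_equal(unname(fit$slope), 0.5, tolerance = 1e-12)
  expect_lt(diff(fit$slope_ci), 1e-10)
  expect_error(robust_fit_bootstrap(rep(1, 6), rnorm(6), B = 200),
               "degenerate")
})

test_that("the shift-method p value equals the exhaustive bootstrap mass", {
  # 5 points: all 5^5 with-replacement resamples are enumerable
  x <- c(1, 2, 3, 4, 5)
  y <- c(0.2, -0.1, 0.4, 0.1, 0.6)
  grid <- expand.grid(rep(list(1:5), 5))
  slopes <- apply(grid, 1, function(idx) {
    xi <- x[idx]; yi <- y[idx]
    if (length(unique(xi)) < 2) return(NA_real_)
    theil_sen(xi, yi)
  })
  exact_p <- mean(slopes <= 0, na.rm = TRUE)
  fit <- robust_fit_bootstrap(x, y, B = 4000, seed = 3)
  se <- sqrt(exact_p * (1 - exact_p) / 4000)
  expect_lt(abs(fit$slope_p - exact_p), 4 * se + 1e-6)
})

test_that("segment regression recovers planted coefficients exactly", {
  areas <- rep(c("V1", "LM", "LI", "LL"), each = 4)
  d <- rep(c(0, 1, 0, 1), 4)
  cl <- rep(c(0, 0, 1, 1), 4)
  beta <- c(b0 = 0.2, LM = 0.21, LI = 0.55, LL = 0.39,
            D = 0.05, C = -0.03, CD = 0.08)
  tau <- beta["b0"] + beta["LM"] * (areas == "LM") +
    beta["LI"] * (areas == "LI") + beta["LL"] * (areas == "LL") +
    beta["D"] * d + beta["C"] * cl + beta["CD"] * d * cl
  fit <- suppressWarnings(segment_regression(tau, areas, d, cl))
  expect_equal(unname(fit$contrasts["LM vs V1", "Estimate"]), 0.21,
               tolerance = 1e-10)
  expect_equal(unname(fit$contrasts["LI vs V1", "Estimate"]), 0.55,
               tolerance = 1e-10)
  expect_equal(unname(fit$contrasts["LL vs V1", "Estimate"]), 0.39,
               tolerance = 1e-10)
  # constant condition flags reduce to a one-way area contrast
  tau2 <- 0.1 + 0.3 * (areas == "LL")
  f2 <- suppressWarnings(segment_regression(tau2, areas, rep(0, 16), rep(0, 16)))
  expect_equal(unname(f2$contrasts["LL vs V1", "Estimate"]), 0.3,
               tolerance = 1e-10)
})

test_that("hierarchy regression handles weights correctly", {
  score <- c(-0.5, -0.2, 0, 0.3, 0.6)
  tau <- 0.5 * score + 1
  fit <- suppressWarnings(hierarchy_regression(tau, score))
  expect_equal(unname(fit$slope), 0.5, tolerance = 1e-12)
  expect_equal(unname(fit$intercept), 1, tolerance = 1e-12)
  # equal weights reproduce the unweighted fit
  fw <- hierarchy_regression(tau + c(0.1, -0.1, 0, 0.05, -0.05), score,
                             weights = rep(2, 5))
  fu <- hierarchy_regression(tau + c(0.1, -0.1, 0, 0.05, -0.05), score)
  expect_equal(fw$slope, fu$slope, tolerance = 1e-12)
  expect_error(hierarchy_regression(tau, score, weights = c(0, 1, 1, 1, 1)),
               "positive")
  expect_error(hierarchy_regression(tau[1:2], score[1:2]), "3 areas")
})

test_that("inverse-variance weighting reduces estimator variance", {
  set.seed(57)
  score <- seq(-1, 1, length.out = 8)
  sds <- c(rep(0.02, 4), rep(0.3, 4))
  sims <- replicate(300, {
    tau <- 0.4 * score + 0.2 + rnorm(8, sd = sds)
    c(hierarchy_regression(tau, score, weights = 1 / sds^2)$slope,
      hierarchy_regression(tau, score)$slope)
  })
  expect_lt(var(sims[1, ]), var(sims[2, ]))
})

test_that("estimators are equivariant under unit rescaling", {
  set.seed(59)
  x <- runif(20); g <- rep(c("A", "B"), 10)
  y <- 0.3 * x + ifelse(g == "B", 0.1, 0) + rnorm(20, sd = 0.05)
  f1 <- ancova_fit(x, y, g)
  f2 <- ancova_fit(x * 1000, y * 60, g)   # e.g. ms and minutes
  expect_equal(f2$slope, f1$slope * 60 / 1000, tolerance = 1e-10)
  expect_equal(unname(f2$intercepts), unname(f1$intercepts) * 60,
               tolerance = 1e-8)
  r1 <- robust_fit_bootstrap(x, y, g, B = 150, seed = 4)
  r2 <- robust_fit_bootstrap(x * 1000, y * 60, g, B = 150, seed = 4)
  expect_equal(r2$slope, r1$slope * 60 / 1000, tolerance = 1e-10)
})

test_that("bootstrap p values are floored at 1/B and runs are reproducible", {
  set.seed(61)
  x <- 1:12; y <- x + rnorm(12, sd = 0.1)
  f1 <- robust_fit_bootstrap(x, y, B = 500, seed = 5)
  f2 <- robust_fit_bootstrap(x, y, B = 500, seed = 5)
  expect_identical(f1$boot_slope, f2$boot_slope)
  expect_equal(f1$slope_p, 1 / 500)
})
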