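test_that("gen_ar_movie is seeded-deterministic and respects its contract", {
  m1 <- gen_ar_movie(60, 30, 8, 9, 0.2, seed = 3)
  m2 <- gen_ar_movie(60, 30, 8, 9, 0.2, seed = 3)
  expect_identical(m1$frames, m2$frames)
  expect_equal(dim(m1$frames), c(60, 8, 9))
  expect_true(all(m1$frames >= 0 & m1$frames <= 255))
  expect_error(gen_ar_movie(60, 30, 8, 9, NaN), "finite")
})

test_that("a zero-timescale AR movie has mutually uncorrelated frames", {
  m <- gen_ar_movie(200, 30, 40, 40, 0, spatial_corr_len = 0, seed = 2)
  cf <- pixel_correlation(m, max_lag_s = 0.2)
  expect_equal(cf$value[1], 1)
  # 1600 pixels, ~190 pairs per lag: sampling error well under 0.02
  expect_lt(max(abs(cf$value[cf$lag_s > 0])), 0.02)
})

test_that("measured AR-movie timescale increases with the target", {
  targets <- c(0.05, 0.2, 0.6)
  fitted <- vapply(targets, function(tt) {
    est <- vapply(1:3, function(s) {
      m <- gen_ar_movie(400, 30, 30, 30, tt, seed = s)
      estimate_timescale(pixel_correlation(m, 2), family = "stimulus",
                         n_restarts = 5)$tau
    }, numeric(1))
    median(est)
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("white-noise movie has the standard geometry and balanced pixels", {
  wn <- gen_white_noise_movie(seed = 4)
  expect_equal(dim(wn$frames), c(400, 45, 80))
  expect_equal(wn$fps, 20)
  expect_true(all(wn$frames %in% c(0, 255)))
  # mean of 1.44e6 symmetric Bernoulli pixels: se ~ 0.1
  expect_lt(abs(mean(wn$frames) - 127.5), 0.5)
  expect_identical(gen_white_noise_movie(seed = 4)$frames, wn$frames)
})

test_that("phase scrambling preserves the amplitude spectrum, mean and sd", {
  m <- tiny_movie(24, 8, 10)
  ps <- phase_scramble(m, seed = 7, clip = FALSE)
  expect_equal(mean(ps$frames), mean(m$frames), tolerance = 1e-10)
  expect_equal(sd(as.vector(ps$frames)), sd(as.vector(m$frames)),
               tolerance = 1e-8)
  a_in <- Mod(fft(m$frames))
  a_out <- Mod(fft(ps$frames))
  expect_lt(max(abs(a_in - a_out)) / max(a_in), 1e-10)
  # Parseval: total spectral power preserved
  expect_equal(sum(a_out^2), sum(a_in^2), tolerance = 1e-6)
})

test_that("identity phase permutation reconstructs the movie", {
  m <- tiny_movie(16, 6, 6)
  d <- dim(m$frames)
  n_free <- sum(seq_len(prod(d)) <
                  neurotimescales:::fft_mirror_index(d))
  ps <- phase_scramble(m, perm = seq_len(n_free))
  expect_equal(ps$frames, m$frames, tolerance = 1e-8)
})

test_that("constant movies cannot be phase-scrambled", {
  const <- movie(array(100, c(10, 4, 4)), 30)
  expect_error(phase_scramble(const), "constant")
})

test_that("linear-filter responses obey their limits", {
  m <- tiny_movie(40, 8, 8)
  centers <- rbind(c(4, 4), c(2, 6))
  # tau = 0: response equals the spatially weighted movie signal
  r0 <- simulate_linear_responses(m, centers, 1.5, c(0, 0))
  flat <- matrix(m$frames, nrow = 40)
  rr <- rep(1:8, times = 8); cc <- rep(1:8, each = 8)
  w1 <- exp(-((rr - 4)^2 + (cc - 4)^2) / (2 * 1.5^2)); w1 <- w1 / sum(w1)
  expect_equal(r0[1, ], as.numeric(flat %*% w1), tolerance = 1e-10)
  # constant movie: constant response at every frame (transient renormalized)
  mc <- movie(array(80, c(30, 5, 5)) + array(rep(0, 750), c(30, 5, 5)), 30)
  mc$frames[1, 1, 1] <- 80   # keep constant
  rc <- simulate_linear_responses(mc, rbind(c(3, 3)), 1, 0.1)
  expect_equal(max(rc) - min(rc), 0, tolerance = 1e-10)
  expect_error(simulate_linear_responses(m, centers, 1.5, c(-1, 0.1)),
               ">= 0")
  expect_error(simulate_linear_responses(m, centers, 1.5, 0.1), "per unit")
})

test_that("filtered white-noise responses carry the kernel timescale", {
  wn <- gen_white_noise_movie(seed = 9, n_frames = 1500, fps = 30,
                              height = 20, width = 20)
  tau <- 0.1
  r <- simulate_linear_responses(wn, rbind(c(10, 10)), 3, tau)
  # analytic: exponentially filtered white noise has autocorrelation
  # exp(-|lag|/tau); estimate the decay from the empirical acf
  ac <- stats::acf(r[1, ], lag.max = 10, plot = FALSE)$acf[, 1, 1]
  fit <- fit_curve((0:10) / 30, ac, model = "exp", n_restarts = 10)
  expect_lt(abs(fit$tau - tau) / tau, 0.25)
})
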