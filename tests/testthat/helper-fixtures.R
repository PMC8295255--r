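# Small programmatic fixtures shared across test files.

# A tiny movie with reproducible pseudo-random content.
tiny_movie <- function(n_frames = 30, h = 6, w = 7, fps = 30, seed = 11) {
  set.seed(seed)
  movie(array(runif(n_frames * h * w, 0, 255), c(n_frames, h, w)), fps)
}

# A small Poisson population with known generative timescales.
tiny_population <- function(n_units = 8, n_trials = 6, n_bins = 40,
                            signal_tau = 0.2, intrinsic_tau = 0.1,
                            intrinsic_amp = 1, rate = 15, seed = 5) {
  spec <- population_spec(
    "test", n_units = n_units, n_trials = n_trials, mean_rate = rate,
    signal_timescale_s = signal_tau, signal_amplitude = 1,
    intrinsic_timescale_s = intrinsic_tau,
    intrinsic_amplitude = intrinsic_amp, seed = seed
  )
  gen_population(spec, n_bins, 0.033)
}

# Independent brute-force oracle: C(Delta) as the plain mean over t of
# cor(col_t, col_{t+Delta}) for a (replicates x time) matrix.
oracle_lagcor <- function(m, max_lag) {
  nt <- ncol(m)
  vapply(0:max_lag, function(d) {
    vals <- c()
    for (t in seq_len(nt - d)) {
      vals <- c(vals, suppressWarnings(cor(m[, t], m[, t + d])))
    }
    mean(vals, na.rm = TRUE)
  }, numeric(1))
}

# Brute-force (a, tau) grid-search oracle for exponential fits.
oracle_exp_grid <- function(lags, values, a_grid = seq(0.1, 2, by = 0.01),
                            tau_grid = exp(seq(log(0.01), log(5),
                                               length.out = 400))) {
  best <- list(sse = Inf)
  for (tau in tau_grid) {
    g <- exp(-lags / tau)
    for (a in a_grid) {
      sse <- sum((values - a * g)^2)
      if (sse < best$sse) best <- list(a = a, tau = tau, sse = sse)
    }
  }
  best
}
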