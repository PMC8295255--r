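test_that("pseudopopulation construction matches the floor(N/M) contract", {
  pops <- make_pseudopopulations(168, M = 20, seed = 1)
  expect_length(pops, 8)
  all_units <- unlist(pops)
  expect_equal(anyDuplicated(all_units), 0)
  expect_true(all(lengths(pops) == 20))
  one <- make_pseudopopulations(20, M = 20, seed = 2)
  expect_length(one, 1)
  expect_setequal(one[[1]], 1:20)
  expect_error(make_pseudopopulations(19, M = 20), "fewer units")
})

test_that("trial shuffling permutes trials but preserves PSTHs", {
  bc <- tiny_population(n_units = 5, n_trials = 10, n_bins = 20, seed = 3)
  sh <- shuffle_trials(bc, 1:6, 7:10, seed = 4)
  for (u in 1:5) {
    # each unit's trial set is a permutation within train and valid blocks
    expect_setequal(
      apply(bc$counts[u, 1:6, ], 1, paste, collapse = ","),
      apply(sh$counts[u, 1:6, ], 1, paste, collapse = ",")
    )
  }
  psth <- apply(bc$counts, c(1, 3), mean)
  psth_sh <- apply(sh$counts, c(1, 3), mean)
  expect_equal(psth, psth_sh)
  expect_error(shuffle_trials(bc, 1:6, 6:10), "disjoint")
})

test_that("shuffling destroys cross-cell same-trial correlations", {
  # correlated population: all units share a common per-trial gain
  set.seed(5)
  n_u <- 12; n_k <- 40; n_b <- 30
  gain <- matrix(rep(rexp(n_k), each = n_u), n_u, n_k)
  counts <- array(0L, c(n_u, n_k, n_b))
  for (b in seq_len(n_b)) {
    counts[, , b] <- matrix(rpois(n_u * n_k, 5 * gain), n_u, n_k)
  }
  bc <- binned_counts(counts, 0.033)
  totals <- function(x) apply(x$counts[, 1:30, ], c(1, 2), sum)
  mean_offdiag_cor <- function(m) {
    cc <- cor(t(m))
    mean(cc[upper.tri(cc)])
  }
  before <- mean_offdiag_cor(totals(bc))
  after <- mean_offdiag_cor(totals(shuffle_trials(bc, 1:30, 31:40, seed = 6)))
  expect_gt(before, 0.5)
  expect_lt(abs(after), 0.15)
})

test_that("linearly separable bins decode perfectly at lag zero", {
  # two temporal halves with disjoint noiseless population patterns
  n_u <- 6; n_k <- 12; n_b <- 70
  counts <- array(0L, c(n_u, n_k, n_b))
  counts[1:3, , 1:35] <- 8L
  counts[4:6, , 36:70] <- 8L
  bc <- binned_counts(counts, 0.033)
  cur <- cross_time_decode(bc, 1:8, 9:12, min_separation_bins = 35,
                           max_lag_bins = 2, stride = 17, seed = 1,
                           fit_timescale = FALSE)
  expect_equal(cur$p_test[1], 1)
  expect_equal(cur$p_train[1], 1)
})

test_that("statistically identical bins decode at chance", {
  set.seed(7)
  counts <- array(rpois(10 * 30 * 90, 2), c(10, 30, 90))
  bc <- binned_counts(counts, 0.033)
  cur <- cross_time_decode(bc, 1:20, 21:30, min_separation_bins = 40,
                           max_lag_bins = 1, stride = 10, seed = 2,
                           fit_timescale = FALSE)
  expect_lt(abs(cur$p_test[1] - 0.5), 0.1)
})

test_that("decoding curves are bit-reproducible for a fixed seed", {
  bc <- tiny_population(n_units = 8, n_trials = 15, n_bins = 60, seed = 8)
  run <- function() {
    sh <- shuffle_trials(bc, 1:10, 11:15, seed = 9)
    cross_time_decode(sh, 1:10, 11:15, min_separation_bins = 30,
                      max_lag_bins = 3, stride = 10, seed = 10,
                      fit_timescale = FALSE)
  }
  a <- run(); b <- run()
  expect_identical(a$p_test, b$p_test)
  expect_identical(a$p_train, b$p_train)
})

test_that("delta_p is the train-test gap at a one-bin lag", {
  cur <- structure(
    list(lag_s = c(0, 0.033), p_test = c(0.9, 0.75),
         p_train = c(1, 0.80), bin_width_s = 0.033),
    class = "decoding_curve"
  )
  expect_equal(delta_p(cur), 0.05)
  cur$p_train[2] <- NA
  expect_error(delta_p(cur), "one-bin lag")
})

test_that("lag folding averages branches and falls back to one branch", {
  vals <- c(NA, 0.6, 0.8, 0.7, 0.4)   # lags -2..2
  folded <- neurotimescales:::fold_lags(vals, -2:2)
  expect_equal(folded[1], 0.8)              # lag 0
  expect_equal(folded[2], mean(c(0.6, 0.7)))
  expect_equal(folded[3], 0.4)              # only the positive branch
})

test_that("static separable segments keep perfect folded performance", {
  n_u <- 21; n_k <- 12; n_b <- 29
  ca <- array(0L, c(n_u, n_k, n_b)); ca[1:10, , ] <- 6L
  cb <- array(0L, c(n_u, n_k, n_b)); cb[11:21, , ] <- 6L
  a <- binned_counts(ca, 1 / 30); b <- binned_counts(cb, 1 / 30)
  seg <- segment_decode(a, b, train_trials = 1:8, valid_trials = 9:12,
                        M = 21, n_repeats = 2, seed = 3)
  expect_equal(length(seg$lag_s), 15)
  expect_true(all(seg$p_test == 1))
  expect_equal(seg$delta_p, 0)
  mism <- binned_counts(cb[, , 1:20], 1 / 30)
  expect_error(segment_decode(a, mism, 1:8, 9:12), "equal")
})
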