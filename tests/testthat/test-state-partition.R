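test_that("epoch detection matches a sample-wise labeling oracle", {
  dt <- 0.05
  # all-rest trace: one epoch covering the trial
  ep <- find_epochs(rep(0, 100), dt)
  expect_equal(nrow(ep), 1)
  expect_equal(c(ep$start_s, ep$end_s, ep$state), c("0", "5", "rest"))
  # step trace 0 -> 5 cm/s at t = 5 s
  v <- c(rep(0, 100), rep(5, 100))
  ep2 <- find_epochs(v, dt)
  expect_equal(ep2$state, c("rest", "run"))
  expect_equal(ep2$start_s, c(0, 5))
  expect_equal(ep2$end_s, c(5, 10))
  # crafted multi-bout trace vs. independent oracle
  set.seed(63)
  v3 <- abs(rnorm(300, mean = 1, sd = 1.2))
  ep3 <- find_epochs(v3, dt)
  labels <- ifelse(v3 > 1, "run", "rest")       # v == 1 -> rest
  # oracle: expand epochs back to per-sample labels
  recon <- character(300)
  for (i in seq_len(nrow(ep3))) {
    idx <- (round(ep3$start_s[i] / dt) + 1):round(ep3$end_s[i] / dt)
    recon[idx] <- ep3$state[i]
  }
  expect_identical(recon, labels)
  # epochs tile the trial with no overlap
  expect_equal(sum(ep3$end_s - ep3$start_s), 300 * dt)
  expect_true(all(ep3$start_s[-1] == ep3$end_s[-nrow(ep3)]))
  # threshold boundary goes to rest
  expect_equal(find_epochs(rep(1, 10), dt)$state, "rest")
})

test_that("shared epochs are interval intersections above the length cut", {
  mk <- function(run_start, run_end, total = 15) {
    data.frame(start_s = c(0, run_start, run_end),
               end_s = c(run_start, run_end, total),
               state = c("rest", "run", "rest"))
  }
  eps <- list(mk(2, 8), mk(4, 10), mk(5, 12))
  sh <- shared_epochs(eps, 1:3, 2.5)
  run_sh <- sh[sh$state == "run", ]
  expect_equal(nrow(run_sh), 1)
  expect_equal(c(run_sh$start_s, run_sh$end_s), c(5, 8))
  # identical epochs in all trials intersect to themselves
  same <- list(mk(3, 9), mk(3, 9))
  sh2 <- shared_epochs(same, 1:2, 1)
  expect_equal(sh2[sh2$state == "run", ]$start_s, 3)
  expect_equal(sh2[sh2$state == "run", ]$end_s, 9)
  # disjoint run bouts share nothing
  disj <- list(mk(1, 4), mk(6, 9))
  expect_equal(nrow(shared_epochs(disj, 1:2, 0.5)[
    shared_epochs(disj, 1:2, 0.5)$state == "run", , drop = FALSE]), 0)
  # commutative in trial order
  sh3 <- shared_epochs(eps, c(3, 1, 2), 2.5)
  expect_equal(sh3[order(sh3$state, sh3$start_s), ],
               sh[order(sh$state, sh$start_s), ],
               ignore_attr = TRUE)
})

test_that("the sweep equalizes epoch counts and recovers planted effects", {
  lens <- c(9, 10, 8, 7, 10, 9, 8, 11, 9, 10, 9)
  sched <- data.frame(start_s = cumsum(c(0, head(lens, -1))),
                      end_s = cumsum(lens),
                      state = rep(c("rest", "run"), length.out = 11))
  vel <- gen_velocity(8, 100, sched, seed = 65, bout_jitter_s = 1)
  areas <- list()
  run_taus <- c(A1 = 0.05, A2 = 0.13, A3 = 0.21)
  for (i in 1:3) {
    spec <- population_spec(
      paste0("A", i), n_units = 12, n_trials = 8, mean_rate = 15,
      signal_timescale_s = 0.15, signal_amplitude = 1,
      intrinsic_amplitude = 1.5, seed = 65 + i
    )
    areas[[paste0("A", i)]] <- gen_state_population(
      spec, 3030, 0.033, vel$trial_schedules,
      intrinsic_tau_rest = 0.07, intrinsic_tau_run = run_taus[i]
    )
  }
  sw <- suppressWarnings(state_sweep(
    areas, vel, c(A1 = 1, A2 = 2, A3 = 3),
    Nt_grid = c(3, 4), L_grid = c(2.5, 4.1), seed = 66, n_restarts = 3
  ))
  # equalization: per combo/kind/area, rest and run epoch counts match
  t_tab <- sw$taus
  for (key in unique(paste(t_tab$Nt, t_tab$L, t_tab$kind, t_tab$area))) {
    sel <- t_tab[paste(t_tab$Nt, t_tab$L, t_tab$kind, t_tab$area) == key, ]
    if (nrow(sel) == 2) {
      expect_equal(sel$n_epochs[1], sel$n_epochs[2])
    }
  }
  # planted run-only intrinsic hierarchy: run slope clearly above rest
  sl <- sw$slopes[sw$slopes$kind == "intrinsic", ]
  expect_gt(mean(sl$slope[sl$state == "run"]),
            mean(sl$slope[sl$state == "rest"]))
})
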