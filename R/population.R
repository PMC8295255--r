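#' Binned spike-count containers
#'
#' `binned_counts` holds a spike-count tensor `(units, trials, bins)`
#' together with the bin width and a per-unit area label. It is produced
#' either by [bin_spikes()] from raw spike times or directly by the synthetic
#' generators.
#'
#' @param counts integer array `(n_units, n_trials, n_bins)` of nonnegative
#'   spike counts.
#' @param bin_width_s bin width in seconds (> 0).
#' @param areas character vector of area labels, one per unit.
#' @return An object of class `binned_counts`.
#' @export
binned_counts <- function(counts, bin_width_s, areas = NULL) {
  if (!is.array(counts) || length(dim(counts)) != 3L) {
    stop("`counts` must be a 3-D array (units, trials, bins)", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (!is.numeric(bin_width_s) || bin_width_s <= 0) {
    stop("`bin_width_s` must be positive", call. = FALSE)
  }
  areas <- areas %||% rep("area1", dim(counts)[1])
  if (length(areas) != dim(counts)[1]) {
    stop("`areas` must have one label per unit", call. = FALSE)
  }
  structure(
    list(counts = counts, bin_width_s = bin_width_s, areas = as.character(areas)),
    class = "binned_counts"
  )
}

#' @export
print.binned_counts <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<binned_counts> %d units x %d trials x %d bins (%.1f ms bins); areas: %s\n",
    d[1], d[2], d[3], 1000 * x$bin_width_s,
    paste(unique(x$areas), collapse = ", ")
  ))
  invisible(x)
}

#' Specification of one synthetic "area" population
#'
#' Collects the generative parameters for a doubly stochastic Poisson
#' population: a trial-invariant stimulus-locked rate modulation `s_u(t)`
#' (an exponential-autocorrelation Gaussian process with time constant
#' `signal_timescale_s`, shared across trials) and an independent per-trial
#' Ornstein-Uhlenbeck-type intrinsic modulation `z_{u,k}(t)` with time
#' constant `intrinsic_timescale_s`. Per unit and trial the firing rate is
#' `max(0, mean_rate * (1 + signal_amplitude * s_u(t) +
#' intrinsic_amplitude * z_{u,k}(t)))` and spike counts are Poisson per bin.
#'
#' @param area_label area name.
#' @param n_units,n_trials population size and number of stimulus
#'   repetitions (both >= 1).
#' @param mean_rate mean firing rate in spikes/s (>= 0).
#' @param signal_timescale_s,intrinsic_timescale_s time constants in
#'   seconds (> 0).
#' @param signal_amplitude,intrinsic_amplitude modulation depths (>= 0).
#' @param seed RNG seed for the population draw.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(area_label = "area1", n_units = 50, n_trials = 30,
                            mean_rate = 10, signal_timescale_s = 0.2,
                            signal_amplitude = 1,
                            intrinsic_timescale_s = 0.1,
                            intrinsic_amplitude = 1, seed = 1) {
  stopifnot(
    n_units >= 1, n_trials >= 1, mean_rate >= 0,
    signal_timescale_s > 0, intrinsic_timescale_s > 0,
    signal_amplitude >= 0, intrinsic_amplitude >= 0
  )
  structure(
    list(
      area_label = area_label, n_units = n_units, n_trials = n_trials,
      mean_rate = mean_rate, signal_timescale_s = signal_timescale_s,
      signal_amplitude = signal_amplitude,
      intrinsic_timescale_s = intrinsic_timescale_s,
      intrinsic_amplitude = intrinsic_amplitude, seed = seed
    ),
    class = "population_spec"
  )
}

# Stationary unit-variance AR(1) sample path on a grid of `n` bins with
# correlation time `tau_s` (exponential autocorrelation exp(-dt/tau)).
ar1_path <- function(n, dt, tau_s) {
  rho <- exp(-dt / tau_s)
  innov <- c(rnorm(1), rnorm(n - 1) * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

# Same, with a per-bin correlation time tau_s[t] (used by the rest/run
# state-dependent generator). Piecewise-constant tau segments are run
# through the recursive filter blockwise.
ar1_path_varying <- function(n, dt, tau_s) {
  rho <- exp(-dt / tau_s)
  eps <- rnorm(n)
  x <- numeric(n)
  x[1] <- eps[1]
  seg <- rle(rho[-1])
  pos <- 2L
  for (i in seq_along(seg$lengths)) {
    r <- seg$values[i]
    len <- seg$lengths[i]
    innov <- sqrt(1 - r^2) * eps[pos:(pos + len - 1L)]
    x[pos:(pos + len - 1L)] <- stats::filter(innov, r, method = "recursive",
                                             init = x[pos - 1L])
    pos <- pos + len
  }
  x
}

#' Generate a doubly stochastic Poisson spike population
#'
#' Draws spike counts per the model documented in [population_spec()]. The
#' generating processes are returned as the ground-truth record so that
#' downstream timescale estimates can be validated against them.
#'
#' @param spec a [population_spec].
#' @param n_bins number of time bins per trial.
#' @param bin_width_s bin width in seconds (> 0).
#' @return A [binned_counts] with attribute `truth`: a list holding the
#'   spec, the signal matrix `signal` `(units, bins)` and the generating
#'   timescales.
#' @export
gen_population <- function(spec, n_bins, bin_width_s = 0.033) {
  stopifnot(inherits(spec, "population_spec"), n_bins >= 2)
  if (bin_width_s <= 0) stop("`bin_width_s` must be positive", call. = FALSE)
  nu <- spec$n_units; nk <- spec$n_trials
  counts <- array(0L, c(nu, nk, n_bins))
  signal <- matrix(0, nu, n_bins)
  with_seed(spec$seed, {
    for (u in seq_len(nu)) {
      s <- ar1_path(n_bins, bin_width_s, spec$signal_timescale_s)
      signal[u, ] <- s
      for (k in seq_len(nk)) {
        z <- ar1_path(n_bins, bin_width_s, spec$intrinsic_timescale_s)
        rate <- pmax(0, spec$mean_rate *
                          (1 + spec$signal_amplitude * s +
                             spec$intrinsic_amplitude * z))
        counts[u, k, ] <- rpois(n_bins, rate * bin_width_s)
      }
    }
  })
  out <- binned_counts(counts, bin_width_s, rep(spec$area_label, nu))
  attr(out, "truth") <- list(
    spec = spec, signal = signal,
    signal_timescale_s = spec$signal_timescale_s,
    intrinsic_timescale_s = spec$intrinsic_timescale_s
  )
  out
}

#' Wheel-velocity traces with alternating rest/run bouts
#'
#' Builds a per-trial sampled speed trace from a bout schedule. Rest bouts
#' are jittered below 1 cm/s, run bouts around `run_speed` (always above
#' 1 cm/s), matching the convention that rest means `v < 1` cm/s and run
#' `v > 1` cm/s.
#'
#' @param n_trials number of trials.
#' @param duration_s trial duration in seconds.
#' @param bout_schedule data frame with columns `start_s`, `end_s`,
#'   `state` (`"rest"` or `"run"`); bouts must be non-overlapping and cover
#'   `[0, duration_s]`.
#' @param seed RNG seed.
#' @param dt_s sampling interval in seconds.
#' @param run_speed nominal running speed in cm/s.
#' @param bout_jitter_s per-trial uniform jitter applied to the interior
#'   bout boundaries (animals do not start or stop running at identical
#'   times in every trial); 0 reproduces the schedule exactly in all trials.
#' @return An object of class `velocity_trace`: list with `v` (matrix
#'   `(trials, samples)`, cm/s), `dt_s`, `duration_s`, and
#'   `trial_schedules`, the realized per-trial bout schedules.
#' @export
gen_velocity <- function(n_trials, duration_s, bout_schedule, seed = 1,
                         dt_s = 0.05, run_speed = 5, bout_jitter_s = 0) {
  sched <- bout_schedule[order(bout_schedule$start_s), , drop = FALSE]
  stopifnot(all(c("start_s", "end_s", "state") %in% names(sched)))
  if (any(sched$end_s <= sched$start_s)) stop("empty bout", call. = FALSE)
  if (nrow(sched) > 1 &&
      any(sched$start_s[-1] < sched$end_s[-nrow(sched)] - 1e-9)) {
    stop("overlapping bouts in schedule", call. = FALSE)
  }
  if (abs(sched$start_s[1]) > 1e-9 ||
      abs(sched$end_s[nrow(sched)] - duration_s) > 1e-9 ||
      (nrow(sched) > 1 &&
       any(abs(sched$start_s[-1] - sched$end_s[-nrow(sched)]) > 1e-9))) {
    stop("bout schedule must tile [0, duration_s]", call. = FALSE)
  }
  times <- seq(0, duration_s - dt_s / 2, by = dt_s)
  nb <- nrow(sched)
  out <- with_seed(seed, {
    v <- matrix(0, n_trials, length(times))
    scheds <- vector("list", n_trials)
    max_jit <- if (nb > 1) {
      min(bout_jitter_s, 0.45 * min(sched$end_s - sched$start_s))
    } else {
      0
    }
    for (k in seq_len(n_trials)) {
      bounds <- c(0, sched$end_s)
      if (max_jit > 0 && nb > 1) {
        bounds[2:nb] <- bounds[2:nb] + runif(nb - 1, -max_jit, max_jit)
      }
      sk <- data.frame(start_s = bounds[-(nb + 1)], end_s = bounds[-1],
                       state = sched$state, stringsAsFactors = FALSE)
      scheds[[k]] <- sk
      state <- character(length(times))
      for (i in seq_len(nb)) {
        sel <- times >= sk$start_s[i] - 1e-9 & times < sk$end_s[i] - 1e-9
        state[sel] <- sk$state[i]
      }
      rest <- state == "rest"
      v[k, rest] <- runif(sum(rest), 0, 0.8)
      v[k, !rest] <- pmax(1.2, run_speed + rnorm(sum(!rest), sd = 0.5))
    }
    list(v = v, scheds = scheds)
  })
  structure(
    list(v = out$v, dt_s = dt_s, duration_s = duration_s, times_s = times,
         schedule = sched, trial_schedules = out$scheds),
    class = "velocity_trace"
  )
}

#' Generate a population whose intrinsic timescale depends on behavioural state
#'
#' Variant of [gen_population()] in which the intrinsic modulation is an
#' AR(1) process whose correlation time switches between `intrinsic_tau_rest`
#' and `intrinsic_tau_run` following a rest/run bout schedule, emulating
#' state-dependent neural dynamics. The stimulus-locked signal is generated
#' as in [gen_population()].
#'
#' @param spec a [population_spec]; its `intrinsic_timescale_s` is ignored in
#'   favour of the two state-specific values.
#' @param n_bins,bin_width_s binning grid.
#' @param bout_schedule rest/run schedule as in [gen_velocity()]: either a
#'   single data frame applied to every trial, or a list of per-trial
#'   schedules (e.g., the `trial_schedules` of a jittered velocity trace).
#' @param intrinsic_tau_rest,intrinsic_tau_run state-specific intrinsic time
#'   constants in seconds.
#' @return A [binned_counts] with a `truth` attribute.
#' @export
gen_state_population <- function(spec, n_bins, bin_width_s, bout_schedule,
                                 intrinsic_tau_rest, intrinsic_tau_run) {
  stopifnot(inherits(spec, "population_spec"),
            intrinsic_tau_rest > 0, intrinsic_tau_run > 0)
  times <- (seq_len(n_bins) - 0.5) * bin_width_s
  per_trial <- is.list(bout_schedule) && !is.data.frame(bout_schedule)
  tau_for <- function(sched) {
    tau_t <- rep(intrinsic_tau_rest, n_bins)
    for (i in seq_len(nrow(sched))) {
      if (sched$state[i] == "run") {
        sel <- times >= sched$start_s[i] & times < sched$end_s[i]
        tau_t[sel] <- intrinsic_tau_run
      }
    }
    tau_t
  }
  nu <- spec$n_units; nk <- spec$n_trials
  if (per_trial && length(bout_schedule) != nk) {
    stop("need one schedule per trial", call. = FALSE)
  }
  tau_by_trial <- if (per_trial) {
    lapply(bout_schedule, tau_for)
  } else {
    rep(list(tau_for(bout_schedule)), nk)
  }
  counts <- array(0L, c(nu, nk, n_bins))
  with_seed(spec$seed, {
    for (u in seq_len(nu)) {
      s <- ar1_path(n_bins, bin_width_s, spec$signal_timescale_s)
      for (k in seq_len(nk)) {
        z <- ar1_path_varying(n_bins, bin_width_s, tau_by_trial[[k]])
        rate <- pmax(0, spec$mean_rate *
                          (1 + spec$signal_amplitude * s +
                             spec$intrinsic_amplitude * z))
        counts[u, k, ] <- rpois(n_bins, rate * bin_width_s)
      }
    }
  })
  out <- binned_counts(counts, bin_width_s, rep(spec$area_label, nu))
  attr(out, "truth") <- list(
    spec = spec, intrinsic_tau_rest = intrinsic_tau_rest,
    intrinsic_tau_run = intrinsic_tau_run
  )
  out
}
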