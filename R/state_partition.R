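#' Rest/run epochs from a wheel-velocity trace
#'
#' Labels every velocity sample as resting (`v < threshold`) or running
#' (`v > threshold`); samples exactly at the threshold are assigned to rest
#' (conservative toward "not running"). Maximal contiguous runs of samples
#' with the same label form the epochs, which tile the trial exactly.
#'
#' @param v numeric velocity samples (cm/s) of one trial, uniformly sampled.
#' @param dt_s sampling interval in seconds.
#' @param threshold rest/run threshold in cm/s (default 1).
#' @return Data frame with columns `start_s`, `end_s`, `state`.
#' @export
find_epochs <- function(v, dt_s, threshold = 1) {
  if (any(v < 0)) stop("velocities must be nonnegative", call. = FALSE)
  running <- v > threshold
  r <- rle(running)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(
    start_s = (starts - 1L) * dt_s,
    end_s = ends * dt_s,
    state = ifelse(r$values, "run", "rest"),
    stringsAsFactors = FALSE
  )
}

#' Per-trial epochs of a velocity trace
#'
#' @param trace a `velocity_trace` (see [gen_velocity()]).
#' @param threshold rest/run threshold in cm/s.
#' @return A list of epoch data frames, one per trial.
#' @export
epochs_by_trial <- function(trace, threshold = 1) {
  stopifnot(inherits(trace, "velocity_trace"))
  lapply(seq_len(nrow(trace$v)), function(k) {
    find_epochs(trace$v[k, ], trace$dt_s, threshold)
  })
}

# Intersection of two sets of disjoint intervals, each a data.frame with
# start_s / end_s.
intersect_intervals <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start_s[i], b$start_s)
    e <- pmin(a$end_s[i], b$end_s)
    ok <- which(e > s + 1e-12)
    for (j in ok) out[[length(out) + 1L]] <- c(s[j], e[j])
  }
  if (!length(out)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start_s = m[, 1], end_s = m[, 2])
}

#' Shared rest/run epochs across trials
#'
#' For each state, intersects the epoch intervals of the chosen trials
#' (segments of the movie where all chosen trials are in that state) and
#' keeps intersections of duration at least `min_duration_L`. An empty
#' result is allowed.
#'
#' @param epoch_list per-trial list of epoch data frames (see
#'   [epochs_by_trial()]).
#' @param chosen_trials indices of the trials to intersect.
#' @param min_duration_L minimum shared-epoch duration in seconds.
#' @return Data frame with `start_s`, `end_s`, `state` (possibly 0 rows).
#' @export
shared_epochs <- function(epoch_list, chosen_trials, min_duration_L) {
  res <- list()
  for (st in c("rest", "run")) {
    cur <- NULL
    for (k in chosen_trials) {
      ep <- epoch_list[[k]]
      ep <- ep[ep$state == st, c("start_s", "end_s"), drop = FALSE]
      cur <- if (is.null(cur)) ep else intersect_intervals(cur, ep)
      if (nrow(cur) == 0) break
    }
    if (!is.null(cur) && nrow(cur)) {
      cur <- cur[cur$end_s - cur$start_s >= min_duration_L - 1e-9, ,
                 drop = FALSE]
      if (nrow(cur)) {
        cur$state <- st
        res[[length(res) + 1L]] <- cur
      }
    }
  }
  if (!length(res)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      state = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Bin indices fully contained in [start_s, end_s].
bins_in_epoch <- function(start_s, end_s, bin_width_s, n_bins) {
  t <- seq_len(n_bins)
  which((t - 1) * bin_width_s >= start_s - 1e-9 &
          t * bin_width_s <= end_s + 1e-9)
}

# Trial subset of size nt maximizing the total duration of shared epochs
# (rest + run) at minimum duration L; seeded tie-break.
best_trial_subset <- function(epoch_list, nt, L, seed, max_combos = 400) {
  n <- length(epoch_list)
  if (nt > n) stop("fewer trials than N_t", call. = FALSE)
  combos <- combn(n, nt, simplify = FALSE)
  if (length(combos) > max_combos) {
    combos <- with_seed(seed, combos[sample(length(combos), max_combos)])
  }
  score <- vapply(combos, function(tr) {
    se <- shared_epochs(epoch_list, tr, L)
    if (nrow(se) == 0) 0 else sum(se$end_s - se$start_s)
  }, numeric(1))
  ties <- which(score >= max(score) - 1e-12)
  pick <- if (length(ties) == 1) ties else with_seed(seed, sample(ties, 1))
  combos[[pick]]
}

# One epoch's response and intrinsic timescale fits for one area.
epoch_fits <- function(binned, trials, bins, max_lag_s, n_restarts) {
  sub <- binned_counts(
    binned$counts[, trials, bins, drop = FALSE],
    binned$bin_width_s, binned$areas
  )
  res <- list()
  for (kind in c("response", "intrinsic")) {
    fit <- tryCatch({
      cf <- if (kind == "response") {
        response_correlation(sub, max_lag_s, min_pairs = 5)
      } else {
        intrinsic_correlation(sub, max_lag_s, min_pairs = 5)
      }
      suppressWarnings(
        fit_curve(cf$lag_s, cf$value, model = "exp",
                  n_restarts = n_restarts, seed = 1)
      )
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      res[[kind]] <- list(tau = fit$tau, rmse = fit$rmse)
    }
  }
  res
}

#' Rest/run sweep of neural timescales over (N_t, L) combinations
#'
#' For every combination of trial count `N_t` and minimal shared-epoch
#' duration `L`: picks the trial subset maximizing total shared rest+run
#' epoch duration, computes response and intrinsic correlation functions
#' restricted to each shared epoch (per area), fits exponential decays,
#' pools the fit errors (rmse) across states and areas per kind and keeps
#' fits in the lower `error_percentile`, equalizes rest/run epoch counts per
#' area by seeded subsampling, averages the retained time constants per
#' area, and regresses them on the anatomical hierarchy score per state.
#' Response and intrinsic timescales are separate analyses throughout: a
#' combo is dropped for one kind (with a warning) when that kind is left
#' with an empty area/state cell. Finally the run-vs-rest slope difference
#' is tested with a paired two-tailed t-test across the (N_t, L)
#' combinations, per kind.
#'
#' @param area_counts named list of [binned_counts], one per area, sharing
#'   the trial/time grid of `velocity`.
#' @param velocity a `velocity_trace` covering the same trials.
#' @param hierarchy_scores named numeric vector of anatomical scores, names
#'   matching `names(area_counts)`.
#' @param Nt_grid trial counts to sweep (default `c(3, 4, 5, 6)`).
#' @param L_grid minimal epoch durations in seconds (default
#'   `c(2.5, 3.3, 4.1, 5.0, 6.6)`).
#' @param error_percentile keep fits with rmse below this pooled quantile
#'   (default 0.5).
#' @param max_lag_s correlation lag range inside epochs (default 0.5 s).
#' @param threshold rest/run velocity threshold (cm/s).
#' @param seed RNG seed (subset tie-breaks and epoch subsampling).
#' @param n_restarts restarts per exponential fit.
#' @return A list of class `state_sweep` with `taus` (long data frame:
#'   `Nt`, `L`, `state`, `kind`, `area`, `tau_s`, `n_epochs`), `slopes`
#'   (per combo / state / kind hierarchy-regression slopes), and `tests`
#'   (per kind: paired t-test of run vs. rest slopes across combos).
#' @export
state_sweep <- function(area_counts, velocity, hierarchy_scores,
                        Nt_grid = c(3, 4, 5, 6),
                        L_grid = c(2.5, 3.3, 4.1, 5.0, 6.6),
                        error_percentile = 0.5, max_lag_s = 0.5,
                        threshold = 1, seed = 1, n_restarts = 10) {
  stopifnot(length(Nt_grid) >= 1, length(L_grid) >= 1)
  stopifnot(all(names(area_counts) %in% names(hierarchy_scores)))
  ep_list <- epochs_by_trial(velocity, threshold)
  taus_rows <- list()
  slope_rows <- list()
  combo_id <- 0L
  for (nt in Nt_grid) {
    for (L in L_grid) {
      combo_id <- combo_id + 1L
      trials <- best_trial_subset(ep_list, nt, L, seed + combo_id)
      shared <- shared_epochs(ep_list, trials, L)
      if (nrow(shared) == 0) {
        warning(sprintf("combo N_t=%d L=%.1f: no shared epochs, dropped",
                        nt, L), call. = FALSE)
        next
      }
      # per-epoch fits
      recs <- list()
      for (ei in seq_len(nrow(shared))) {
        for (area in names(area_counts)) {
          bc <- area_counts[[area]]
          bins <- bins_in_epoch(shared$start_s[ei], shared$end_s[ei],
                                bc$bin_width_s, dim(bc$counts)[3])
          if (length(bins) < 8) next
          f <- epoch_fits(bc, trials, bins, max_lag_s, n_restarts)
          for (kind in names(f)) {
            recs[[length(recs) + 1L]] <- data.frame(
              state = shared$state[ei], area = area, kind = kind,
              tau = f[[kind]]$tau, rmse = f[[kind]]$rmse,
              stringsAsFactors = FALSE
            )
          }
        }
      }
      if (!length(recs)) {
        warning(sprintf("combo N_t=%d L=%.1f: no valid fits, dropped",
                        nt, L), call. = FALSE)
        next
      }
      recs <- do.call(rbind, recs)
      # response and intrinsic timescales are separate analyses: filter,
      # equalize and regress each kind on its own, dropping the combo for a
      # kind only when that kind has an empty area/state cell
      for (kind in unique(recs$kind)) {
        rk <- recs[recs$kind == kind, , drop = FALSE]
        # percentile filter on fit error, pooled across states and areas
        cut <- quantile(rk$rmse, error_percentile, names = FALSE)
        rk <- rk[rk$rmse <= cut, , drop = FALSE]
        # equalize rest/run epoch counts per area
        eq <- list()
        dropped <- FALSE
        for (area in names(area_counts)) {
          sel <- rk[rk$area == area, , drop = FALSE]
          n_keep <- min(sum(sel$state == "rest"), sum(sel$state == "run"))
          if (n_keep == 0) { dropped <- TRUE; break }
          for (st in c("rest", "run")) {
            rows <- which(sel$state == st)
            if (length(rows) > n_keep) {
              rows <- with_seed(seed + combo_id, sample(rows, n_keep))
            }
            eq[[length(eq) + 1L]] <- sel[rows, , drop = FALSE]
          }
        }
        if (dropped || !length(eq)) {
          warning(sprintf(
            "combo N_t=%d L=%.1f (%s): an area has zero retained epochs in one state, dropped",
            nt, L, kind), call. = FALSE)
          next
        }
        eq <- do.call(rbind, eq)
        # per-area mean taus and hierarchy regression per state
        for (st in c("rest", "run")) {
          sub <- eq[eq$state == st, , drop = FALSE]
          agg <- tapply(sub$tau, sub$area, mean)
          areas <- names(agg)
          taus_rows[[length(taus_rows) + 1L]] <- data.frame(
            Nt = nt, L = L, state = st, kind = kind, area = areas,
            tau_s = as.numeric(agg),
            n_epochs = as.numeric(table(sub$area)[areas]),
            stringsAsFactors = FALSE
          )
          if (length(agg) >= 3) {
            hr <- hierarchy_regression(as.numeric(agg),
                                       hierarchy_scores[areas])
            slope_rows[[length(slope_rows) + 1L]] <- data.frame(
              Nt = nt, L = L, state = st, kind = kind, slope = hr$slope,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  taus <- if (length(taus_rows)) do.call(rbind, taus_rows) else NULL
  slopes <- if (length(slope_rows)) do.call(rbind, slope_rows) else NULL
  tests <- list()
  if (!is.null(slopes)) {
    for (kind in unique(slopes$kind)) {
      sk <- slopes[slopes$kind == kind, , drop = FALSE]
      wide <- merge(
        sk[sk$state == "run", c("Nt", "L", "slope")],
        sk[sk$state == "rest", c("Nt", "L", "slope")],
        by = c("Nt", "L"), suffixes = c("_run", "_rest")
      )
      if (nrow(wide) >= 2) {
        tt <- t.test(wide$slope_run, wide$slope_rest, paired = TRUE)
        tests[[kind]] <- list(
          p_value = tt$p.value, t = unname(tt$statistic),
          mean_difference = unname(tt$estimate), n_combos = nrow(wide)
        )
      }
    }
  }
  structure(list(taus = taus, slopes = slopes, tests = tests),
            class = "state_sweep")
}

#' @export
print.state_sweep <- function(x, ...) {
  cat("<state_sweep>\n")
  if (!is.null(x$slopes)) {
    cat(sprintf("  %d combo/state/kind slopes\n", nrow(x$slopes)))
  }
  for (kind in names(x$tests)) {
    cat(sprintf("  %s: run-rest slope diff = %.4g, paired t p = %.3g (%d combos)\n",
                kind, x$tests[[kind]]$mean_difference,
                x$tests[[kind]]$p_value, x$tests[[kind]]$n_combos))
  }
  invisible(x)
}
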