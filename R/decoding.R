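#' Random disjoint pseudopopulations
#'
#' Splits a pool of `N` units into `K = floor(N / M)` disjoint random
#' subpopulations of size `M` (without replacement); leftover units are
#' unused. The same sets are used for the training and validation trials.
#'
#' @param unit_ids vector of unit identifiers (or a single integer `N`,
#'   taken as `1:N`).
#' @param M pseudopopulation size (default 20).
#' @param seed RNG seed.
#' @return A list of `K` vectors of unit ids.
#' @export
make_pseudopopulations <- function(unit_ids, M = 20, seed = 1) {
  if (length(unit_ids) == 1L && is.numeric(unit_ids)) {
    unit_ids <- seq_len(unit_ids)
  }
  n <- length(unit_ids)
  if (n < M) stop("fewer units (", n, ") than the population size ", M,
                  call. = FALSE)
  k <- n %/% M
  shuffled <- with_seed(seed, sample(unit_ids))
  lapply(seq_len(k), function(i) shuffled[((i - 1) * M + 1):(i * M)])
}

#' Shuffle cell activity across trials
#'
#' Applies an independent permutation of trial indices to every unit,
#' separately within the training and validation trial sets. This destroys
#' cross-cell noise correlations while preserving each unit's within-trial
#' temporal structure and its PSTH.
#'
#' @param binned a [binned_counts].
#' @param train_trials,valid_trials disjoint trial index sets.
#' @param seed RNG seed.
#' @return A [binned_counts] with shuffled trial assignment.
#' @export
shuffle_trials <- function(binned, train_trials, valid_trials, seed = 1) {
  stopifnot(inherits(binned, "binned_counts"))
  if (length(intersect(train_trials, valid_trials)) > 0) {
    stop("training and validation trial sets must be disjoint", call. = FALSE)
  }
  counts <- binned$counts
  nu <- dim(counts)[1]
  with_seed(seed, {
    for (u in seq_len(nu)) {
      counts[u, train_trials, ] <-
        counts[u, train_trials[sample(length(train_trials))], ]
      counts[u, valid_trials, ] <-
        counts[u, valid_trials[sample(length(valid_trials))], ]
    }
  })
  binned_counts(counts, binned$bin_width_s, binned$areas)
}

# Fit a linear SVM (hinge loss, C-classification) on rows of `x` with labels
# `y`; returns a prediction closure. Falls back to a majority vote when the
# solver cannot run (e.g., zero-variance features in both classes).
linear_svm <- function(x, y, cost) {
  fit <- tryCatch(
    e1071::svm(x, factor(y), kernel = "linear", cost = cost, scale = FALSE,
               type = "C-classification"),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    lev <- names(which.max(table(y)))
    return(function(newx) rep(lev, nrow(newx)))
  }
  function(newx) as.character(predict(fit, newx))
}

# Stratified k-fold assignment: per class, a seeded random split into
# `n_folds` nearly equal folds.
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (lev in unique(y)) {
      idx <- which(y == lev)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

# Select the regularization cost by stratified cross-validation; ties go to
# the smallest cost (strongest regularization).
select_cost <- function(x, y, c_grid, n_folds, seed) {
  c_grid <- sort(c_grid)
  folds <- stratified_folds(y, n_folds, seed)
  acc <- vapply(c_grid, function(cost) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      te <- folds == f
      pred <- linear_svm(x[!te, , drop = FALSE], y[!te], cost)(
        x[te, , drop = FALSE])
      correct <- correct + sum(pred == y[te])
    }
    correct / length(y)
  }, numeric(1))
  c_grid[which.max(acc)]   # which.max takes the first (= smallest) maximum
}

#' Cross-temporal decoding of population activity
#'
#' Assesses the temporal stability of a population code. For every
#' "reference" pair of time bins `(t1, t2)` separated by at least
#' `min_separation_bins`, a linear support vector classifier is trained to
#' discriminate the population spike-count vectors of the training trials at
#' `t1` vs. `t2` (regularization cost selected by stratified cross-validation
#' over `c_grid`, then retrained on the full training set). The fixed
#' classifier is then tested at time bins lagged by `-max_lag_bins ..
#' +max_lag_bins` from the training bins, separately on the held-out
#' validation trials (`p_test`) and on the training trials themselves
#' (`p_train`). Accuracies at `+Delta` and `-Delta` are folded by averaging,
#' curves are averaged over all reference pairs, and a decoding timescale is
#' extracted from `p_test` with the decoding model family.
#'
#' @param binned a [binned_counts] holding one pseudopopulation
#'   (units x trials x bins); trial shuffling should already have been
#'   applied (see [shuffle_trials()]).
#' @param train_trials,valid_trials disjoint trial index sets (the standard
#'   split is 20 training / 10 validation).
#' @param min_separation_bins minimum separation of the reference bins
#'   (default 40 bins = 1320 ms at 33 ms).
#' @param max_lag_bins largest test lag in bins (default 20).
#' @param c_grid candidate regularization costs (default `10^(-2:2)`).
#' @param n_folds cross-validation folds (default 3).
#' @param stride subsampling stride over reference-pair start bins; 1 uses
#'   all pairs, larger values an unbiased uniform subsample.
#' @param seed RNG seed (cost selection folds).
#' @param fit_timescale fit the decoding timescale (set `FALSE` to skip).
#' @param n_restarts restarts for the timescale fit.
#' @return An object of class `decoding_curve`: `lag_s`, `p_test`,
#'   `p_train` (folded, lag 0..max), `n_reference_pairs`, `delta_p`
#'   (`p_train - p_test` at a one-bin lag), and `fit` (a `timescale_fit` or
#'   `NULL`).
#' @export
cross_time_decode <- function(binned, train_trials, valid_trials,
                              min_separation_bins = 40, max_lag_bins = 20,
                              c_grid = 10^(-2:2), n_folds = 3, stride = 1,
                              seed = 1, fit_timescale = TRUE,
                              n_restarts = 20) {
  stopifnot(inherits(binned, "binned_counts"))
  if (length(intersect(train_trials, valid_trials)) > 0) {
    stop("training and validation trial sets must be disjoint", call. = FALSE)
  }
  counts <- binned$counts
  nb <- dim(counts)[3]
  if (length(train_trials) < n_folds) {
    stop("need at least `n_folds` training trials per class", call. = FALSE)
  }
  t1s <- seq(1, nb, by = stride)
  pairs <- list()
  for (t1 in t1s) {
    if (t1 + min_separation_bins > nb) break
    t2s <- seq(t1 + min_separation_bins, nb, by = stride)
    for (t2 in t2s) pairs[[length(pairs) + 1L]] <- c(t1, t2)
  }
  if (length(pairs) == 0) {
    stop("no reference pair satisfies the separation constraint",
         call. = FALSE)
  }
  lags_signed <- -max_lag_bins:max_lag_bins
  ntr <- length(train_trials); nva <- length(valid_trials)
  y_train <- rep(c("A", "B"), each = ntr)
  sum_test <- sum_train <- n_test <- n_train <- numeric(max_lag_bins + 1)
  for (pi in seq_along(pairs)) {
    t1 <- pairs[[pi]][1]; t2 <- pairs[[pi]][2]
    xa <- t(counts[, train_trials, t1])
    xb <- t(counts[, train_trials, t2])
    x_train <- rbind(xa, xb)
    cost <- select_cost(x_train, y_train, c_grid, n_folds,
                        seed + 1000 * pi)
    clf <- linear_svm(x_train, y_train, cost)
    # evaluate every admissible lagged bin pair in one prediction call
    ok <- lags_signed[t1 + lags_signed >= 1 & t2 + lags_signed <= nb]
    if (length(ok) == 0) next
    eval_set <- function(trials) {
      nt <- length(trials)
      blocks <- lapply(ok, function(dl) {
        rbind(t(counts[, trials, t1 + dl]), t(counts[, trials, t2 + dl]))
      })
      pred <- clf(do.call(rbind, blocks))
      truth <- rep(rep(c("A", "B"), each = nt), times = length(ok))
      accs <- colMeans(matrix(pred == truth, ncol = length(ok)))
      names(accs) <- as.character(ok)
      accs
    }
    acc_va <- eval_set(valid_trials)
    acc_tr <- eval_set(train_trials)
    for (d in 0:max_lag_bins) {
      for (acc in list(list(a = acc_va, s = "test"),
                       list(a = acc_tr, s = "train"))) {
        branches <- acc$a[as.character(unique(c(d, -d)))]
        branches <- branches[!is.na(branches)]
        if (length(branches) == 0) next
        v <- mean(branches)
        if (acc$s == "test") {
          sum_test[d + 1] <- sum_test[d + 1] + v
          n_test[d + 1] <- n_test[d + 1] + 1
        } else {
          sum_train[d + 1] <- sum_train[d + 1] + v
          n_train[d + 1] <- n_train[d + 1] + 1
        }
      }
    }
  }
  p_test <- ifelse(n_test > 0, sum_test / n_test, NA_real_)
  p_train <- ifelse(n_train > 0, sum_train / n_train, NA_real_)
  lag_s <- (0:max_lag_bins) * binned$bin_width_s
  dp <- if (max_lag_bins >= 1 && !is.na(p_train[2]) && !is.na(p_test[2])) {
    p_train[2] - p_test[2]
  } else {
    NA_real_
  }
  fit <- NULL
  if (fit_timescale) {
    fit <- tryCatch(
      estimate_timescale(lag_s, p_test, family = "decoding",
                         n_restarts = n_restarts, seed = seed),
      error = function(e) NULL
    )
  }
  structure(
    list(lag_s = lag_s, p_test = p_test, p_train = p_train,
         n_reference_pairs = length(pairs), delta_p = dp, fit = fit,
         bin_width_s = binned$bin_width_s),
    class = "decoding_curve"
  )
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat(sprintf(
    "<decoding_curve> %d lags, %d reference pairs; p_test(0) = %.3f, delta_p = %.4f%s\n",
    length(x$lag_s), x$n_reference_pairs, x$p_test[1],
    x$delta_p,
    if (!is.null(x$fit)) sprintf(", tau = %.3f s", x$fit$tau) else ""
  ))
  invisible(x)
}

#' Performance gain from intrinsic correlations
#'
#' `delta_p = p_train - p_test` evaluated at a lag of one bin (33 ms at the
#' default bin width) from the training bin: the extra lagged decoding
#' accuracy obtained when the test samples come from the same experimental
#' trials as the training data, attributable to within-trial intrinsic
#' temporal correlations.
#'
#' @param curve a `decoding_curve`.
#' @return A single number.
#' @export
delta_p <- function(curve) {
  stopifnot(inherits(curve, "decoding_curve"))
  if (length(curve$lag_s) < 2 || is.na(curve$p_train[2]) ||
      is.na(curve$p_test[2])) {
    stop("curve does not contain a one-bin lag for both trial sets",
         call. = FALSE)
  }
  curve$p_train[2] - curve$p_test[2]
}

# Fold a signed-lag curve: average the +d and -d branches, ignoring missing
# values; lags with a single branch use that branch alone.
fold_lags <- function(values, lags_signed, max_fold_lag = max(abs(lags_signed))) {
  out <- rep(NA_real_, max_fold_lag + 1)
  for (d in 0:max_fold_lag) {
    v <- values[lags_signed %in% unique(c(d, -d))]
    v <- v[!is.na(v)]
    if (length(v)) out[d + 1] <- mean(v)
  }
  out
}

#' Decoding analysis on hand-matched movie-segment pairs
#'
#' Variant of the cross-temporal analysis for pairs of movie segments of
#' exactly `n_bins` frames (29 frames, ~967 ms, binned at 1/30 s). Every
#' time bin is sequentially used as the training bin for a classifier
#' discriminating segment A vs. segment B at that bin; the fixed classifier
#' is tested at all other bins, yielding per-training-bin performance
#' curves over lags `-(n_bins-1) .. +(n_bins-1)` that are aligned,
#' nan-averaged, folded to `0 .. max_fold_lag` bins, and averaged over all
#' pseudopopulations and `n_repeats` random pseudopopulation draws. A
#' timescale is fitted to the folded held-out curve.
#'
#' @param counts_a,counts_b [binned_counts] for the two segments (same
#'   units, same trials; bins = segment frames at 1/30 s).
#' @param train_trials,valid_trials disjoint trial sets.
#' @param M pseudopopulation size (default 20).
#' @param n_repeats random pseudopopulation draws (default 10).
#' @param max_fold_lag folded curve extent in bins (default 14).
#' @param c_grid,n_folds classifier selection settings.
#' @param seed RNG seed.
#' @param n_restarts restarts for the timescale fit.
#' @return A list of class `segment_decoding`: `lag_s`, folded `p_test` and
#'   `p_train`, `delta_p`, `fit`.
#' @export
segment_decode <- function(counts_a, counts_b, train_trials, valid_trials,
                           M = 20, n_repeats = 10, max_fold_lag = 14,
                           c_grid = 10^(-2:2), n_folds = 3, seed = 1,
                           n_restarts = 20) {
  stopifnot(inherits(counts_a, "binned_counts"),
            inherits(counts_b, "binned_counts"))
  da <- dim(counts_a$counts); db <- dim(counts_b$counts)
  if (!all(da == db)) {
    stop("the two segments must have equal units, trials and length",
         call. = FALSE)
  }
  nb <- da[3]
  n_units <- da[1]
  lags_signed <- -(nb - 1):(nb - 1)
  ntr <- length(train_trials)
  y_train <- rep(c("A", "B"), each = ntr)
  rep_curves_test <- rep_curves_train <- list()
  for (r in seq_len(n_repeats)) {
    pops <- make_pseudopopulations(n_units, M, seed + r)
    pop_test <- pop_train <- matrix(NA_real_, length(pops),
                                    length(lags_signed))
    for (gi in seq_along(pops)) {
      g <- pops[[gi]]
      acc_test <- acc_train <- matrix(NA_real_, nb, length(lags_signed))
      for (tb in seq_len(nb)) {
        x_train <- rbind(t(counts_a$counts[g, train_trials, tb]),
                         t(counts_b$counts[g, train_trials, tb]))
        cost <- select_cost(x_train, y_train, c_grid, n_folds,
                            seed + 131 * r + 17 * gi + tb)
        clf <- linear_svm(x_train, y_train, cost)
        eval_set <- function(trials) {
          nt <- length(trials)
          blocks <- lapply(seq_len(nb), function(bb) {
            rbind(t(counts_a$counts[g, trials, bb]),
                  t(counts_b$counts[g, trials, bb]))
          })
          pred <- clf(do.call(rbind, blocks))
          truth <- rep(rep(c("A", "B"), each = nt), times = nb)
          colMeans(matrix(pred == truth, ncol = nb))
        }
        av <- eval_set(valid_trials)
        at <- eval_set(train_trials)
        cols <- (seq_len(nb) - tb) + nb      # lag index into -(nb-1)..(nb-1)
        acc_test[tb, cols] <- av
        acc_train[tb, cols] <- at
      }
      pop_test[gi, ] <- colMeans(acc_test, na.rm = TRUE)
      pop_train[gi, ] <- colMeans(acc_train, na.rm = TRUE)
    }
    rep_curves_test[[r]] <- colMeans(pop_test, na.rm = TRUE)
    rep_curves_train[[r]] <- colMeans(pop_train, na.rm = TRUE)
  }
  unfold_test <- colMeans(do.call(rbind, rep_curves_test), na.rm = TRUE)
  unfold_train <- colMeans(do.call(rbind, rep_curves_train), na.rm = TRUE)
  p_test <- fold_lags(unfold_test, lags_signed, max_fold_lag)
  p_train <- fold_lags(unfold_train, lags_signed, max_fold_lag)
  lag_s <- (0:max_fold_lag) * counts_a$bin_width_s
  fit <- tryCatch(
    estimate_timescale(lag_s, p_test, family = "decoding",
                       n_restarts = n_restarts, seed = seed),
    error = function(e) NULL
  )
  structure(
    list(lag_s = lag_s, p_test = p_test, p_train = p_train,
         delta_p = p_train[2] - p_test[2], fit = fit,
         unfolded_test = unfold_test, lags_signed = lags_signed),
    class = "segment_decoding"
  )
}
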