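#' Correlation-versus-lag functions
#'
#' The pipeline's three correlation functions share one definition: for a
#' set of vectors `X_t` indexed by time, `C(Delta)` is the average over `t`
#' of the Pearson correlation coefficient between `X_t` and `X_{t+Delta}`.
#' What varies is what `X_t` ranges over: pixels of a movie frame
#' (`stimulus`), units of the trial-averaged population response
#' (`response`), or trials of a single cell's spike count (`intrinsic`,
#' averaged across units afterwards).
#'
#' @name correlation_function
#' @keywords internal
NULL

new_correlation_function <- function(lag_s, value, n_pairs, kind) {
  out <- data.frame(lag_s = lag_s, value = value, n_pairs = n_pairs)
  structure(out, kind = kind, class = c("correlation_function", "data.frame"))
}

#' @export
print.correlation_function <- function(x, ...) {
  cat(sprintf("<correlation_function: %s> %d lags (0..%.3f s)\n",
              attr(x, "kind"), nrow(x), max(x$lag_s)))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

# Pearson correlation matrix between the columns of M (rows = replicate
# dimension). Columns with zero variance yield NA rows/columns.
colcor_matrix <- function(m) {
  n <- nrow(m)
  z <- sweep(m, 2, colMeans(m))
  ss <- sqrt(colSums(z^2))
  bad <- ss == 0
  ss[bad] <- 1
  z <- sweep(z, 2, ss, "/")
  cc <- crossprod(z)
  cc[bad, ] <- NA_real_
  cc[, bad] <- NA_real_
  pmin(pmax(cc, -1), 1)
}

# Average the superdiagonals of a correlation matrix: C(Delta) = mean over t
# of cc[t, t + Delta], skipping NA pairs. Lags with fewer than `min_pairs`
# valid pairs are dropped.
lagged_average <- function(cc, max_lag_bins, bin_width_s, kind,
                           min_pairs = 10) {
  nt <- nrow(cc)
  max_lag_bins <- min(max_lag_bins, nt - 1L)
  lags <- 0:max_lag_bins
  value <- n_pairs <- numeric(length(lags))
  for (i in seq_along(lags)) {
    d <- lags[i]
    v <- cc[cbind(seq_len(nt - d), seq_len(nt - d) + d)]
    n_pairs[i] <- sum(!is.na(v))
    value[i] <- if (n_pairs[i] > 0) mean(v, na.rm = TRUE) else NA_real_
  }
  keep <- n_pairs >= min_pairs
  if (!any(keep)) {
    stop("no lag has enough valid pairs (all pairs degenerate?)",
         call. = FALSE)
  }
  new_correlation_function(lags[keep] * bin_width_s, value[keep],
                           n_pairs[keep], kind)
}

#' Pixel-correlation function of a movie
#'
#' For each lag, the Pearson correlation over pixel positions between frame
#' `t` and frame `t + Delta`, averaged over `t`. Frames with zero pixel
#' variance are skipped (with a warning); the frame pairs they would form do
#' not contribute.
#'
#' @param mov a [movie].
#' @param max_lag_s largest lag in seconds (default 2 s).
#' @param min_pairs minimum number of valid frame pairs for a lag to be
#'   reported.
#' @return A `correlation_function` (`kind = "stimulus"`).
#' @export
pixel_correlation <- function(mov, max_lag_s = 2, min_pairs = 10) {
  stopifnot(inherits(mov, "movie"))
  nt <- n_frames(mov)
  m <- t(matrix(mov$frames, nrow = nt))    # pixels x frames
  cc <- colcor_matrix(m)
  if (anyNA(diag(cc))) {
    warning("constant frame(s): the pairs they form are skipped",
            call. = FALSE)
  }
  lagged_average(cc, round(max_lag_s * mov$fps), 1 / mov$fps, "stimulus",
                 min_pairs)
}

#' Response-correlation function of a population PSTH
#'
#' Builds the trial-averaged spike count of every unit (the PSTH), centers
#' each unit on its temporal average, and correlates the resulting
#' population vectors across time bins: `C(Delta)` is the mean over `t` of
#' the Pearson correlation (over units) between the centered population
#' vectors at bins `t` and `t + Delta`. Bins with zero across-unit variance
#' are skipped with a warning.
#'
#' @param binned a [binned_counts] with at least 2 units (typically one
#'   area's pooled units).
#' @param max_lag_s largest lag in seconds.
#' @param min_pairs minimum valid pairs per reported lag.
#' @return A `correlation_function` (`kind = "response"`).
#' @export
response_correlation <- function(binned, max_lag_s = 2, min_pairs = 10) {
  stopifnot(inherits(binned, "binned_counts"))
  d <- dim(binned$counts)
  if (d[1] < 2) stop("at least 2 units are required", call. = FALSE)
  psth <- apply(binned$counts, c(1, 3), mean)       # units x bins
  centered <- psth - rowMeans(psth)
  cc <- colcor_matrix(centered)
  if (anyNA(diag(cc))) {
    warning("bin(s) with zero across-unit variance skipped", call. = FALSE)
  }
  lagged_average(cc, round(max_lag_s / binned$bin_width_s),
                 binned$bin_width_s, "response", min_pairs)
}

#' Intrinsic (across-trial) correlation function
#'
#' For each unit, `C_u(Delta)` is the mean over `t` of the Pearson
#' correlation across trials between the unit's spike counts at bins `t` and
#' `t + Delta`; the function returns the across-unit average of `C_u`,
#' capturing within-trial firing fluctuations that are not locked to the
#' stimulus. Bin pairs where either bin has zero across-trial variance are
#' skipped; units silent in every bin are excluded with a warning.
#'
#' @param binned a [binned_counts] with at least 2 trials.
#' @param max_lag_s largest lag in seconds.
#' @param min_pairs minimum valid `(t, t + Delta)` pairs per unit and lag
#'   for the unit to contribute at that lag.
#' @return A `correlation_function` (`kind = "intrinsic"`) whose `n_pairs`
#'   column counts contributing units per lag.
#' @export
intrinsic_correlation <- function(binned, max_lag_s = 2, min_pairs = 10) {
  stopifnot(inherits(binned, "binned_counts"))
  d <- dim(binned$counts)
  if (d[2] < 2) stop("at least 2 trials are required", call. = FALSE)
  max_lag_bins <- min(round(max_lag_s / binned$bin_width_s), d[3] - 1L)
  lags <- 0:max_lag_bins
  acc <- matrix(NA_real_, d[1], length(lags))
  n_silent <- 0L
  for (u in seq_len(d[1])) {
    m <- binned$counts[u, , ]                      # trials x bins
    if (all(m == 0)) {
      n_silent <- n_silent + 1L
      next
    }
    cc <- colcor_matrix(m)
    nt <- ncol(m)
    for (i in seq_along(lags)) {
      dd <- lags[i]
      v <- cc[cbind(seq_len(nt - dd), seq_len(nt - dd) + dd)]
      if (sum(!is.na(v)) >= min_pairs) acc[u, i] <- mean(v, na.rm = TRUE)
    }
  }
  if (n_silent > 0) {
    warning(n_silent, " fully silent unit(s) excluded", call. = FALSE)
  }
  n_units <- colSums(!is.na(acc))
  if (all(n_units == 0)) {
    stop("no unit has enough valid pairs at any lag", call. = FALSE)
  }
  keep <- n_units > 0
  new_correlation_function(
    lags[keep] * binned$bin_width_s,
    colMeans(acc, na.rm = TRUE)[keep],
    n_units[keep],
    "intrinsic"
  )
}
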