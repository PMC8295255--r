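#' Spike-train sessions
#'
#' A `spike_session` holds, per unit, the spike times (seconds from stimulus
#' onset) of every repeated presentation (trial) of one stimulus, plus the
#' unit's area label. All units of a session share the same trial count and
#' stimulus duration.
#'
#' @param units list of unit entries, each a list with `unit_id`, `area`,
#'   and `spikes`: a list of numeric vectors (one per trial) of spike times
#'   within `[0, duration_s]`.
#' @param duration_s stimulus duration in seconds.
#' @param stimulus_id optional stimulus identifier.
#' @return An object of class `spike_session`.
#' @export
spike_session <- function(units, duration_s, stimulus_id = "stim") {
  if (length(units) == 0) stop("session has no units", call. = FALSE)
  ntr <- vapply(units, function(u) length(u$spikes), integer(1))
  if (length(unique(ntr)) != 1L) {
    stop("all units of a session must have the same trial count", call. = FALSE)
  }
  for (u in units) {
    for (tr in u$spikes) {
      if (length(tr) && (min(tr) < 0 || max(tr) > duration_s)) {
        stop("spike times must lie within [0, duration_s]", call. = FALSE)
      }
    }
  }
  structure(
    list(units = units, duration_s = duration_s, stimulus_id = stimulus_id,
         n_trials = ntr[1]),
    class = "spike_session"
  )
}

#' Bin a spike session into spike counts
#'
#' Counts spikes in half-open bins `[t * w, (t + 1) * w)`: a spike exactly at
#' a bin edge belongs to the later bin. The trailing partial bin is dropped,
#' so `n_bins = floor(duration_s / bin_width_s)`.
#'
#' @param session a [spike_session].
#' @param bin_width_s bin width in seconds; the pipeline default is 33 ms.
#' @return A [binned_counts] of shape `(units, trials, bins)`.
#' @export
bin_spikes <- function(session, bin_width_s = 0.033) {
  stopifnot(inherits(session, "spike_session"))
  if (bin_width_s <= 0) stop("`bin_width_s` must be positive", call. = FALSE)
  nb <- floor(session$duration_s / bin_width_s)
  if (nb < 1) stop("bin width longer than the stimulus", call. = FALSE)
  nu <- length(session$units)
  nk <- session$n_trials
  counts <- array(0L, c(nu, nk, nb))
  edges <- (0:nb) * bin_width_s
  for (u in seq_len(nu)) {
    for (k in seq_len(nk)) {
      st <- session$units[[u]]$spikes[[k]]
      st <- st[st < edges[nb + 1]]            # beyond the last full bin: dropped
      if (length(st)) {
        idx <- pmin(nb, floor(st / bin_width_s) + 1L)  # half-open convention
        tab <- tabulate(idx, nbins = nb)
        counts[u, k, ] <- tab
      }
    }
  }
  binned_counts(counts, bin_width_s,
                vapply(session$units, function(u) u$area, character(1)))
}

#' Reproducibility index of a single unit
#'
#' Quantifies how repeatable a unit's response to its preferred movie frames
#' is across trials. The top `top_fraction` of time bins by trial-averaged
#' response are selected (ties broken toward earlier bins); over those bins
#' the coefficient of variation across trials (population standard deviation
#' over mean) is averaged, and the index is `1 - <CV> / sqrt(N)` for `N`
#' trials. Identical responses in every trial give 1. Selected bins whose
#' trial mean is zero are excluded from the average; if every selected bin is
#' silent the unit is scored `-Inf` (non-reproducible).
#'
#' @param counts_one_unit numeric matrix `(trials, bins)` of spike counts.
#' @param top_fraction fraction of bins entering the metric (default 0.10).
#' @return A single numeric score `<= 1`.
#' @export
reproducibility_index <- function(counts_one_unit, top_fraction = 0.10) {
  x <- as.matrix(counts_one_unit)
  n <- nrow(x)
  if (n < 2) stop("at least 2 trials are required", call. = FALSE)
  nb <- ncol(x)
  psth <- colMeans(x)
  n_top <- ceiling(top_fraction * nb)
  sel <- order(-psth, seq_len(nb))[seq_len(n_top)]
  mu <- psth[sel]
  keep <- mu > 0
  if (!any(keep)) return(-Inf)
  sdev <- apply(x[, sel[keep], drop = FALSE], 2,
                function(v) sqrt(mean((v - mean(v))^2)))
  cv <- sdev / mu[keep]
  1 - mean(cv) / sqrt(n)
}

#' Filter units by their reproducibility across movies
#'
#' A unit is retained if, for at least one movie, its reproducibility index
#' reaches the threshold (default 0.7).
#'
#' @param index_matrix numeric matrix `(units, movies)` of reproducibility
#'   indices; rownames identify units.
#' @param threshold retention threshold (inclusive).
#' @return Integer indices of the retained units (named if `index_matrix`
#'   has rownames).
#' @export
filter_units <- function(index_matrix, threshold = 0.7) {
  m <- as.matrix(index_matrix)
  best <- apply(m, 1, max)
  keep <- which(best >= threshold)
  keep
}
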