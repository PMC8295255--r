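#' Pipeline configuration
#'
#' Collects the pipeline's tunable constants with their standard defaults:
#' 33-ms bins, 2-s lag range (0.5 s in short-movie mode), regularization
#' grid `10^(-2..2)` with 3-fold cross-validation, pseudopopulation size 20,
#' 20 training / 10 validation trials, model-selection alpha 0.05, and
#' reproducibility threshold 0.7. Every analysis entry point takes its
#' constants from such a config (or the matching argument defaults), never
#' from hard-coded literals at call sites.
#'
#' @param bin_width_s spike-count bin width (s).
#' @param max_lag_s correlation lag range (s).
#' @param short_max_lag_s lag range for short-movie data (s).
#' @param c_grid classifier regularization grid.
#' @param cv_folds cross-validation folds.
#' @param pop_size pseudopopulation size.
#' @param n_train_trials,n_valid_trials trial split.
#' @param min_separation_bins reference-pair separation (bins).
#' @param max_lag_bins decoding test-lag range (bins).
#' @param alpha model-selection threshold.
#' @param reproducibility_threshold unit-filter threshold.
#' @param top_fraction reproducibility top-bin fraction.
#' @param seed default RNG seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(bin_width_s = 0.033, max_lag_s = 2,
                            short_max_lag_s = 0.5, c_grid = 10^(-2:2),
                            cv_folds = 3, pop_size = 20,
                            n_train_trials = 20, n_valid_trials = 10,
                            min_separation_bins = 40, max_lag_bins = 20,
                            alpha = 0.05, reproducibility_threshold = 0.7,
                            top_fraction = 0.10, seed = 1) {
  cfg <- list(
    bin_width_s = bin_width_s, max_lag_s = max_lag_s,
    short_max_lag_s = short_max_lag_s, c_grid = c_grid,
    cv_folds = cv_folds, pop_size = pop_size,
    n_train_trials = n_train_trials, n_valid_trials = n_valid_trials,
    min_separation_bins = min_separation_bins, max_lag_bins = max_lag_bins,
    alpha = alpha, reproducibility_threshold = reproducibility_threshold,
    top_fraction = top_fraction, seed = seed
  )
  stopifnot(cfg$bin_width_s > 0, cfg$max_lag_s > 0, cfg$alpha > 0,
            cfg$alpha < 1)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path file path.
#' @param config a [pipeline_config()].
#' @return `load_config` returns a `pipeline_config`; `save_config` the
#'   path, invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Serialize a correlation function to CSV
#'
#' Columns `lag_s`, `value`, `n_pairs`, `kind`.
#'
#' @param cf a `correlation_function`.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_correlation_csv <- function(cf, path) {
  stopifnot(inherits(cf, "correlation_function"))
  df <- as.data.frame(cf)
  df$kind <- attr(cf, "kind")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_csv
#' @export
read_correlation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("lag_s", "value", "n_pairs")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("correlation CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  new_correlation_function(df$lag_s, df$value, df$n_pairs,
                           df$kind[1] %||% "stimulus")
}

#' Serialize a timescale fit to JSON
#'
#' @param fit a `timescale_fit`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "timescale_fit"))
  out <- list(
    model = fit$model, params = as.list(fit$params), tau = fit$tau,
    sse = fit$sse, rmse = fit$rmse, n_points = fit$n_points,
    f_p = fit$f_p %||% NA, selected = fit$selected %||% NA
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load binned spike counts as CSV + JSON sidecar
#'
#' The count tensor is stored in long format (`unit`, `trial`, `bin`,
#' `count`, zeros omitted) with a JSON sidecar holding the dimensions, bin
#' width and area labels. Round-trips are exact.
#'
#' @param binned a [binned_counts].
#' @param path_prefix files `<prefix>.csv` and `<prefix>.json` are written.
#' @return `save_binned_counts`: the prefix, invisibly;
#'   `load_binned_counts`: a [binned_counts].
#' @export
save_binned_counts <- function(binned, path_prefix) {
  stopifnot(inherits(binned, "binned_counts"))
  d <- dim(binned$counts)
  nz <- which(binned$counts != 0, arr.ind = TRUE)
  df <- data.frame(unit = nz[, 1], trial = nz[, 2], bin = nz[, 3],
                   count = binned$counts[nz])
  utils::write.csv(df, paste0(path_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_units = d[1], n_trials = d[2], n_bins = d[3],
         bin_width_s = binned$bin_width_s, areas = binned$areas),
    paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path_prefix)
}

#' @rdname save_binned_counts
#' @export
load_binned_counts <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path_prefix, ".csv"))
  need <- c("unit", "trial", "bin", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("counts CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  counts <- array(0L, c(meta$n_units, meta$n_trials, meta$n_bins))
  counts[cbind(df$unit, df$trial, df$bin)] <- as.integer(df$count)
  binned_counts(counts, meta$bin_width_s, meta$areas)
}

#' Read a spike session from CSV files
#'
#' `spikes_csv` must have columns `unit_id`, `trial`, `spike_time`;
#' `units_csv` columns `unit_id`, `area`. Units listed in `units_csv` with
#' no spikes are included as silent.
#'
#' @param spikes_csv,units_csv file paths.
#' @param duration_s stimulus duration (s).
#' @param n_trials number of trials (inferred from the spike table when
#'   `NULL`).
#' @return A [spike_session].
#' @export
read_session_csv <- function(spikes_csv, units_csv, duration_s,
                             n_trials = NULL) {
  for (p in c(spikes_csv, units_csv)) {
    if (!file.exists(p)) {
      stop("file not found: ", p,
           " (deposited recordings must be downloaded and converted to the ",
           "documented CSV layout first)", call. = FALSE)
    }
  }
  sp <- utils::read.csv(spikes_csv)
  un <- utils::read.csv(units_csv)
  for (col in c("unit_id", "trial", "spike_time")) {
    if (!col %in% names(sp)) {
      stop("spike CSV is missing column: ", col, call. = FALSE)
    }
  }
  for (col in c("unit_id", "area")) {
    if (!col %in% names(un)) {
      stop("units CSV is missing column: ", col, call. = FALSE)
    }
  }
  n_trials <- n_trials %||% max(sp$trial)
  units <- lapply(seq_len(nrow(un)), function(i) {
    uid <- un$unit_id[i]
    mine <- sp[sp$unit_id == uid, , drop = FALSE]
    spikes <- lapply(seq_len(n_trials), function(k) {
      sort(mine$spike_time[mine$trial == k])
    })
    list(unit_id = uid, area = un$area[i], spikes = spikes)
  })
  spike_session(units, duration_s)
}

#' Read / write wheel-velocity traces as CSV
#'
#' Long format with columns `trial`, `time_s`, `v_cm_s`.
#'
#' @param trace a `velocity_trace`.
#' @param path CSV path.
#' @return `write_velocity_csv`: the path, invisibly; `read_velocity_csv`:
#'   a `velocity_trace`.
#' @export
write_velocity_csv <- function(trace, path) {
  stopifnot(inherits(trace, "velocity_trace"))
  df <- data.frame(
    trial = rep(seq_len(nrow(trace$v)), each = ncol(trace$v)),
    time_s = rep(trace$times_s, nrow(trace$v)),
    v_cm_s = as.vector(t(trace$v))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_csv
#' @export
read_velocity_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial", "time_s", "v_cm_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("velocity CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  trials <- sort(unique(df$trial))
  times <- sort(unique(df$time_s))
  v <- matrix(NA_real_, length(trials), length(times))
  for (i in seq_along(trials)) {
    sub <- df[df$trial == trials[i], , drop = FALSE]
    v[i, ] <- sub$v_cm_s[order(sub$time_s)]
  }
  dt <- if (length(times) > 1) stats::median(diff(times)) else 1
  structure(
    list(v = v, dt_s = dt, duration_s = max(times) + dt, times_s = times,
         schedule = NULL),
    class = "velocity_trace"
  )
}

#' Save / load a movie as RDS with a JSON sidecar
#'
#' @param mov a [movie].
#' @param path_prefix files `<prefix>.rds` (frames) and `<prefix>.json`
#'   (`fps`) are written.
#' @return `write_movie`: the prefix, invisibly; `read_movie`: a [movie].
#' @export
write_movie <- function(mov, path_prefix) {
  stopifnot(inherits(mov, "movie"))
  saveRDS(mov$frames, paste0(path_prefix, ".rds"))
  jsonlite::write_json(list(fps = mov$fps), paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' @rdname write_movie
#' @export
read_movie <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  movie(readRDS(paste0(path_prefix, ".rds")), as.numeric(meta$fps))
}
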