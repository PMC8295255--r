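#' Regression results
#'
#' Common container for the package's regression layer. Holds the slope(s),
#' per-group intercepts, standard errors, t statistics, p values (with their
#' sidedness), degrees of freedom, a residual-normality (Jarque-Bera) p
#' value where applicable, and the method used.
#'
#' @name regression_result
#' @keywords internal
NULL

new_regression_result <- function(method, ...) {
  structure(c(list(method = method), list(...)), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result: %s>\n", x$method))
  if (!is.null(x$slope)) {
    cat(sprintf("  slope = %.4g", x$slope))
    if (!is.null(x$slope_se)) cat(sprintf(" (se %.3g)", x$slope_se))
    if (!is.null(x$slope_p)) cat(sprintf(", p = %.3g [%s]", x$slope_p,
                                         x$sidedness %||% "two-tailed"))
    cat("\n")
  }
  if (!is.null(x$intercepts)) {
    cat("  intercepts:\n")
    print(round(x$intercepts, 4))
  }
  invisible(x)
}

# Jarque-Bera normality statistic: n/6 * (S^2 + (K - 3)^2 / 4), compared to
# a chi-squared with 2 df.
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2
  stat <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = stat, p_value = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Common-slope, area-intercept linear model (ANCOVA-style OLS)
#'
#' Ordinary least squares of `y ~ x + group`: one slope shared across all
#' groups and a separate intercept per group. Two-tailed t-tests are
#' reported for the slope and for every intercept contrast against the
#' baseline group, plus a Jarque-Bera p value on the residuals.
#'
#' @param x,y numeric vectors (e.g., stimulus timescale and response
#'   timescale, in seconds).
#' @param group group labels (e.g., cortical areas); coerced to factor. The
#'   first level is the baseline for intercept contrasts.
#' @param pooling optional named character vector mapping original labels to
#'   pooled labels (e.g., `c(LM = "extrastriate", LI = "extrastriate", LL =
#'   "extrastriate")`).
#' @param baseline optional baseline level (e.g., `"V1"`).
#' @return A `regression_result` with elements `slope`, `slope_se`,
#'   `slope_t`, `slope_p`, `intercepts` (per group), `contrasts` (matrix of
#'   estimate / se / t / p for each non-baseline group vs. baseline), `dof`,
#'   `jarque_bera_p`, and the underlying `lm` fit.
#' @export
ancova_fit <- function(x, y, group, pooling = NULL, baseline = NULL) {
  group <- as.character(group)
  if (!is.null(pooling)) {
    mapped <- !is.na(match(group, names(pooling)))
    group[mapped] <- pooling[group[mapped]]
  }
  g <- factor(group)
  if (!is.null(baseline)) g <- stats::relevel(g, ref = baseline)
  dat <- data.frame(x = x, y = y, g = g)
  lev <- levels(g)
  fit <- if (length(lev) > 1) lm(y ~ x + g, data = dat) else lm(y ~ x, data = dat)
  if (anyNA(coef(fit))) stop("design matrix is rank deficient", call. = FALSE)
  sm <- summary(fit)
  ct <- sm$coefficients
  base_int <- ct["(Intercept)", "Estimate"]
  intercepts <- if (length(lev) > 1) {
    c(base_int, base_int + ct[paste0("g", lev[-1]), "Estimate"])
  } else {
    base_int
  }
  names(intercepts) <- lev
  contrasts <- NULL
  if (length(lev) > 1) {
    rows <- paste0("g", lev[-1])
    contrasts <- ct[rows, , drop = FALSE]
    rownames(contrasts) <- paste(lev[-1], "vs", lev[1])
  }
  new_regression_result(
    "ols",
    slope = ct["x", "Estimate"], slope_se = ct["x", "Std. Error"],
    slope_t = ct["x", "t value"], slope_p = ct["x", "Pr(>|t|)"],
    sidedness = "two-tailed",
    intercepts = intercepts, contrasts = contrasts,
    dof = fit$df.residual,
    jarque_bera_p = jarque_bera(stats::residuals(fit))$p_value,
    fit = fit
  )
}

#' Theil-Sen slope estimator
#'
#' Median of all pairwise slopes `(y_j - y_i) / (x_j - x_i)` over pairs with
#' distinct `x`.
#'
#' @param x,y numeric vectors.
#' @return The slope estimate.
#' @export
theil_sen <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  ij <- combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  s <- dy[dx != 0] / dx[dx != 0]
  if (!length(s)) stop("all x values are equal", call. = FALSE)
  median(s)
}

# Common Theil-Sen slope across groups: pairwise slopes are formed within
# each group only, pooled, and the pooled median taken; intercepts are
# per-group medians of y - slope * x. Fully rank-based while preserving the
# common-slope structure.
ts_common_fit <- function(x, y, g) {
  slopes <- unlist(lapply(split(seq_along(x), g), function(idx) {
    if (length(idx) < 2) return(numeric(0))
    ij <- combn(length(idx), 2)
    dx <- x[idx[ij[2, ]]] - x[idx[ij[1, ]]]
    dy <- y[idx[ij[2, ]]] - y[idx[ij[1, ]]]
    dy[dx != 0] / dx[dx != 0]
  }))
  if (!length(slopes)) stop("all x values are equal within groups",
                            call. = FALSE)
  slope <- median(slopes)
  intercepts <- vapply(split(seq_along(x), g), function(idx) {
    median(y[idx] - slope * x[idx])
  }, numeric(1))
  list(slope = slope, intercepts = intercepts)
}

#' Robust common-slope fit with stratified percentile bootstrap
#'
#' Theil-Sen common-slope fit (pairwise-slope median pooled across groups,
#' per-group median intercepts), with uncertainty from a percentile
#' bootstrap of `B` resamples stratified by group: observations are
#' resampled with replacement within each group. One-tailed p values use the
#' shift method: the bootstrap distribution of a parameter is subtracted
#' from its estimate to form a null surrogate, and the p value is the mass
#' of the surrogate at or above the estimate (equivalently, the fraction of
#' bootstrap replicates at or below zero), floored at `1 / B`.
#'
#' @param x,y numeric vectors.
#' @param group stratification labels (a single stratum when `NULL`).
#' @param B bootstrap resamples (default 10000).
#' @param seed RNG seed.
#' @param conf confidence level for the percentile intervals.
#' @return A `regression_result` with `slope`, `slope_ci`, `slope_p`,
#'   `intercepts`, `intercept_ci` (matrix), `intercept_p`,
#'   `contrast_ci` / `contrast_p` (non-baseline intercepts minus baseline),
#'   and the bootstrap draws.
#' @export
robust_fit_bootstrap <- function(x, y, group = NULL, B = 10000, seed = 1,
                                 conf = 0.95) {
  if (B < 100) warning("B < 100 gives unstable percentile intervals",
                       call. = FALSE)
  g <- factor(group %||% rep("all", length(x)))
  if (any(tapply(x, g, function(v) length(unique(v))) < 2)) {
    stop("degenerate x (all equal) within a stratum", call. = FALSE)
  }
  est <- ts_common_fit(x, y, g)
  lev <- levels(g)
  idx_by_g <- split(seq_along(x), g)
  boot_slope <- numeric(B)
  boot_int <- matrix(NA_real_, B, length(lev), dimnames = list(NULL, lev))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- unlist(lapply(idx_by_g, function(ii) {
        ii[sample.int(length(ii), replace = TRUE)]
      }))
      fb <- tryCatch(ts_common_fit(x[idx], y[idx], g[idx]),
                     error = function(e) NULL)
      if (is.null(fb)) next
      boot_slope[b] <- fb$slope
      boot_int[b, names(fb$intercepts)] <- fb$intercepts
    }
  })
  alpha <- (1 - conf) / 2
  one_tailed_p <- function(draws) {
    draws <- draws[is.finite(draws)]
    max(1 / B, mean(draws <= 0))
  }
  slope_ci <- quantile(boot_slope, c(alpha, 1 - alpha), na.rm = TRUE)
  int_ci <- t(apply(boot_int, 2, quantile, c(alpha, 1 - alpha), na.rm = TRUE))
  contrast_ci <- contrast_p <- NULL
  if (length(lev) > 1) {
    dmat <- boot_int[, lev[-1], drop = FALSE] - boot_int[, lev[1]]
    contrast_ci <- t(apply(dmat, 2, quantile, c(alpha, 1 - alpha),
                           na.rm = TRUE))
    contrast_p <- apply(dmat, 2, one_tailed_p)
    names(contrast_p) <- paste(lev[-1], "vs", lev[1])
  }
  new_regression_result(
    "theil_sen_bootstrap",
    slope = est$slope, slope_ci = slope_ci,
    slope_p = one_tailed_p(boot_slope),
    sidedness = "one-tailed (H1: parameter > 0)",
    intercepts = est$intercepts, intercept_ci = int_ci,
    intercept_p = apply(boot_int, 2, one_tailed_p),
    contrast_ci = contrast_ci, contrast_p = contrast_p,
    B = B, boot_slope = boot_slope, boot_intercepts = boot_int
  )
}

#' Categorical regression of segment-decoding timescales
#'
#' OLS of per-segment-pair timescales on area identity and task condition:
#' `tau ~ b0 + b_LM*LM + b_LI*LI + b_LL*LL + b_D*Direction + b_C*Color +
#' b_CD*Direction*Color`, where the area terms are indicators against the
#' baseline area (V1) and `Direction` / `Color` indicate whether the two
#' segments of a pair share motion direction / object color. `b_LM` is then
#' the mean timescale difference between LM and V1 controlling for
#' condition.
#'
#' @param tau_values numeric timescales (seconds).
#' @param area_labels area per observation; baseline is `"V1"` when present,
#'   otherwise the first level.
#' @param direction_flags,color_flags 0/1 (or logical) condition indicators
#'   (1 = same direction / color within the pair).
#' @return A `regression_result` with the coefficient table (`coefficients`)
#'   and per-area contrasts vs. baseline (estimate, se, t, two-tailed p).
#' @export
segment_regression <- function(tau_values, area_labels, direction_flags,
                               color_flags) {
  g <- factor(area_labels)
  if ("V1" %in% levels(g)) g <- stats::relevel(g, ref = "V1")
  d <- as.numeric(direction_flags)
  cl <- as.numeric(color_flags)
  dat <- data.frame(tau = tau_values, g = g, d = d, cl = cl)
  # constant condition columns drop out of the design: the model then
  # reduces to a one-way area contrast (possibly plus the varying factor)
  terms <- c("g",
             if (length(unique(d)) > 1) "d",
             if (length(unique(cl)) > 1) "cl",
             if (length(unique(d)) > 1 && length(unique(cl)) > 1) "d:cl")
  fit <- lm(stats::reformulate(terms, response = "tau"), data = dat)
  if (anyNA(coef(fit))) stop("collinear design (a factor level or condition cell is missing)",
                             call. = FALSE)
  ct <- summary(fit)$coefficients
  lev <- levels(g)
  rows <- paste0("g", lev[-1])
  contrasts <- ct[rows, , drop = FALSE]
  rownames(contrasts) <- paste(lev[-1], "vs", lev[1])
  new_regression_result(
    "ols",
    coefficients = ct, contrasts = contrasts,
    sidedness = "two-tailed", dof = fit$df.residual, fit = fit
  )
}

#' Regression of timescales on an anatomical hierarchy score
#'
#' OLS (or inverse-variance-weighted least squares when `weights` are given)
#' of per-area timescales on the areas' anatomical hierarchy score, with a
#' one-tailed t-test on a positive slope (the hierarchical-increase
#' hypothesis).
#'
#' @param taus per-area timescales (seconds).
#' @param hierarchy_scores anatomical scores, same order.
#' @param weights optional positive weights (typically inverse variances of
#'   the timescale estimates).
#' @return A `regression_result` with `slope`, `slope_se`, `slope_t`,
#'   `slope_p` (one-tailed, H1: slope > 0), `intercept`, `dof`.
#' @export
hierarchy_regression <- function(taus, hierarchy_scores, weights = NULL) {
  if (length(taus) < 3) stop("need at least 3 areas", call. = FALSE)
  if (!is.null(weights)) {
    if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
    fit <- lm(taus ~ hierarchy_scores, weights = weights)
    method <- "weighted_ols"
  } else {
    fit <- lm(taus ~ hierarchy_scores)
    method <- "ols"
  }
  ct <- summary(fit)$coefficients
  tval <- ct["hierarchy_scores", "t value"]
  new_regression_result(
    method,
    slope = ct["hierarchy_scores", "Estimate"],
    slope_se = ct["hierarchy_scores", "Std. Error"],
    slope_t = tval,
    slope_p = pt(tval, fit$df.residual, lower.tail = FALSE),
    sidedness = "one-tailed (H1: slope > 0)",
    intercept = ct["(Intercept)", "Estimate"],
    dof = fit$df.residual, fit = fit
  )
}
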