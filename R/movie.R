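#' Movie objects
#'
#' A movie is a 3-D grayscale intensity stack indexed `(frame, row, column)`
#' with values in `[0, 255]` and a frame rate. This is the common container
#' for natural-style synthetic stimuli, white-noise stimuli, and
#' phase-scrambled stimuli.
#'
#' @param frames numeric array `(n_frames, height, width)`, finite, in
#'   `[0, 255]`.
#' @param fps frames per second (> 0).
#' @return An object of class `movie`: a list with elements `frames`, `fps`
#'   and `duration_s = n_frames / fps`.
#' @export
movie <- function(frames, fps) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array (frame, row, column)", call. = FALSE)
  }
  if (dim(frames)[1] < 2L) stop("a movie needs at least 2 frames", call. = FALSE)
  if (!all(is.finite(frames))) stop("frame intensities must be finite", call. = FALSE)
  if (min(frames) < 0 || max(frames) > 255) {
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  structure(
    list(frames = frames, fps = fps, duration_s = dim(frames)[1] / fps),
    class = "movie"
  )
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<movie> %d frames of %d x %d px at %g fps (%.2f s)\n",
    d[1], d[2], d[3], x$fps, x$duration_s
  ))
  invisible(x)
}

n_frames <- function(m) dim(m$frames)[1]

# Row-normalized Gaussian smoothing matrix along one spatial axis.
gauss_smoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma^2))
  k / rowSums(k)
}

#' Generate a movie with a controllable temporal correlation timescale
#'
#' Each pixel follows a stationary first-order autoregressive process with
#' lag-one coefficient `rho = exp(-(1/fps) / target_timescale_s)`, so the
#' expected pixel correlation at lag `Delta` frames is `rho^Delta`, i.e. an
#' exponential decay with time constant `target_timescale_s`. Innovations are
#' smoothed with an isotropic Gaussian kernel across space (the temporal
#' correlation target is unaffected), and the full stack is rescaled linearly
#' to `[0, 255]`.
#'
#' @param n_frames,height,width stack dimensions (all >= 2).
#' @param fps frames per second.
#' @param target_timescale_s temporal correlation time constant in seconds;
#'   `0` yields mutually independent frames.
#' @param spatial_corr_len Gaussian smoothing length of the innovations, in
#'   pixels (0 disables smoothing).
#' @param seed RNG seed; equal seeds give bit-identical movies.
#' @return A [movie] with an attribute `truth` recording the generating
#'   parameters.
#' @export
gen_ar_movie <- function(n_frames, fps, height, width, target_timescale_s,
                         spatial_corr_len = 2, seed = 1) {
  stopifnot(n_frames >= 2, height >= 2, width >= 2, fps > 0)
  if (!is.finite(target_timescale_s) || target_timescale_s < 0) {
    stop("`target_timescale_s` must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(spatial_corr_len) || spatial_corr_len < 0) {
    stop("`spatial_corr_len` must be finite and >= 0", call. = FALSE)
  }
  rho <- if (target_timescale_s == 0) 0 else exp(-(1 / fps) / target_timescale_s)
  sh <- gauss_smoother(height, spatial_corr_len)
  sw <- gauss_smoother(width, spatial_corr_len)
  x <- array(0, c(n_frames, height, width))
  with_seed(seed, {
    innov <- function() sh %*% matrix(rnorm(height * width), height, width) %*% t(sw)
    x[1, , ] <- innov()
    scale_new <- sqrt(1 - rho^2)
    for (t in 2:n_frames) {
      x[t, , ] <- rho * x[t - 1, , ] + scale_new * innov()
    }
  })
  rng <- range(x)
  frames <- (x - rng[1]) / (rng[2] - rng[1]) * 255
  out <- movie(frames, fps)
  attr(out, "truth") <- list(
    target_timescale_s = target_timescale_s, rho = rho, seed = seed
  )
  out
}

#' Generate the binary white-noise movie stimulus
#'
#' Every pixel of every frame is set independently to black (0) or white
#' (255) with equal probability. Defaults reproduce the standard construction
#' used with this pipeline: 45 x 80 pixels shown at 20 fps for 20 s.
#'
#' @param seed RNG seed.
#' @param n_frames,fps,height,width stack geometry.
#' @return A [movie].
#' @export
gen_white_noise_movie <- function(seed = 1, n_frames = 400, fps = 20,
                                  height = 45, width = 80) {
  frames <- with_seed(seed, {
    array(255 * rbinom(n_frames * height * width, 1, 0.5),
          c(n_frames, height, width))
  })
  movie(frames, fps)
}

# 0-based index grids of the 3-D DFT and the linear index of each bin's
# Hermitian mirror (-k mod n along every axis).
fft_mirror_index <- function(d) {
  g <- expand.grid(k1 = 0:(d[1] - 1), k2 = 0:(d[2] - 1), k3 = 0:(d[3] - 1))
  m1 <- (d[1] - g$k1) %% d[1]
  m2 <- (d[2] - g$k2) %% d[2]
  m3 <- (d[3] - g$k3) %% d[3]
  1 + m1 + d[1] * (m2 + d[2] * m3)
}

#' Phase-scramble a movie
#'
#' Computes the 3-D spatiotemporal discrete Fourier transform of the
#' standardized frame stack, permutes the phase spectrum while preserving
#' Hermitian (conjugate) symmetry, merges the shuffled phases with the
#' unaltered amplitude spectrum, and inverse-transforms. The (numerically
#' zero) imaginary parts are discarded, the original mean and standard
#' deviation are restored, and values are clipped to `[0, 255]`. Bins that
#' are their own conjugate mirror (DC and Nyquist combinations) keep their
#' original (real) phase. The amplitude spectrum -- hence all second-order
#' spatiotemporal statistics -- is preserved exactly up to clipping.
#'
#' @param mov a [movie].
#' @param seed RNG seed for the phase permutation.
#' @param perm optional explicit permutation of the free (half-spectrum)
#'   phase bins, overriding the seeded draw; the identity permutation
#'   reconstructs the input.
#' @param clip if `FALSE`, the restored (but unclipped) frames are returned
#'   in a plain list, which may leave `[0, 255]`; used for spectral checks.
#' @return A [movie] (or, with `clip = FALSE`, a list with elements `frames`
#'   and `fps`).
#' @export
phase_scramble <- function(mov, seed = 1, perm = NULL, clip = TRUE) {
  stopifnot(inherits(mov, "movie"))
  x <- mov$frames
  mu <- mean(x)
  sig <- sqrt(mean((x - mu)^2))
  if (sig == 0) stop("cannot phase-scramble a constant movie", call. = FALSE)
  z <- (x - mu) / sig
  fz <- fft(z)
  amp <- Mod(fz)
  ph <- Arg(fz)
  d <- dim(z)
  mirror <- fft_mirror_index(d)
  idx <- seq_along(mirror)
  free <- which(idx < mirror)           # one representative per conjugate pair
  if (is.null(perm)) {
    perm <- with_seed(seed, sample(length(free)))
  }
  if (length(perm) != length(free) || !setequal(perm, seq_along(free))) {
    stop("`perm` must be a permutation of the ", length(free),
         " half-spectrum bins", call. = FALSE)
  }
  ph2 <- ph
  ph2[free] <- ph[free][perm]
  ph2[mirror[free]] <- -ph2[free]       # conjugate symmetry
  f2 <- array(complex(modulus = amp, argument = ph2), d)
  y <- Re(fft(f2, inverse = TRUE)) / prod(d)   # imaginary parts discarded
  ysig <- sqrt(mean((y - mean(y))^2))
  out <- (y - mean(y)) / ysig * sig + mu       # restore mean and sd
  if (!clip) {
    return(list(frames = out, fps = mov$fps))
  }
  movie(pmin(pmax(out, 0), 255), mov$fps)
}

#' Simulate linear-filter responses to a movie
#'
#' Models each unit as a linear spatiotemporal filter: a Gaussian spatial
#' receptive field weighting the movie frames, followed by causal convolution
#' with an exponential temporal kernel `exp(-t / tau)` normalized to unit
#' area. The truncated kernel is renormalized during the initial transient,
#' so a constant movie gives a constant response at every frame, and
#' `tau = 0` reduces to the spatially weighted movie signal itself.
#'
#' @param mov a [movie].
#' @param rf_centers numeric matrix `(n_units, 2)` of (row, column) RF
#'   centers in pixel coordinates.
#' @param rf_widths Gaussian RF standard deviations, in pixels (recycled).
#' @param temporal_taus exponential kernel time constants in seconds, one per
#'   unit; must be `>= 0`.
#' @return Numeric matrix `(n_units, n_frames)` of rate-like responses.
#' @export
simulate_linear_responses <- function(mov, rf_centers, rf_widths, temporal_taus) {
  stopifnot(inherits(mov, "movie"))
  rf_centers <- as.matrix(rf_centers)
  n_units <- nrow(rf_centers)
  rf_widths <- rep_len(rf_widths, n_units)
  if (length(temporal_taus) != n_units) {
    stop("one temporal tau per unit is required", call. = FALSE)
  }
  if (any(!is.finite(temporal_taus)) || any(temporal_taus < 0)) {
    stop("temporal taus must be finite and >= 0", call. = FALSE)
  }
  d <- dim(mov$frames)
  nt <- d[1]; h <- d[2]; w <- d[3]
  dt <- 1 / mov$fps
  flat <- matrix(mov$frames, nrow = nt)   # frames x (h*w), column-major (row fast)
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  out <- matrix(0, n_units, nt)
  for (u in seq_len(n_units)) {
    wts <- exp(-((rr - rf_centers[u, 1])^2 + (cc - rf_centers[u, 2])^2) /
                 (2 * rf_widths[u]^2))
    wts <- wts / sum(wts)
    sig <- as.numeric(flat %*% wts)
    tau <- temporal_taus[u]
    if (tau == 0) {
      out[u, ] <- sig
      next
    }
    klen <- min(nt, ceiling(8 * tau / dt) + 1L)
    kern <- exp(-(seq_len(klen) - 1) * dt / tau)
    kern <- kern / sum(kern)
    full <- stats::filter(sig, kern, method = "convolution", sides = 1)
    resp <- as.numeric(full)
    for (t in seq_len(min(klen - 1L, nt))) {   # transient: renormalized kernel
      kt <- kern[seq_len(t)]
      resp[t] <- sum(kt * sig[t:1]) / sum(kt)
    }
    out[u, ] <- resp
  }
  out
}
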