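#' Configuration for the bounded smoothed random walk
#'
#' The semi-parametric generator used for both the broad spectral baseline and
#' the irregular residual-water region. The two built-in profiles differ
#' mainly in smoothing window and ppm span: `"baseline"` uses a wide uniform
#' kernel (window 0.15 of the length) over 0.2–4.2 ppm, producing broad smooth
#' curves; `"residual_water"` uses a narrow kernel (0.02) over 4.2–5.1 ppm,
#' producing highly irregular curves. Scales are relative to the spectrum
#' maximum (see [scale_nuisance()]).
#'
#' @param profile `"baseline"` or `"residual_water"`; presets the defaults.
#' @param start,end Curve endpoint values at the edges of `ppm_span`.
#' @param std Step-noise standard deviation of the underlying walk.
#' @param lower_bound,upper_bound Bounds of the walk (`lower < upper`).
#' @param length Number of samples the walk is generated on (>= 8).
#' @param window_size Uniform smoothing kernel size as a fraction of `length`
#'   (0 < window_size <= 1).
#' @param ppm_span Length-2 ppm interval the curve covers.
#' @param scale Output magnitude relative to the spectrum's maximum.
#' @return An object of class `walk_config`.
#' @export
walk_config <- function(profile = c("baseline", "residual_water"),
                        start = 0, end = 0, std = 1,
                        lower_bound = -1, upper_bound = 1,
                        length = 256L,
                        window_size = NULL, ppm_span = NULL, scale = NULL) {
  profile <- match.arg(profile)
  if (is.null(window_size)) window_size <- if (profile == "baseline") 0.15 else 0.02
  if (is.null(ppm_span)) ppm_span <- if (profile == "baseline") c(0.2, 4.2) else c(4.2, 5.1)
  if (is.null(scale)) scale <- if (profile == "baseline") 0.25 else 1.0
  if (!(lower_bound < upper_bound)) stop("`lower_bound` must be < `upper_bound`")
  if (!(window_size > 0 && window_size <= 1)) stop("`window_size` must be in (0, 1]")
  if (length < 8) stop("`length` must be >= 8")
  check_number(std, "std", nonneg = TRUE)
  check_number(start, "start"); check_number(end, "end")
  if (length(ppm_span) != 2L || ppm_span[1] >= ppm_span[2]) {
    stop("`ppm_span` must be an increasing length-2 ppm interval")
  }
  structure(list(profile = profile, start = start, end = end, std = std,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 length = as.integer(length), window_size = window_size,
                 ppm_span = ppm_span, scale = scale),
            class = "walk_config")
}

# Uniform moving average with reflected edges; a convex combination, so any
# pointwise bounds on the input survive smoothing.
smooth_uniform <- function(x, k) {
  k <- as.integer(max(1L, k))
  if (k == 1L) return(x)
  n <- length(x)
  k <- min(k, n)
  pad <- c(rev(x[seq_len(k)]), x, rev(x[(n - k + 1L):n]))
  sm <- stats::filter(pad, rep(1 / k, k), sides = 2)
  as.numeric(sm[(k + 1L):(k + n)])
}

#' Smoothed bounded pseudo-random walk
#'
#' The nuisance-curve generator: a cumulative-sum Gaussian walk is detrended
#' against the straight line through its own endpoints, the fluctuations are
#' rescaled so their range equals `upper_bound - lower_bound`, clipped to half
#' that range about the trend, added to the straight trend line running from
#' `start` to `end`, clipped to the bounds, and finally smoothed with a
#' uniform kernel of `round(window_size * length)` samples (reflected edges).
#' With `std = 0` the output is the pure trend line. Identical configuration
#' and seed give bit-identical curves.
#'
#' @param cfg A [walk_config()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `cfg$length` samples, all within
#'   `[lower_bound, upper_bound]`.
#' @export
bounded_smoothed_walk <- function(cfg, seed = NULL) {
  if (!inherits(cfg, "walk_config")) stop("`cfg` must be a walk_config")
  n <- cfg$length
  bounds <- cfg$upper_bound - cfg$lower_bound
  walk <- with_seed(seed, cumsum(stats::rnorm(n, 0, cfg$std)))
  own_trend <- seq(walk[1], walk[n], length.out = n)
  deltas <- walk - own_trend
  rng <- max(deltas) - min(deltas)
  if (rng > 0) deltas <- deltas * (bounds / rng) else deltas <- numeric(n)
  deltas <- pmin(pmax(deltas, -bounds / 2), bounds / 2)
  trend <- seq(cfg$start, cfg$end, length.out = n)
  out <- trend + deltas
  out <- pmin(pmax(out, cfg$lower_bound), cfg$upper_bound)
  smooth_uniform(out, round(cfg$window_size * n))
}

# Discrete quadrature (Hilbert) partner of a real curve: every positive-
# frequency component of its conjugate-domain representation is rotated by a
# quarter cycle. Applying it twice negates the curve (up to DC/Nyquist).
quadrature_partner <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  sgn <- numeric(n)
  if (n %% 2 == 0) {
    if (n > 2) sgn[2:(n / 2)] <- 1
    if (n > 2) sgn[(n / 2 + 2):n] <- -1
  } else {
    sgn[2:((n + 1) / 2)] <- 1
    sgn[((n + 1) / 2 + 1):n] <- -1
  }
  Re(stats::fft(-1i * sgn * X, inverse = TRUE)) / n
}

#' Complete a real nuisance curve to a complex one
#'
#' Synthesises the imaginary channel of a nuisance curve as the quadrature
#' partner of the real channel — the conjugate-domain representation receives
#' a 90-degree phase rotation and is transformed back. For a Lorentzian
#' absorption input the imaginary channel is the matching dispersion curve.
#'
#' @param real_curve Real-valued curve on the spectral axis.
#' @return Complex curve; `Re` equals the input.
#' @export
make_complex_nuisance <- function(real_curve) {
  if (!all(is.finite(real_curve))) stop("`real_curve` must be finite")
  complex(real = real_curve, imaginary = quadrature_partner(real_curve))
}

#' Resample a nuisance curve onto the acquisition ppm axis
#'
#' The curve, defined on its own uniform axis over `ppm_span`, is interpolated
#' (modified Akima) onto the target ppm axis and set to zero outside its span.
#'
#' @param curve Numeric or complex curve.
#' @param ppm_span Length-2 ppm interval the curve covers.
#' @param target_ppm Target ppm axis (ascending).
#' @return Curve sampled on `target_ppm`.
#' @export
resample_to_grid <- function(curve, ppm_span, target_ppm) {
  if (ppm_span[1] > max(target_ppm) || ppm_span[2] < min(target_ppm)) {
    stop("curve span [", ppm_span[1], ", ", ppm_span[2],
         "] ppm does not overlap the target axis")
  }
  x <- seq(ppm_span[1], ppm_span[2], length.out = length(curve))
  interp_makima(x, curve, target_ppm)
}

#' Scale a nuisance curve relative to the spectrum
#'
#' Rescales so that `max(Mod(curve)) == scale * spectrum_max`, matching the
#' curve's order of magnitude to the spectra and letting `scale` modulate its
#' impact. `scale = 0` returns a zero curve.
#'
#' @param curve Numeric or complex curve.
#' @param spectrum_max Maximum of the reference spectrum (> 0).
#' @param scale Relative magnitude (>= 0).
#' @return The rescaled curve.
#' @export
scale_nuisance <- function(curve, spectrum_max, scale) {
  check_number(spectrum_max, "spectrum_max", positive = TRUE)
  check_number(scale, "scale", nonneg = TRUE)
  if (scale == 0) return(curve * 0)
  m <- max(Mod(curve))
  if (m == 0) stop("cannot scale an all-zero curve to a nonzero magnitude")
  curve * (scale * spectrum_max / m)
}

#' Simulate a nuisance curve on an acquisition grid
#'
#' Convenience wrapper: runs the bounded smoothed walk, completes it to a
#' complex curve, resamples it onto the grid's ppm axis (zero outside the
#' profile's span) and scales it relative to the spectrum maximum. The
#' returned curve is the pre-artifact ground-truth nuisance component.
#'
#' @param cfg A [walk_config()].
#' @param grid An acquisition grid.
#' @param spectrum_max Reference spectrum maximum (> 0).
#' @param seed Optional integer seed.
#' @return Complex curve of length `grid$n_points` on the spectral axis.
#' @export
simulate_nuisance <- function(cfg, grid, spectrum_max, seed = NULL) {
  walk <- bounded_smoothed_walk(cfg, seed)
  cplx <- make_complex_nuisance(walk)
  on_grid <- resample_to_grid(cplx, cfg$ppm_span, grid$ppm)
  if (max(Mod(on_grid)) == 0) return(on_grid)
  scale_nuisance(on_grid, spectrum_max, cfg$scale)
}
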