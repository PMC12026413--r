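#' Multi-coil / multi-average transient configuration
#'
#' One operator covers both phased-array coil elements and repeated signal
#' averages: per-transient coil sensitivities (clamped Gaussian, default
#' Normal(1.0, 0.5) clamped to \[0, 2\]), per-transient SNR targets centred on
#' `snr0 / sqrt(C)` with a narrow multiplicative spread, and independent
#' frequency and zero-order phase drifts. An optional C x C correlation matrix
#' induces inter-coil noise correlation.
#'
#' @param n_transients Number of transients C (>= 1).
#' @param sens_mu,sens_sd Mean and SD of the sensitivity sampler.
#' @param sens_clamp Length-2 clamp interval for sensitivities.
#' @param snr_spread Relative SD of the per-transient SNR factors (the
#'   "narrow normal"; default 0.05).
#' @param drift_freq_range Frequency-drift half-range, Hz (uniform in +/-).
#' @param drift_phase_range Phase-drift half-range, degrees (uniform in +/-).
#' @param noise_correlation Optional symmetric positive-semidefinite C x C
#'   matrix with unit diagonal.
#' @return An object of class `coil_config`.
#' @export
coil_config <- function(n_transients, sens_mu = 1.0, sens_sd = 0.5,
                        sens_clamp = c(0, 2), snr_spread = 0.05,
                        drift_freq_range = 5, drift_phase_range = 20,
                        noise_correlation = NULL) {
  if (!is.numeric(n_transients) || n_transients < 1 ||
      n_transients != round(n_transients)) {
    stop("`n_transients` must be an integer >= 1")
  }
  if (length(sens_clamp) != 2L || sens_clamp[1] >= sens_clamp[2]) {
    stop("`sens_clamp` must be an increasing length-2 interval")
  }
  check_number(snr_spread, "snr_spread", nonneg = TRUE)
  check_number(drift_freq_range, "drift_freq_range", nonneg = TRUE)
  check_number(drift_phase_range, "drift_phase_range", nonneg = TRUE)
  C <- as.integer(n_transients)
  if (!is.null(noise_correlation)) {
    m <- noise_correlation
    if (!is.matrix(m) || any(dim(m) != C) || !isSymmetric(m) ||
        any(abs(diag(m) - 1) > 1e-12)) {
      stop("`noise_correlation` must be a symmetric ", C, "x", C,
           " matrix with unit diagonal")
    }
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      stop("`noise_correlation` must be positive semidefinite")
    }
  }
  structure(list(n_transients = C, sens_mu = sens_mu, sens_sd = sens_sd,
                 sens_clamp = sens_clamp, snr_spread = snr_spread,
                 drift_freq_range = drift_freq_range,
                 drift_phase_range = drift_phase_range,
                 noise_correlation = noise_correlation),
            class = "coil_config")
}

#' Sample coil sensitivities
#'
#' Draws C scale factors from Normal(`sens_mu`, `sens_sd`) and clamps them to
#' `sens_clamp`. With the defaults (Normal(1, 0.5) clamped to \[0, 2\]) the
#' clamp is symmetric about the mean, so the sample mean stays at 1.0.
#'
#' @param cfg A [coil_config()].
#' @param seed Optional integer seed.
#' @param n Number of draws; defaults to `cfg$n_transients`.
#' @return Numeric vector of sensitivities.
#' @export
sample_sensitivities <- function(cfg, seed = NULL, n = cfg$n_transients) {
  with_seed(seed, {
    s <- stats::rnorm(n, cfg$sens_mu, cfg$sens_sd)
    pmin(pmax(s, cfg$sens_clamp[1]), cfg$sens_clamp[2])
  })
}

#' Sample per-transient SNR targets
#'
#' The target linear SNR is scaled by the number of transients — each
#' transient aims at `snr0 / sqrt(C)` so that averaging the C transients
#' recovers `snr0` — and then multiplied by factors drawn from a narrow
#' Normal(1, `snr_spread`) clamped positive, which preserves the mean target.
#'
#' @param snr0 Combined-spectrum target linear SNR (> 0).
#' @param cfg A [coil_config()].
#' @param seed Optional integer seed.
#' @return Numeric vector of C per-transient linear SNRs.
#' @export
sample_transient_snrs <- function(snr0, cfg, seed = NULL) {
  check_number(snr0, "snr0", positive = TRUE, allow_inf = TRUE)
  base <- snr0 / sqrt(cfg$n_transients)
  with_seed(seed, {
    f <- stats::rnorm(cfg$n_transients, 1, cfg$snr_spread)
    base * pmax(f, .Machine$double.eps)
  })
}

#' Synthesise multi-coil / multi-average transients
#'
#' Applies the coil operator to a noiseless FID: each transient is the clean
#' FID scaled by its sensitivity, shifted by its frequency drift, rotated by
#' its phase drift, plus complex Gaussian noise scaled to that transient's
#' SNR target (`sigma_c = sens_c * ref_height / snr_c`, so the measured
#' per-transient SNR matches the target irrespective of the sensitivity).
#' Noise is deferred to this stage: pass a noiseless FID. Every random draw is
#' recorded with its seed so each transient can be rebuilt exactly with
#' [apply_transient_params()].
#'
#' @param clean_fid Noiseless complex FID.
#' @param cfg A [coil_config()].
#' @param snr0 Combined-spectrum target SNR.
#' @param ref_height Reference spectral peak height of the clean FID.
#' @param t Time axis, seconds (length of `clean_fid`).
#' @param seed Integer seed governing all draws.
#' @return An object of class `transient_set`: `fids` (n_points x C complex
#'   matrix), `ground_truth` (data.frame: sensitivity, snr, dfreq_hz,
#'   dphase_deg, noise_seed) and `sigma` per transient.
#' @export
make_transients <- function(clean_fid, cfg, snr0, ref_height, t, seed = NULL) {
  if (!inherits(cfg, "coil_config")) stop("`cfg` must be a coil_config")
  if (length(clean_fid) != length(t)) {
    stop("clean_fid length (", length(clean_fid),
         ") != time axis length (", length(t), ")")
  }
  check_number(ref_height, "ref_height", positive = TRUE)
  C <- cfg$n_transients
  n <- length(clean_fid)
  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^31 - 2))
  sens <- sample_sensitivities(cfg, sub_seed(seed, 1L))
  snrs <- sample_transient_snrs(snr0, cfg, sub_seed(seed, 2L))
  drifts <- with_seed(sub_seed(seed, 3L), list(
    dfreq = stats::runif(C, -cfg$drift_freq_range, cfg$drift_freq_range),
    dphase = stats::runif(C, -cfg$drift_phase_range, cfg$drift_phase_range)
  ))
  noise_seeds <- vapply(seq_len(C), function(c) sub_seed(seed, 100L + c), integer(1))
  sigma <- sens * ref_height / snrs
  s_t <- noise_sd_time(sigma, n)

  fids <- matrix(complex(real = 0), nrow = n, ncol = C)
  if (is.null(cfg$noise_correlation)) {
    for (c in seq_len(C)) {
      clean_c <- sens[c] * clean_fid
      clean_c <- apply_freq_shift(clean_c, drifts$dfreq[c], t)
      clean_c <- apply_phase0(clean_c, drifts$dphase[c])
      noise <- with_seed(noise_seeds[c],
                         complex(real = stats::rnorm(n, 0, s_t[c]),
                                 imaginary = stats::rnorm(n, 0, s_t[c])))
      fids[, c] <- clean_c + noise
    }
  } else {
    # correlated inter-coil noise: one unit-variance draw per coil, mixed by
    # the Cholesky factor of the requested correlation, then scaled per coil
    U <- chol(cfg$noise_correlation)
    zr <- with_seed(sub_seed(seed, 4L),
                    matrix(stats::rnorm(C * n), nrow = C))
    zi <- with_seed(sub_seed(seed, 5L),
                    matrix(stats::rnorm(C * n), nrow = C))
    nr <- t(U) %*% zr
    ni <- t(U) %*% zi
    for (c in seq_len(C)) {
      clean_c <- sens[c] * clean_fid
      clean_c <- apply_freq_shift(clean_c, drifts$dfreq[c], t)
      clean_c <- apply_phase0(clean_c, drifts$dphase[c])
      fids[, c] <- clean_c + complex(real = s_t[c] * nr[c, ],
                                     imaginary = s_t[c] * ni[c, ])
    }
  }
  structure(list(
    fids = fids,
    ground_truth = data.frame(sensitivity = sens, snr = snrs,
                              dfreq_hz = drifts$dfreq,
                              dphase_deg = drifts$dphase,
                              noise_seed = noise_seeds),
    sigma = sigma, seed = as.integer(seed), correlated = !is.null(cfg$noise_correlation)
  ), class = "transient_set")
}

#' Rebuild one transient from its stored ground truth
#'
#' Re-applies a transient's recorded sensitivity, drifts and seeded noise to
#' the clean FID; reproduces the stored transient bit-exactly for
#' uncorrelated noise.
#'
#' @param clean_fid Noiseless complex FID.
#' @param record One row of a `transient_set$ground_truth` data.frame.
#' @param ref_height Reference spectral peak height used at synthesis time.
#' @param t Time axis, seconds.
#' @return Complex FID of the rebuilt transient.
#' @export
apply_transient_params <- function(clean_fid, record, ref_height, t) {
  n <- length(clean_fid)
  clean_c <- record$sensitivity * clean_fid
  clean_c <- apply_freq_shift(clean_c, record$dfreq_hz, t)
  clean_c <- apply_phase0(clean_c, record$dphase_deg)
  s_t <- noise_sd_time(record$sensitivity * ref_height / record$snr, n)
  noise <- with_seed(record$noise_seed,
                     complex(real = stats::rnorm(n, 0, s_t),
                             imaginary = stats::rnorm(n, 0, s_t)))
  clean_c + noise
}

#' Combine transients into a spectrum-level FID
#'
#' Weighted recombination. `"average"` computes `sum(w_c * x_c) / sum(w_c)`;
#' `"sum"` normalises the weights by their sum first — by construction both
#' modes give the identical result, the sum mode existing for protocol
#' fidelity with acquisition schemes that sum rather than average.
#'
#' @param set A `transient_set` (or a complex matrix n_points x C).
#' @param weights Non-negative weights, length C, not all zero; default equal.
#' @param mode `"average"` or `"sum"`.
#' @return Complex FID.
#' @export
combine_transients <- function(set, weights = NULL, mode = c("average", "sum")) {
  mode <- match.arg(mode)
  fids <- if (inherits(set, "transient_set")) set$fids else set
  C <- ncol(fids)
  if (is.null(weights)) weights <- rep(1, C)
  if (length(weights) != C) stop("need ", C, " weights, got ", length(weights))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) == 0) stop("weights must not all be zero")
  w <- weights / sum(weights)
  as.complex(fids %*% w)
}
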