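#' Zero-order phase
#'
#' Global time-domain rotation `fid * exp(-1i * phi0 * pi/180)`. 180 degrees
#' negates the signal; phases compose additively and 360 degrees is the
#' identity.
#'
#' @param fid Complex FID.
#' @param phi0 Zero-order phase, degrees.
#' @return The phased FID.
#' @export
apply_phase0 <- function(fid, phi0) {
  check_number(phi0, "phi0")
  fid * exp(-1i * phi0 * pi / 180)
}

#' First-order (linear) phase
#'
#' Frequency-domain rotation `F * exp(-1i * phi1 * (ppm - ppm_ref) * pi/180)`,
#' emanating from the reference point (water, 4.65 ppm by default elsewhere):
#' the sample at `ppm_ref` is left exactly unchanged and the applied phase at
#' `ppm_ref + 1` is exactly `phi1` degrees.
#'
#' @param spectrum Complex spectrum.
#' @param phi1 First-order phase, degrees per ppm.
#' @param ppm_axis ppm axis matching `spectrum`.
#' @param ppm_ref Pivot, ppm.
#' @return The phased spectrum.
#' @export
apply_phase1 <- function(spectrum, phi1, ppm_axis, ppm_ref) {
  check_number(phi1, "phi1")
  if (length(spectrum) != length(ppm_axis)) {
    stop("spectrum length (", length(spectrum), ") != ppm axis length (",
         length(ppm_axis), ")")
  }
  spectrum * exp(-1i * phi1 * (ppm_axis - ppm_ref) * pi / 180)
}

#' First-order eddy-current artifact
#'
#' Time-varying phase distortion from switched gradients, the two-parameter
#' model `fid * exp(-1i * phi(t))` with `phi(t) = 2*pi * A0 * t * exp(-t/tc0)`
#' radians. A time constant much longer than the acquisition reduces to a
#' global frequency shift of `A0` Hz; short time constants produce transient
#' lineshape distortion.
#'
#' @param fid Complex FID.
#' @param A0 Eddy-current amplitude, Hz.
#' @param tc0 Time constant, seconds (> 0 when `A0 != 0`).
#' @param t Time axis, seconds.
#' @return The distorted FID.
#' @export
apply_eddy <- function(fid, A0, tc0, t) {
  check_number(A0, "A0")
  if (A0 != 0) check_number(tc0, "tc0", positive = TRUE)
  if (A0 == 0) return(fid)
  fid * exp(-1i * 2 * pi * A0 * t * exp(-t / tc0))
}

# Time-domain per-channel noise SD that yields a frequency-domain real-channel
# SD of sigma_f under the package's unnormalised spectral transform:
# each spectral bin sums n independent rotated noise samples, so the spectral
# real-channel variance is n * s_t^2.
noise_sd_time <- function(sigma_f, n) sigma_f / sqrt(n)

#' Add SNR-defined complex Gaussian noise
#'
#' The noise level is defined spectrally: `sigma = ref_height / snr0` is the
#' standard deviation of the real channel of the spectrum in a signal-free
#' region. Noise is drawn in the time domain (independent real/imaginary
#' channels by default) with its variance scaled so the spectral real-channel
#' SD equals `sigma` under the package's transform convention. The correlated
#' mode draws a single real vector and synthesises the imaginary channel as
#' its quadrature (90-degree-rotated) partner.
#'
#' @param fid Complex FID.
#' @param snr0 Target linear SNR (> 0); `Inf` disables noise.
#' @param ref_height Reference spectral amplitude (maximum real peak height of
#'   the noiseless metabolite spectrum, or of a metabolite of choice).
#' @param seed Optional integer seed (bit-reproducible draws); `NULL` uses the
#'   current RNG stream.
#' @param correlated Logical; correlated real/imaginary channels.
#' @return List with `fid` (noisy FID) and `sigma` (spectral real-channel SD).
#' @export
add_noise <- function(fid, snr0, ref_height, seed = NULL, correlated = FALSE) {
  check_number(snr0, "snr0", positive = TRUE, allow_inf = TRUE)
  if (is.infinite(snr0)) return(list(fid = fid, sigma = 0))
  check_number(ref_height, "ref_height", positive = TRUE)
  n <- length(fid)
  sigma <- ref_height / snr0
  s_t <- noise_sd_time(sigma, n)
  noise <- with_seed(seed, {
    if (correlated) {
      re <- stats::rnorm(n, 0, s_t)
      complex(real = re, imaginary = quadrature_partner(re))
    } else {
      complex(real = stats::rnorm(n, 0, s_t),
              imaginary = stats::rnorm(n, 0, s_t))
    }
  })
  list(fid = fid + noise, sigma = sigma)
}

#' Measure spectral SNR
#'
#' Maximum peak height of the real spectral channel divided by one standard
#' deviation of the real channel over a signal-free noise region. The default
#' noise region is the highest-ppm 10% of the axis, which the toy bases leave
#' signal-free; override it for other layouts.
#'
#' @param spectrum Complex spectrum (or an `mrs_spectrum` object).
#' @param ppm ppm axis (taken from the object if a spectrum object is given).
#' @param noise_region Length-2 ppm interval containing no signal; `NULL` for
#'   the default region.
#' @return Linear SNR; `Inf` for a noiseless spectrum.
#' @export
measure_snr <- function(spectrum, ppm = NULL, noise_region = NULL) {
  if (inherits(spectrum, "mrs_spectrum")) {
    ppm <- spectrum$ppm
    spectrum <- spectrum$values
  }
  if (is.null(ppm) || length(ppm) != length(spectrum)) {
    stop("a ppm axis matching the spectrum is required")
  }
  if (is.null(noise_region)) {
    span <- max(ppm) - min(ppm)
    noise_region <- c(max(ppm) - 0.1 * span, max(ppm))
  }
  idx <- ppm >= min(noise_region) & ppm <= max(noise_region)
  if (!any(idx)) stop("noise region [", min(noise_region), ", ",
                      max(noise_region), "] ppm contains no spectral points")
  s <- stats::sd(Re(spectrum[idx]))
  if (s == 0) return(Inf)
  max(Re(spectrum)) / s
}
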