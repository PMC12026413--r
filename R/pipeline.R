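#' Simulate one spectrum from a ground-truth parameter record
#'
#' Executes the forward model in acquisition order: each basis function is
#' amplitude-scaled, Voigt-broadened and modulated by the sub-voxel B0 field,
#' per-function frequency shifts are applied and the functions are summed;
#' the global metabolite shift is applied to the sum; baseline and residual
#' water are generated on the spectral axis, completed to complex curves,
#' carried into the time domain and added (with the nuisance-group global
#' shift); noise is added at the spectrum's target SNR; then zero-order
#' phase, first-order phase and the eddy-current term are applied. When the
#' transient stage is enabled, noise is deferred to it and the coil operator
#' synthesises the transients from the artifact-complete clean FID.
#'
#' All randomness comes from the seeds stored in the record, so the same
#' record always reproduces the identical output, bit for bit.
#'
#' @param sample A `parameter_sample` from [sample_parameters()].
#' @param basis An `mrs_basis`.
#' @return An object of class `sim_result`: `fid` (combined, artifact-laden),
#'   `transients` (`transient_set` or `NULL`), and `ground_truth` (noiseless
#'   metabolite-only FID, pre-artifact baseline and residual-water curves on
#'   the spectral axis, the reference peak height, and the noise sigma).
#' @export
simulate_spectrum <- function(sample, basis) {
  if (!inherits(basis, "mrs_basis")) stop("`basis` must be an mrs_basis")
  missing <- setdiff(basis$names, names(sample$amplitudes))
  if (length(missing)) {
    stop("parameter record does not cover basis function(s): ",
         paste(missing, collapse = ", "))
  }
  grid <- basis$grid
  t <- grid$t

  modulator <- NULL
  if (!is.null(sample$b0)) {
    pars <- b0_params(dx = sample$b0$dx, dy = sample$b0$dy, dz = sample$b0$dz,
                      mu = sample$b0$mu, grid_shape = sample$b0$grid_shape)
    modulator <- b0_modulator(simulate_field_map(pars), t)
  }

  mp <- metab_params(
    amplitudes = sample$amplitudes, d = sample$d,
    g_metab = sample$g_metab, g_mm = sample$g_mm,
    freq_shift = sample$freq_shift,
    global_shift_metab = sample$global_shift_metab,
    global_shift_nuisance = sample$global_shift_nuisance
  )
  metab_fid <- scale_and_sum(basis, mp, modulator)
  metab_fid <- apply_freq_shift(metab_fid, sample$global_shift_metab, t)

  ref_height <- max(Re(spec_from_td(metab_fid)))
  fid <- metab_fid

  nuisance_curve <- function(block, seed) {
    if (is.null(block)) return(NULL)
    cfg <- do.call(walk_config, block)
    simulate_nuisance(cfg, grid, ref_height, seed)
  }
  baseline <- nuisance_curve(sample$baseline, sample$baseline_seed)
  water <- nuisance_curve(sample$water, sample$water_seed)
  for (curve in list(baseline, water)) {
    if (!is.null(curve)) {
      nfid <- td_from_spec(curve)
      nfid <- apply_freq_shift(nfid, sample$global_shift_nuisance, t)
      fid <- fid + nfid
    }
  }

  sigma <- 0
  transients_on <- !is.null(sample$transients)
  if (!is.null(sample$snr) && !transients_on) {
    noisy <- add_noise(fid, sample$snr, ref_height, seed = sample$noise_seed,
                       correlated = isTRUE(sample$noise_correlated))
    fid <- noisy$fid
    sigma <- noisy$sigma
  }

  if (!is.null(sample$phi0)) fid <- apply_phase0(fid, sample$phi0)
  if (!is.null(sample$phi1)) {
    spec <- spec_from_td(fid)
    spec <- apply_phase1(spec, sample$phi1, grid$ppm, grid$ppm_ref)
    fid <- td_from_spec(spec)
  }
  if (!is.null(sample$eddy)) {
    fid <- apply_eddy(fid, sample$eddy$A0, sample$eddy$tc0, t)
  }

  tset <- NULL
  if (transients_on) {
    if (is.null(sample$snr)) {
      stop("transient stage requires an SNR value in the parameter record")
    }
    cfg <- do.call(coil_config, sample$transients)
    tset <- make_transients(fid, cfg, sample$snr, ref_height, t,
                            seed = sample$transient_seed)
    fid <- combine_transients(tset)
  }

  structure(list(
    fid = fid, transients = tset,
    ground_truth = list(metab_fid = metab_fid, baseline = baseline,
                        water = water, ref_height = ref_height, sigma = sigma)
  ), class = "sim_result")
}

#' Apodize, zero-fill and Fourier transform an FID
#'
#' The spectral post-processing stage: the FID is multiplied by the
#' apodization window `exp(-t * TL)`, padded with trailing zeros to `len`
#' points, and transformed with the package's single fixed (centre-shifted)
#' spectral convention. Apodizing a Lorentzian line of rate `d` yields a
#' measured FWHM of `(d + TL)/pi` Hz; zero-filling interpolates the axis
#' without moving peaks in ppm.
#'
#' @param fid Complex FID.
#' @param grid The acquisition grid the FID lives on.
#' @param TL Apodization rate, 1/s (>= 0).
#' @param len Zero-fill target length (>= FID length).
#' @return An object of class `mrs_spectrum`: `values` (complex), `ppm`
#'   (ascending axis of length `len`) and grid metadata.
#' @export
apodize_zerofill_fft <- function(fid, grid, TL = 0, len = length(fid)) {
  check_number(TL, "TL", nonneg = TRUE)
  if (len < length(fid)) {
    stop("zero-fill target (", len, ") must be >= FID length (", length(fid), ")")
  }
  apodized <- fid * exp(-grid$t * TL)
  values <- spec_from_td(apodized, len = len)
  ppm <- grid$ppm_ref +
    freq_axis_hz(as.integer(len), grid$spectral_width) / grid$carrier_frequency
  structure(list(values = values, ppm = ppm,
                 spectral_width = grid$spectral_width,
                 carrier_frequency = grid$carrier_frequency,
                 ppm_ref = grid$ppm_ref),
            class = "mrs_spectrum")
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf("<mrs_spectrum> %d points, %.4g .. %.4g ppm (plotted high-to-low)\n",
              length(x$values), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Plot a spectrum (high ppm left, field convention)
#'
#' @param x An `mrs_spectrum`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mrs_spectrum <- function(x, ...) {
  graphics::plot(x$ppm, Re(x$values), type = "l", xlim = rev(range(x$ppm)),
                 xlab = "ppm", ylab = "real signal", ...)
  invisible(x)
}

#' Crop and resample a spectrum
#'
#' Interpolates the spectrum (modified Akima, exact at coincident nodes) onto
#' `n_out` uniform points inside `ppm_window`.
#'
#' @param spectrum An `mrs_spectrum`.
#' @param ppm_window Length-2 ppm interval inside the spectrum's axis.
#' @param n_out Number of output points (>= 2).
#' @return An `mrs_spectrum` on the new axis.
#' @export
crop_resample <- function(spectrum, ppm_window, n_out) {
  if (!inherits(spectrum, "mrs_spectrum")) stop("`spectrum` must be an mrs_spectrum")
  if (length(ppm_window) != 2L) stop("`ppm_window` must be a length-2 interval")
  ppm_window <- sort(ppm_window)
  if (ppm_window[1] < min(spectrum$ppm) || ppm_window[2] > max(spectrum$ppm)) {
    stop("ppm window [", ppm_window[1], ", ", ppm_window[2],
         "] lies outside the spectral axis")
  }
  if (n_out < 2) stop("`n_out` must be >= 2")
  new_ppm <- seq(ppm_window[1], ppm_window[2], length.out = n_out)
  values <- interp_makima(spectrum$ppm, spectrum$values, new_ppm)
  structure(list(values = values, ppm = new_ppm,
                 spectral_width = spectrum$spectral_width,
                 carrier_frequency = spectrum$carrier_frequency,
                 ppm_ref = spectrum$ppm_ref),
            class = "mrs_spectrum")
}

#' Simulate a batch of spectra
#'
#' Draws `n` ground-truth parameter records and simulates each one. The whole
#' dataset is a deterministic function of (spec, basis, seed); simulating the
#' records one at a time with the same seeds gives identical results.
#'
#' @param spec A [sampling_spec()].
#' @param basis An `mrs_basis`.
#' @param n Number of spectra.
#' @param seed Master seed.
#' @return An object of class `spectral_dataset`: `fids` (n_points x n
#'   complex matrix), `samples` (list of parameter records), `components`
#'   (per-spectrum ground-truth signals), `transients` (list or `NULL`),
#'   `grid` and `seed`.
#' @export
simulate_dataset <- function(spec, basis, n, seed = 1L) {
  samples <- sample_parameters(spec, n, basis, seed)
  fids <- matrix(complex(real = 0), nrow = basis$grid$n_points, ncol = n)
  components <- vector("list", n)
  transients <- if (is.null(spec$transients)) NULL else vector("list", n)
  for (i in seq_len(n)) {
    res <- simulate_spectrum(samples[[i]], basis)
    fids[, i] <- res$fid
    components[[i]] <- res$ground_truth
    if (!is.null(transients)) transients[[i]] <- res$transients
  }
  structure(list(fids = fids, samples = samples, components = components,
                 transients = transients, grid = basis$grid,
                 basis_names = basis$names, seed = as.integer(seed)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d points (seed %d)%s\n",
              ncol(x$fids), nrow(x$fids), x$seed,
              if (!is.null(x$transients))
                sprintf(", %d transients each",
                        ncol(x$transients[[1]]$fids)) else ""))
  invisible(x)
}
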