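#' Parameter sampling distributions
#'
#' Descriptors for how each model parameter is drawn per spectrum:
#' `dist_fixed(v)`, `dist_uniform(lo, hi)`, `dist_normal(mu, sd)` and
#' `dist_clamped_normal(mu, sd, lo, hi)`. Descriptors are plain serialisable
#' lists; [draw_dist()] realises them.
#'
#' @param v,mu,sd,lo,hi Distribution parameters (`lo <= hi`).
#' @return An object of class `sim_dist`.
#' @export
dist_fixed <- function(v) {
  check_number(v, "v", allow_inf = TRUE)
  structure(list(type = "fixed", v = v), class = "sim_dist")
}

#' @rdname dist_fixed
#' @export
dist_uniform <- function(lo, hi) {
  check_number(lo, "lo"); check_number(hi, "hi")
  if (lo > hi) stop("`lo` must be <= `hi`")
  structure(list(type = "uniform", lo = lo, hi = hi), class = "sim_dist")
}

#' @rdname dist_fixed
#' @export
dist_normal <- function(mu, sd) {
  check_number(mu, "mu"); check_number(sd, "sd", nonneg = TRUE)
  structure(list(type = "normal", mu = mu, sd = sd), class = "sim_dist")
}

#' @rdname dist_fixed
#' @export
dist_clamped_normal <- function(mu, sd, lo, hi) {
  check_number(mu, "mu"); check_number(sd, "sd", nonneg = TRUE)
  check_number(lo, "lo"); check_number(hi, "hi")
  if (lo > hi) stop("`lo` must be <= `hi`")
  structure(list(type = "clamped_normal", mu = mu, sd = sd, lo = lo, hi = hi),
            class = "sim_dist")
}

#' Draw from a sampling descriptor
#'
#' @param d A `sim_dist` descriptor (a bare number is treated as fixed).
#' @param n Number of draws.
#' @return Numeric vector of `n` draws, always inside the descriptor support.
#' @export
draw_dist <- function(d, n = 1L) {
  if (is.numeric(d) && length(d) == 1L) return(rep(d, n))
  if (!inherits(d, "sim_dist")) stop("not a sampling distribution descriptor")
  switch(d$type,
    fixed = rep(d$v, n),
    uniform = stats::runif(n, d$lo, d$hi),
    normal = stats::rnorm(n, d$mu, d$sd),
    clamped_normal = pmin(pmax(stats::rnorm(n, d$mu, d$sd), d$lo), d$hi),
    stop("unknown distribution type: ", d$type)
  )
}

# internal: is x a descriptor or bare number usable as one?
is_dist_like <- function(x) {
  inherits(x, "sim_dist") || (is.numeric(x) && length(x) == 1L)
}

#' Declarative simulation sampling specification
#'
#' Describes, per model parameter, the distribution it is drawn from, plus
#' which model components are enabled. A component is enabled by supplying its
#' block and disabled with `NULL`: `snr = NULL` disables noise, `phi0`/`phi1`
#' the phase offsets, `eddy` the eddy current, `b0` the field-inhomogeneity
#' modulator, `baseline`/`water` the nuisance signals, and `transients` the
#' coil stage (which also defers noise to that stage).
#'
#' @param amplitudes Named list of descriptors (one per basis function) or a
#'   single descriptor applied to every function.
#' @param d Lorentzian rate descriptor(s), 1/s; named list or single.
#' @param g_metab,g_mm Gaussian rate descriptors (1/s^2) for the metabolite
#'   and macromolecule/lipid groups (`g_mm` defaults to `g_metab`).
#' @param freq_shift Per-function frequency-shift descriptor, Hz (drawn
#'   independently per function).
#' @param global_shift_metab,global_shift_nuisance Global-shift descriptors, Hz.
#' @param phi0,phi1 Phase descriptors (degrees; degrees/ppm), or `NULL`.
#' @param eddy `list(A0 = , tc0 = )` descriptors (Hz; s), or `NULL`.
#' @param snr SNR descriptor (linear), or `NULL` for noiseless.
#' @param noise_correlated Logical: correlated real/imaginary noise channels.
#' @param b0 `list(mu = , delta = , grid_shape = )` (descriptors; integer
#'   3-vector) or `list(mu=, dx=, dy=, dz=, grid_shape=)`, or `NULL`.
#' @param baseline,water Nuisance blocks: a list of [walk_config()] arguments
#'   whose `start`, `end`, `std` and `scale` entries may be descriptors, or
#'   `NULL`.
#' @param transients `list(n_transients = , ...)` of [coil_config()] arguments,
#'   or `NULL`.
#' @param TL Apodization rate descriptor, 1/s.
#' @param zero_fill Zero-fill target length (integer) or `NULL` for none.
#' @return An object of class `sampling_spec`.
#' @export
sampling_spec <- function(amplitudes, d, g_metab = dist_fixed(0), g_mm = NULL,
                          freq_shift = dist_fixed(0),
                          global_shift_metab = dist_fixed(0),
                          global_shift_nuisance = dist_fixed(0),
                          phi0 = NULL, phi1 = NULL, eddy = NULL,
                          snr = NULL, noise_correlated = FALSE,
                          b0 = NULL, baseline = NULL, water = NULL,
                          transients = NULL, TL = dist_fixed(0),
                          zero_fill = NULL) {
  if (missing(amplitudes) || is.null(amplitudes)) {
    stop("no descriptor given for parameter `amplitudes`")
  }
  if (missing(d) || is.null(d)) stop("no descriptor given for parameter `d`")
  if (!is.null(eddy) && (!is_dist_like(eddy$A0) || !is_dist_like(eddy$tc0))) {
    stop("eddy component enabled but descriptor missing for `eddy$A0` or `eddy$tc0`")
  }
  if (!is.null(b0)) {
    if (is.null(b0$grid_shape)) stop("b0 component enabled but `b0$grid_shape` missing")
    if (!is_dist_like(b0$mu)) stop("b0 component enabled but descriptor missing for `b0$mu`")
    if (is.null(b0$delta) && !(is_dist_like(b0$dx) && is_dist_like(b0$dy) &&
                               is_dist_like(b0$dz))) {
      stop("b0 component enabled but descriptor missing for `b0$delta` (or dx/dy/dz)")
    }
  }
  if (!is.null(transients) && is.null(transients$n_transients)) {
    stop("transients enabled but `transients$n_transients` missing")
  }
  structure(list(amplitudes = amplitudes, d = d, g_metab = g_metab,
                 g_mm = if (is.null(g_mm)) g_metab else g_mm,
                 freq_shift = freq_shift,
                 global_shift_metab = global_shift_metab,
                 global_shift_nuisance = global_shift_nuisance,
                 phi0 = phi0, phi1 = phi1, eddy = eddy, snr = snr,
                 noise_correlated = isTRUE(noise_correlated),
                 b0 = b0, baseline = baseline, water = water,
                 transients = transients, TL = TL, zero_fill = zero_fill),
            class = "sampling_spec")
}

#' Default study-condition sampling specification
#'
#' The package's reference simulation conditions for the toy basis: SNR fixed
#' at 15, water reference at 4.65 ppm on a 3 T grid, moderate Voigt
#' broadening, small per-metabolite and global frequency shifts, modest phase
#' offsets, eddy current with amplitude up to 5 Hz and time constant around
#' 0.15 s, and baseline/residual-water profiles at their documented default
#' spans and scales. B0 heterogeneity and transients are off by default and
#' opt-in per dataset.
#'
#' @param basis_names Character vector of basis function names.
#' @return A [sampling_spec()].
#' @export
default_sampling_spec <- function(basis_names = c("NAA", "Cr", "Cho")) {
  amps <- stats::setNames(
    rep(list(dist_uniform(0.5, 2.0)), length(basis_names)), basis_names)
  sampling_spec(
    amplitudes = amps,
    d = dist_uniform(2, 10),
    g_metab = dist_uniform(5, 50),
    freq_shift = dist_normal(0, 1),
    global_shift_metab = dist_normal(0, 3),
    global_shift_nuisance = dist_normal(0, 3),
    phi0 = dist_uniform(-20, 20),
    phi1 = dist_uniform(-5, 5),
    eddy = list(A0 = dist_uniform(0, 5), tc0 = dist_uniform(0.1, 0.3)),
    snr = dist_fixed(15),
    baseline = list(profile = "baseline", std = dist_uniform(0.5, 2),
                    scale = dist_uniform(0.1, 0.5)),
    water = list(profile = "residual_water", std = dist_uniform(0.5, 2),
                 scale = dist_uniform(0.5, 2))
  )
}

# realise one value from a field that may be a descriptor or a bare number
resolve_field <- function(x) {
  if (is_dist_like(x)) draw_dist(x, 1L) else x
}

# realise a per-basis-name vector from a single descriptor or a named list
resolve_named <- function(x, nm, what) {
  if (is_dist_like(x)) {
    return(stats::setNames(vapply(nm, function(z) draw_dist(x, 1L), numeric(1)), nm))
  }
  missing <- setdiff(nm, names(x))
  if (length(missing)) {
    stop("no descriptor given for `", what, "` of: ",
         paste(missing, collapse = ", "))
  }
  stats::setNames(vapply(nm, function(z) draw_dist(x[[z]], 1L), numeric(1)), nm)
}

#' Draw complete per-spectrum parameter records
#'
#' Realises `n` ground-truth parameter records from a sampling specification.
#' Each record is complete (every enabled component has concrete values and a
#' private seed), serialisable, and sufficient to re-simulate its spectrum
#' exactly. Sampling is deterministic under the master seed, and each record
#' is drawn from its own derived sub-stream, so a batch of `n` equals `n`
#' independent single-record calls with the same master seed.
#'
#' @param spec A [sampling_spec()].
#' @param n Number of records.
#' @param basis The basis set the records will be simulated against.
#' @param seed Master integer seed.
#' @return List of `n` parameter records (class `parameter_sample`).
#' @export
sample_parameters <- function(spec, n, basis, seed = 1L) {
  if (!inherits(spec, "sampling_spec")) stop("`spec` must be a sampling_spec")
  if (!inherits(basis, "mrs_basis")) stop("`basis` must be an mrs_basis")
  nm <- basis$names
  lapply(seq_len(n), function(i) {
    base <- sub_seed(seed, i)
    rec <- with_seed(base, {
      walk_block <- function(block, profile) {
        if (is.null(block)) return(NULL)
        args <- block
        args$profile <- if (is.null(block$profile)) profile else block$profile
        for (f in c("start", "end", "std", "scale")) {
          if (!is.null(args[[f]])) args[[f]] <- resolve_field(args[[f]])
        }
        cfg <- do.call(walk_config, args)
        unclass(cfg)
      }
      b0_block <- if (is.null(spec$b0)) NULL else {
        if (!is.null(spec$b0$delta)) {
          delta <- resolve_field(spec$b0$delta)
          list(dx = delta / 2, dy = delta / 2, dz = delta / 2,
               mu = resolve_field(spec$b0$mu),
               grid_shape = as.integer(spec$b0$grid_shape))
        } else {
          list(dx = resolve_field(spec$b0$dx), dy = resolve_field(spec$b0$dy),
               dz = resolve_field(spec$b0$dz), mu = resolve_field(spec$b0$mu),
               grid_shape = as.integer(spec$b0$grid_shape))
        }
      }
      trans_block <- if (is.null(spec$transients)) NULL else {
        tb <- spec$transients
        tb$n_transients <- as.integer(tb$n_transients)
        tb
      }
      list(
        amplitudes = resolve_named(spec$amplitudes, nm, "amplitudes"),
        d = resolve_named(spec$d, nm, "d"),
        g_metab = resolve_field(spec$g_metab),
        g_mm = resolve_field(spec$g_mm),
        freq_shift = resolve_named(spec$freq_shift, nm, "freq_shift"),
        global_shift_metab = resolve_field(spec$global_shift_metab),
        global_shift_nuisance = resolve_field(spec$global_shift_nuisance),
        phi0 = if (is.null(spec$phi0)) NULL else resolve_field(spec$phi0),
        phi1 = if (is.null(spec$phi1)) NULL else resolve_field(spec$phi1),
        eddy = if (is.null(spec$eddy)) NULL else
          list(A0 = resolve_field(spec$eddy$A0),
               tc0 = resolve_field(spec$eddy$tc0)),
        snr = if (is.null(spec$snr)) NULL else resolve_field(spec$snr),
        noise_correlated = spec$noise_correlated,
        b0 = b0_block,
        baseline = walk_block(spec$baseline, "baseline"),
        water = walk_block(spec$water, "residual_water"),
        transients = trans_block,
        TL = resolve_field(spec$TL),
        zero_fill = spec$zero_fill
      )
    })
    rec$noise_seed <- sub_seed(base, 1L)
    rec$baseline_seed <- sub_seed(base, 2L)
    rec$water_seed <- sub_seed(base, 3L)
    rec$transient_seed <- sub_seed(base, 4L)
    class(rec) <- "parameter_sample"
    rec
  })
}
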