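#' Build an acquisition grid
#'
#' Defines the uniform time axis and the matching chemical-shift (ppm) axis for
#' a single-voxel MRS acquisition. The time axis starts exactly at t = 0 (first
#' FID sample at the echo; any acquisition delay is modelled separately as
#' first-order phase). The ppm axis is stored ascending and is centred on
#' `ppm_ref`: the bin at index `floor(n/2) + 1` sits exactly at `ppm_ref`.
#'
#' @param n_points Number of complex FID points (>= 2).
#' @param spectral_width Spectral width / sampling rate, Hz.
#' @param carrier_frequency Spectrometer (carrier) frequency, MHz. At 3 T for
#'   protons this is 127.7 MHz, the package default elsewhere.
#' @param ppm_ref Chemical-shift reference point, ppm (water, 4.65 ppm).
#' @return An object of class `mrs_grid` with fields `n_points`,
#'   `spectral_width`, `carrier_frequency`, `ppm_ref`, `t` (seconds) and
#'   `ppm` (ascending).
#' @examples
#' g <- build_grid(2048, 2000, 127.7, 4.65)
#' head(g$t)        # 0, 1/2000, 2/2000, ...
#' range(g$ppm)     # spans 2000/127.7 ppm about 4.65
#' @export
build_grid <- function(n_points, spectral_width, carrier_frequency = 127.7,
                       ppm_ref = 4.65) {
  if (!is.numeric(n_points) || length(n_points) != 1L || !is.finite(n_points) ||
      n_points < 2 || n_points != round(n_points)) {
    stop("`n_points` must be a single integer >= 2, got ", deparse(n_points))
  }
  check_number(spectral_width, "spectral_width", positive = TRUE)
  check_number(carrier_frequency, "carrier_frequency", positive = TRUE)
  check_number(ppm_ref, "ppm_ref")
  n_points <- as.integer(n_points)
  t <- (seq_len(n_points) - 1) / spectral_width
  ppm <- ppm_ref + freq_axis_hz(n_points, spectral_width) / carrier_frequency
  structure(
    list(n_points = n_points, spectral_width = spectral_width,
         carrier_frequency = carrier_frequency, ppm_ref = ppm_ref,
         t = t, ppm = ppm),
    class = "mrs_grid"
  )
}

#' @export
print.mrs_grid <- function(x, ...) {
  cat(sprintf("<mrs_grid> %d points, sw %.6g Hz, f0 %.6g MHz, ppm_ref %.6g\n",
              x$n_points, x$spectral_width, x$carrier_frequency, x$ppm_ref))
  cat(sprintf("  t: 0 .. %.6g s   ppm: %.4g .. %.4g (ascending)\n",
              max(x$t), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Convert between Hz and ppm offsets on a grid
#'
#' Offsets are relative to the carrier: `delta_ppm * carrier_frequency` (MHz)
#' equals `delta_hz` exactly.
#'
#' @param hz,ppm Offset to convert.
#' @param grid An [build_grid()] acquisition grid.
#' @return The converted offset.
#' @export
hz_to_ppm <- function(hz, grid) hz / grid$carrier_frequency

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(ppm, grid) ppm * grid$carrier_frequency

#' Synthesise a toy metabolite basis set
#'
#' Generates simple exponentially damped singlet/multiplet basis functions on
#' an acquisition grid. Each basis function is the sum of its lines,
#' `amplitude * exp(-2i*pi*f_line*t) * exp(-t/t2_star)`, where `f_line` is the
#' line's offset from `ppm_ref` in Hz, and is then normalised so that its
#' noiseless real spectral maximum is 1.0 — the numerical meaning of "one basis
#' unit = 1.0 mM" used by the amplitude scaling stage. This generator stands in
#' for density-matrix-simulated basis sets in tests and examples; it is not a
#' quantum-mechanical simulation.
#'
#' @param lines Named list; one element per basis function, each a two-column
#'   matrix or data.frame with ppm position (column 1) and relative amplitude
#'   (column 2).
#' @param t2_star Apparent transverse decay time(s), seconds. A single value or
#'   a named vector matching `lines`.
#' @param grid An [build_grid()] acquisition grid.
#' @param groups Optional named character vector, `"metabolite"` (default) or
#'   `"mm_lipid"` per basis function.
#' @return An object of class `mrs_basis`: list with `grid`, `names`, `groups`
#'   and `fids` (complex matrix, `n_points` x n_functions).
#' @examples
#' g <- build_grid(2048, 2000)
#' b <- synth_toy_basis(list(NAA = cbind(2.01, 1)), t2_star = 0.1, grid = g)
#' @export
synth_toy_basis <- function(lines, t2_star, grid,
                            groups = NULL) {
  if (!inherits(grid, "mrs_grid")) stop("`grid` must be an mrs_grid")
  if (length(lines) == 0 || is.null(names(lines)) || any(names(lines) == "")) {
    stop("`lines` must be a non-empty named list of line tables")
  }
  if (anyDuplicated(names(lines))) stop("basis function names must be unique")
  nm <- names(lines)
  if (length(t2_star) == 1L && is.null(names(t2_star))) {
    t2_star <- stats::setNames(rep(t2_star, length(nm)), nm)
  }
  if (is.null(groups)) groups <- stats::setNames(rep("metabolite", length(nm)), nm)
  lo <- min(grid$ppm); hi <- max(grid$ppm)
  fids <- matrix(complex(real = 0), nrow = grid$n_points, ncol = length(nm),
                 dimnames = list(NULL, nm))
  for (name in nm) {
    tab <- lines[[name]]
    if (is.null(dim(tab))) tab <- matrix(tab, ncol = 2, byrow = TRUE)
    tab <- as.matrix(tab)
    if (nrow(tab) > 0) {
      if (any(tab[, 1] < lo | tab[, 1] > hi)) {
        stop("line position outside the grid's ppm span [", signif(lo, 4), ", ",
             signif(hi, 4), "] for basis function '", name, "'")
      }
      t2 <- t2_star[[name]]
      check_number(t2, paste0("t2_star['", name, "']"), positive = TRUE)
      fid <- complex(real = numeric(grid$n_points))
      for (j in seq_len(nrow(tab))) {
        f_line <- ppm_to_hz(tab[j, 1] - grid$ppm_ref, grid)
        fid <- fid + tab[j, 2] * exp(-2i * pi * f_line * grid$t) *
          exp(-grid$t / t2)
      }
      peak <- max(Re(spec_from_td(fid)))
      if (peak > 0) fid <- fid / peak
      fids[, name] <- fid
    }
  }
  structure(
    list(grid = grid, names = nm, groups = groups[nm], fids = fids),
    class = "mrs_basis"
  )
}

#' Default three-singlet toy basis
#'
#' The standing simulation fixture: NAA (2.01 ppm), Cr (3.03 ppm) and Cho
#' (3.22 ppm) singlets with distinct T2* values on the supplied grid.
#'
#' @param grid An acquisition grid; defaults to the 2048-point, 2000 Hz, 3 T
#'   grid used throughout.
#' @return An `mrs_basis`.
#' @export
default_toy_basis <- function(grid = build_grid(2048, 2000, 127.7, 4.65)) {
  synth_toy_basis(
    lines = list(NAA = cbind(2.01, 1.0),
                 Cr  = cbind(3.03, 1.0),
                 Cho = cbind(3.22, 1.0)),
    t2_star = c(NAA = 0.10, Cr = 0.09, Cho = 0.11),
    grid = grid
  )
}

#' @export
print.mrs_basis <- function(x, ...) {
  cat(sprintf("<mrs_basis> %d functions on %d points: %s\n",
              length(x$names), x$grid$n_points,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Write / read a basis set container
#'
#' Lossless structured-JSON container for a basis set: per-function complex
#' FIDs (stored as full-precision real/imaginary arrays) plus grid metadata
#' (`spectral_width_hz`, `carrier_frequency_mhz`, `ppm_ref`, group labels).
#'
#' @param basis An `mrs_basis`.
#' @param path File path (`.json`).
#' @return `read_basis` returns the reconstructed `mrs_basis`; `write_basis`
#'   returns `path` invisibly.
#' @export
write_basis <- function(basis, path) {
  if (!inherits(basis, "mrs_basis")) stop("`basis` must be an mrs_basis")
  obj <- list(
    format = "mrsforge-basis-v1",
    n_points = basis$grid$n_points,
    spectral_width_hz = basis$grid$spectral_width,
    carrier_frequency_mhz = basis$grid$carrier_frequency,
    ppm_ref = basis$grid$ppm_ref,
    functions = lapply(basis$names, function(name) {
      list(name = name, group = unname(basis$groups[[name]]),
           fid_re = Re(basis$fids[, name]), fid_im = Im(basis$fids[, name]))
    })
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (field in c("n_points", "spectral_width_hz", "carrier_frequency_mhz",
                  "ppm_ref", "functions")) {
    if (is.null(obj[[field]])) {
      stop("basis container is missing required field `", field, "`")
    }
  }
  grid <- build_grid(obj$n_points, obj$spectral_width_hz,
                     obj$carrier_frequency_mhz, obj$ppm_ref)
  nm <- vapply(obj$functions, function(f) {
    if (is.null(f$name) || !nzchar(f$name)) stop("basis function with empty `name`")
    f$name
  }, character(1))
  if (anyDuplicated(nm)) stop("duplicate basis function names in container")
  fids <- matrix(complex(real = 0), nrow = grid$n_points, ncol = length(nm),
                 dimnames = list(NULL, nm))
  groups <- character(length(nm)); names(groups) <- nm
  for (f in obj$functions) {
    if (length(f$fid_re) != grid$n_points || length(f$fid_im) != grid$n_points) {
      stop("fid length mismatch for basis function '", f$name, "': expected ",
           grid$n_points, ", got ", length(f$fid_re))
    }
    fids[, f$name] <- complex(real = f$fid_re, imaginary = f$fid_im)
    groups[f$name] <- if (is.null(f$group)) "metabolite" else f$group
  }
  structure(list(grid = grid, names = nm, groups = groups, fids = fids),
            class = "mrs_basis")
}
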