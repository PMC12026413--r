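# Dataset container (structured JSON) and NIfTI-MRS export.

cplx_out <- function(z) list(re = Re(z), im = Im(z))
cplx_in <- function(l) complex(real = l$re, imaginary = l$im)

sample_to_list <- function(s) {
  s <- unclass(s)
  # named numeric vectors must serialise as JSON objects, not bare arrays
  for (f in c("amplitudes", "d", "freq_shift")) s[[f]] <- as.list(s[[f]])
  s
}

sample_from_list <- function(l) {
  for (f in c("amplitudes", "d", "freq_shift")) {
    l[[f]] <- unlist(l[[f]])
  }
  class(l) <- "parameter_sample"
  l
}

#' Export a simulated dataset
#'
#' Writes a [simulate_dataset()] result to disk: a structured JSON container
#' (`dataset.json`) holding the complex FIDs, every ground-truth parameter
#' record, the noiseless component signals (metabolite-only fit, baseline,
#' residual water) and a run manifest (seed, package version); and/or a
#' NIfTI-MRS file (`dataset.nii` with complex time-domain data, dwell time in
#' the header, and a JSON sidecar carrying `SpectrometerFrequency` and
#' `ResonantNucleus`). Both round-trip losslessly.
#'
#' @param dataset A `spectral_dataset`.
#' @param dir Output directory (created if absent).
#' @param formats Any of `"container"`, `"nifti-mrs"`.
#' @return Invisibly, the paths written.
#' @export
export_dataset <- function(dataset, dir, formats = c("container", "nifti-mrs")) {
  if (!inherits(dataset, "spectral_dataset")) {
    stop("`dataset` must be a spectral_dataset")
  }
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if ("container" %in% formats) {
    comp_out <- lapply(dataset$components, function(gt) {
      list(metab_fid = cplx_out(gt$metab_fid),
           baseline = if (is.null(gt$baseline)) NULL else cplx_out(gt$baseline),
           water = if (is.null(gt$water)) NULL else cplx_out(gt$water),
           ref_height = gt$ref_height, sigma = gt$sigma)
    })
    trans_out <- if (is.null(dataset$transients)) NULL else
      lapply(dataset$transients, function(ts) {
        list(fids = cplx_out(as.complex(ts$fids)),
             n_transients = ncol(ts$fids),
             ground_truth = ts$ground_truth, sigma = ts$sigma,
             seed = ts$seed, correlated = ts$correlated)
      })
    obj <- list(
      format = "mrsforge-dataset-v1",
      manifest = list(seed = dataset$seed,
                      package_version = as.character(utils::packageVersion("mrsforge")),
                      n_spectra = ncol(dataset$fids)),
      grid = list(n_points = dataset$grid$n_points,
                  spectral_width_hz = dataset$grid$spectral_width,
                  carrier_frequency_mhz = dataset$grid$carrier_frequency,
                  ppm_ref = dataset$grid$ppm_ref),
      basis_names = dataset$basis_names,
      fids = cplx_out(as.complex(dataset$fids)),
      samples = lapply(dataset$samples, sample_to_list),
      components = comp_out,
      transients = trans_out
    )
    p <- file.path(dir, "dataset.json")
    jsonlite::write_json(obj, p, digits = I(17), auto_unbox = TRUE,
                         null = "null")
    paths <- c(paths, p)
  }
  if ("nifti-mrs" %in% formats) {
    p <- file.path(dir, "dataset.nii")
    write_nifti_mrs(dataset$fids, dataset$grid, p, dim5_tag = "DIM_DYN")
    paths <- c(paths, p, paste0(p, ".json"))
  }
  invisible(paths)
}

#' Read a dataset container back
#'
#' Reconstructs a `spectral_dataset` from the JSON container written by
#' [export_dataset()]; FIDs and parameter records are recovered exactly.
#'
#' @param path Path to `dataset.json` (or the directory holding it).
#' @return A `spectral_dataset`.
#' @export
read_dataset <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "dataset.json")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "mrsforge-dataset-v1")) {
    stop("not an mrsforge dataset container: ", path)
  }
  grid <- build_grid(obj$grid$n_points, obj$grid$spectral_width_hz,
                     obj$grid$carrier_frequency_mhz, obj$grid$ppm_ref)
  n <- obj$manifest$n_spectra
  fids <- matrix(cplx_in(obj$fids), nrow = grid$n_points, ncol = n)
  samples <- lapply(obj$samples, sample_from_list)
  components <- lapply(obj$components, function(gt) {
    list(metab_fid = cplx_in(gt$metab_fid),
         baseline = if (is.null(gt$baseline)) NULL else cplx_in(gt$baseline),
         water = if (is.null(gt$water)) NULL else cplx_in(gt$water),
         ref_height = gt$ref_height, sigma = gt$sigma)
  })
  transients <- if (is.null(obj$transients)) NULL else
    lapply(obj$transients, function(ts) {
      structure(list(
        fids = matrix(cplx_in(ts$fids), nrow = grid$n_points,
                      ncol = ts$n_transients),
        ground_truth = do.call(rbind, lapply(ts$ground_truth, as.data.frame)),
        sigma = ts$sigma, seed = ts$seed, correlated = ts$correlated
      ), class = "transient_set")
    })
  structure(list(fids = fids, samples = samples, components = components,
                 transients = transients, grid = grid,
                 basis_names = obj$basis_names,
                 seed = as.integer(obj$manifest$seed)),
            class = "spectral_dataset")
}

#' Write / read complex MRS data as NIfTI-MRS
#'
#' Single-voxel layout: data dimensions `1 x 1 x 1 x n_points [x dim5 [x dim6]]`
#' with complex time-domain values, the dwell time (`1/spectral_width`) stored
#' as the spacing of the 4th (time) dimension, and a JSON sidecar carrying
#' `SpectrometerFrequency` (MHz), `ResonantNucleus` and the higher-dimension
#' tags (`dim_5`, `dim_6`: `DIM_COIL` for coil transients, `DIM_DYN` for
#' repeats/averages).
#'
#' @param data Complex matrix (`n_points x k`) or 3D array
#'   (`n_points x C x k`), or a vector for a single FID.
#' @param grid The acquisition grid.
#' @param path Output `.nii` path; the sidecar is written to `<path>.json`.
#' @param dim5_tag,dim6_tag NIfTI-MRS dimension tags.
#' @param nucleus Resonant nucleus label.
#' @return `write_nifti_mrs` returns `path` invisibly; `read_nifti_mrs`
#'   returns a list with `data` (complex array, singleton spatial dims
#'   dropped), `dwell_time_s` and the sidecar `header`.
#' @export
write_nifti_mrs <- function(data, grid, path, dim5_tag = "DIM_DYN",
                            dim6_tag = "DIM_DYN", nucleus = "1H") {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  d <- dim(data)
  if (d[1] != grid$n_points) {
    stop("first data dimension (", d[1], ") must equal grid n_points (",
         grid$n_points, ")")
  }
  arr <- array(data, dim = c(1L, 1L, 1L, d))
  dwell <- 1 / grid$spectral_width
  hdr <- RNifti::niftiHeader(arr)
  hdr$pixdim[5] <- dwell
  hdr$intent_name <- "mrs_v0_2"
  img <- RNifti::asNifti(arr, reference = hdr)
  RNifti::writeNifti(img, path)
  sidecar <- list(
    SpectrometerFrequency = grid$carrier_frequency,
    ResonantNucleus = nucleus,
    SpectralWidth = grid$spectral_width,
    ChemicalShiftReference = grid$ppm_ref
  )
  if (length(d) >= 2 && d[2] > 1) sidecar$dim_5 <- dim5_tag
  if (length(d) >= 3 && d[3] > 1) sidecar$dim_6 <- dim6_tag
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_nifti_mrs
#' @export
read_nifti_mrs <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  data <- array(as.complex(img), dim = d)
  keep <- c(4L, if (length(d) > 4) 5:length(d))
  data <- array(data, dim = d[keep])
  sidecar_path <- paste0(path, ".json")
  header <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else list()
  list(data = data, dwell_time_s = hdr$pixdim[5], header = header)
}
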