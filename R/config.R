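# Declarative simulation configuration files (JSON) for the command-line
# entry point. A config mirrors sampling_spec(): distribution descriptors are
# written as {"dist": "uniform", "lo": ..., "hi": ...} (types fixed, uniform,
# normal, clamped_normal); bare numbers mean fixed values.

parse_dist <- function(x, where) {
  if (is.numeric(x) && length(x) == 1L) return(x)
  if (is.list(x) && !is.null(x$dist)) {
    return(switch(x$dist,
      fixed = dist_fixed(x$v),
      uniform = dist_uniform(x$lo, x$hi),
      normal = dist_normal(x$mu, x$sd),
      clamped_normal = dist_clamped_normal(x$mu, x$sd, x$lo, x$hi),
      stop("unknown distribution type '", x$dist, "' in `", where, "`")
    ))
  }
  stop("`", where, "` is not a number or a distribution descriptor")
}

parse_dist_map <- function(x, where) {
  if (is.null(x)) return(NULL)
  if (is.list(x) && is.null(x$dist) && !is.null(names(x))) {
    return(lapply(stats::setNames(names(x), names(x)),
                  function(nm) parse_dist(x[[nm]], paste0(where, "$", nm))))
  }
  parse_dist(x, where)
}

#' Read a simulation configuration file
#'
#' Parses a declarative JSON configuration into a [sampling_spec()] plus run
#' settings (`n`, `seed`, basis source). Unknown or malformed entries are
#' rejected with the offending field named.
#'
#' @param path Path to the JSON configuration.
#' @return List with `spec` (a `sampling_spec`), `n`, `seed` and `basis`
#'   (a basis-container path, or `"toy"` for the built-in fixture).
#' @export
read_sim_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(cfg$spec)) stop("config is missing the `spec` block")
  s <- cfg$spec
  block <- function(b, fields, where) {
    if (is.null(b)) return(NULL)
    for (f in fields) {
      if (!is.null(b[[f]])) b[[f]] <- parse_dist(b[[f]], paste0(where, "$", f))
    }
    b
  }
  spec <- sampling_spec(
    amplitudes = parse_dist_map(s$amplitudes, "spec$amplitudes"),
    d = parse_dist_map(s$d, "spec$d"),
    g_metab = if (is.null(s$g_metab)) dist_fixed(0) else parse_dist(s$g_metab, "spec$g_metab"),
    g_mm = if (is.null(s$g_mm)) NULL else parse_dist(s$g_mm, "spec$g_mm"),
    freq_shift = if (is.null(s$freq_shift)) dist_fixed(0) else
      parse_dist_map(s$freq_shift, "spec$freq_shift"),
    global_shift_metab = if (is.null(s$global_shift_metab)) dist_fixed(0) else
      parse_dist(s$global_shift_metab, "spec$global_shift_metab"),
    global_shift_nuisance = if (is.null(s$global_shift_nuisance)) dist_fixed(0) else
      parse_dist(s$global_shift_nuisance, "spec$global_shift_nuisance"),
    phi0 = if (is.null(s$phi0)) NULL else parse_dist(s$phi0, "spec$phi0"),
    phi1 = if (is.null(s$phi1)) NULL else parse_dist(s$phi1, "spec$phi1"),
    eddy = block(s$eddy, c("A0", "tc0"), "spec$eddy"),
    snr = if (is.null(s$snr)) NULL else parse_dist(s$snr, "spec$snr"),
    noise_correlated = isTRUE(s$noise_correlated),
    b0 = block(s$b0, c("mu", "delta", "dx", "dy", "dz"), "spec$b0"),
    baseline = block(s$baseline, c("start", "end", "std", "scale"), "spec$baseline"),
    water = block(s$water, c("start", "end", "std", "scale"), "spec$water"),
    transients = s$transients,
    TL = if (is.null(s$TL)) dist_fixed(0) else parse_dist(s$TL, "spec$TL"),
    zero_fill = s$zero_fill
  )
  list(spec = spec,
       n = if (is.null(cfg$n)) 1L else as.integer(cfg$n),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       basis = if (is.null(cfg$basis)) "toy" else cfg$basis)
}

#' Validate a simulation configuration file
#'
#' @param path Path to the JSON configuration.
#' @return `TRUE` invisibly if valid; otherwise an error naming the problem.
#' @export
validate_sim_config <- function(path) {
  invisible({read_sim_config(path); TRUE})
}
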