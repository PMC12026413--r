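# Shared fixtures and independent measurement oracles.

toy_grid <- function(n = 2048L, sw = 2000, f0 = 127.7, ref = 4.65) {
  build_grid(n, sw, f0, ref)
}

toy_basis <- function(grid = toy_grid()) default_toy_basis(grid)

# FFT peak-pick oracle: location (ppm) of the magnitude maximum on a
# zero-filled axis, independent of the pipeline's spectrum object.
peak_ppm <- function(fid, grid, zf = 8L) {
  len <- zf * length(fid)
  s <- mrsforge:::spec_from_td(fid, len)
  ppm <- grid$ppm_ref +
    mrsforge:::freq_axis_hz(len, grid$spectral_width) / grid$carrier_frequency
  ppm[which.max(Mod(s))]
}

# Numeric FWHM oracle (Hz): half-max crossings of the real channel with
# linear interpolation between bins, measured on a heavily zero-filled axis.
measure_fwhm_hz <- function(fid, grid, zf = 16L) {
  len <- zf * length(fid)
  s <- Re(mrsforge:::spec_from_td(fid, len))
  f <- mrsforge:::freq_axis_hz(len, grid$spectral_width)
  ip <- which.max(s)
  half <- s[ip] / 2
  il <- ip; while (il > 1 && s[il] > half) il <- il - 1
  ir <- ip; while (ir < len && s[ir] > half) ir <- ir + 1
  xl <- f[il] + (half - s[il]) / (s[il + 1] - s[il]) * (f[il + 1] - f[il])
  xr <- f[ir - 1] + (half - s[ir - 1]) / (s[ir] - s[ir - 1]) * (f[ir] - f[ir - 1])
  xr - xl
}

# metabolite-only fixture: three-singlet FID with fixed Voigt broadening
toy_metab_fid <- function(basis = toy_basis()) {
  mp <- metab_params(amplitudes = c(NAA = 1, Cr = 0.8, Cho = 0.6),
                     d = c(NAA = 5, Cr = 5, Cho = 5), g_metab = 10)
  scale_and_sum(basis, mp)
}

ref_height_of <- function(fid) max(Re(mrsforge:::spec_from_td(fid)))
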