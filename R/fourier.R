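# Internal Fourier helpers.
#
# One fixed spectral convention for the whole package:
#   S[j] = sum_k fid[k] * exp(+2*pi*1i * j*k / n),  then fftshifted,
# i.e. the unnormalised inverse-type DFT with the zero-frequency bin moved to
# the centre of the axis. Under this convention a time-domain factor
# exp(-2*pi*1i * f * t) displaces a resonance by +f Hz (toward higher ppm).
# Noise scaling (add_noise) and all shift/phase signs rely on this single
# convention; do not introduce a second one.

fftshift <- function(x) {
  n <- length(x)
  x[((seq_len(n) - 1L + floor((n + 1L) / 2)) %% n) + 1L]
}

ifftshift <- function(x) {
  n <- length(x)
  x[((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L]
}

# FID (t >= 0) -> centred spectrum, optionally zero-filled to `len` points.
spec_from_td <- function(fid, len = length(fid)) {
  if (len < length(fid)) {
    stop("zero-fill length (", len, ") must be >= FID length (", length(fid), ")")
  }
  padded <- c(fid, complex(real = numeric(len - length(fid))))
  fftshift(stats::fft(padded, inverse = TRUE))
}

# Centred spectrum -> FID; exact inverse of spec_from_td at equal lengths.
td_from_spec <- function(spec) {
  stats::fft(ifftshift(spec)) / length(spec)
}

# Frequency axis (Hz) matching spec_from_td output ordering.
freq_axis_hz <- function(n, spectral_width) {
  (seq_len(n) - 1L - floor(n / 2)) * spectral_width / n
}
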