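test_that("zero-order phase behaves as a global rotation group", {
  g <- toy_grid(512L)
  fid <- toy_basis(g)$fids[, "NAA"]

  expect_identical(apply_phase0(fid, 0), fid)
  expect_equal(apply_phase0(fid, 180), -fid, tolerance = 1e-12)
  expect_equal(apply_phase0(apply_phase0(fid, 50), 70),
               apply_phase0(fid, 120), tolerance = 1e-12)
  expect_equal(apply_phase0(fid, 360), fid, tolerance = 1e-12)

  # 90 degrees swaps absorption into dispersion: real channel becomes the
  # former imaginary channel (up to sign)
  s0 <- mrsforge:::spec_from_td(fid)
  s90 <- mrsforge:::spec_from_td(apply_phase0(fid, 90))
  expect_equal(Re(s90), Im(s0), tolerance = 1e-10)

  # unitary: magnitudes preserved
  expect_equal(Mod(s90), Mod(s0), tolerance = 1e-10)
})

test_that("first-order phase pivots exactly at ppm_ref", {
  g <- toy_grid()
  spec <- mrsforge:::spec_from_td(toy_metab_fid())
  for (phi1 in c(-90, 7.3, 45)) {
    out <- apply_phase1(spec, phi1, g$ppm, g$ppm_ref)
    i_ref <- which(g$ppm == g$ppm_ref)
    expect_length(i_ref, 1)
    expect_identical(out[i_ref], spec[i_ref])
    # applied phase at ppm_ref + 1 is exactly phi1 degrees
    i1 <- which.min(abs(g$ppm - (g$ppm_ref + 1)))
    expect_equal(Arg(out[i1] / spec[i1]) * 180 / pi,
                 -phi1 * (g$ppm[i1] - g$ppm_ref), tolerance = 1e-6)
    expect_equal(Mod(out), Mod(spec), tolerance = 1e-12)
  }
  expect_identical(apply_phase1(spec, 0, g$ppm, g$ppm_ref), spec)
})

test_that("eddy-current term matches its closed form and limits", {
  g <- toy_grid()
  fid <- toy_basis(g)$fids[, "NAA"]

  expect_identical(apply_eddy(fid, 0, 0.15, g$t), fid)

  # pointwise formula oracle at the documented example point
  A0 <- 5; tc0 <- 0.15
  out <- apply_eddy(fid, A0, tc0, g$t)
  k <- which.min(abs(g$t - 0.15))
  phi_expect <- 2 * pi * A0 * g$t[k] * exp(-g$t[k] / tc0)
  expect_equal(out[k], fid[k] * exp(-1i * phi_expect), tolerance = 1e-12)

  # unitary: time-domain magnitudes and total spectral energy preserved
  expect_equal(Mod(out), Mod(fid), tolerance = 1e-12)
  expect_equal(sum(Mod(mrsforge:::spec_from_td(out))^2),
               sum(Mod(mrsforge:::spec_from_td(fid))^2), tolerance = 1e-10)

  # tc0 >> acquisition: converges to a global shift of A0 Hz
  shifted <- apply_eddy(fid, 3, 1e3, g$t)
  dppm <- peak_ppm(shifted, g) - peak_ppm(fid, g)
  expect_equal(dppm * g$carrier_frequency, 3,
               tolerance = g$spectral_width / g$n_points)
})

test_that("noise is seeded, calibrated to the spectral sigma, and SNR-faithful", {
  g <- toy_grid()
  fid <- toy_metab_fid()
  ref <- ref_height_of(fid)

  # sentinel: no noise
  clean <- add_noise(fid, Inf, ref)
  expect_identical(clean$fid, fid)
  expect_identical(clean$sigma, 0)

  # bit-reproducible under a seed; near-independent across seeds
  n1 <- add_noise(fid, 15, ref, seed = 7)
  n2 <- add_noise(fid, 15, ref, seed = 7)
  n3 <- add_noise(fid, 15, ref, seed = 8)
  expect_identical(n1$fid, n2$fid)
  expect_lt(abs(cor(Re(n1$fid - fid), Re(n3$fid - fid))), 0.1)

  # Monte-Carlo: empirical SD of a signal-free spectral region matches sigma
  sds <- vapply(1:200, function(s) {
    nf <- add_noise(fid, 15, ref, seed = s)$fid
    spec <- mrsforge:::spec_from_td(nf)
    sd(Re(spec[g$ppm > max(g$ppm) - 0.1 * diff(range(g$ppm))]))
  }, numeric(1))
  expect_equal(mean(sds), n1$sigma, tolerance = 0.05)

  # measured SNR over replicates averages the request
  snrs <- vapply(1:100, function(s) {
    measure_snr(mrsforge:::spec_from_td(add_noise(fid, 15, ref, seed = s)$fid),
                g$ppm)
  }, numeric(1))
  expect_equal(mean(snrs), 15, tolerance = 0.03)

  # correlated mode: imaginary channel is the quadrature of the real channel
  nc <- add_noise(fid, 15, ref, seed = 5, correlated = TRUE)
  noise <- nc$fid - fid
  expect_equal(Im(noise), mrsforge:::quadrature_partner(Re(noise)),
               tolerance = 1e-12)

  expect_error(add_noise(fid, -3, ref), "snr0")
})

test_that("measure_snr is scale invariant and guards degenerate inputs", {
  g <- toy_grid()
  spec <- mrsforge:::spec_from_td(add_noise(toy_metab_fid(), 15,
                                            ref_height_of(toy_metab_fid()),
                                            seed = 1)$fid)
  s1 <- measure_snr(spec, g$ppm)
  expect_equal(measure_snr(3.7 * spec, g$ppm), s1, tolerance = 1e-12)
  # noiseless: Inf sentinel
  expect_identical(measure_snr(mrsforge:::spec_from_td(toy_metab_fid()) * 0 + 1,
                               g$ppm), Inf)
  expect_error(measure_snr(spec, g$ppm, noise_region = c(100, 101)),
               "noise region")
})
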