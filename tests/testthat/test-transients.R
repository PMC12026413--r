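test_that("sensitivity sampler is a clamped Gaussian centred at 1", {
  cfg <- coil_config(8)
  expect_identical(sample_sensitivities(coil_config(4, sens_sd = 0), seed = 1),
                   rep(1, 4))
  s <- sample_sensitivities(cfg, seed = 3, n = 1e5)
  expect_true(all(s >= 0 & s <= 2))
  expect_equal(mean(s), 1.0, tolerance = 0.005)
})

test_that("per-transient SNR targets scale as snr0/sqrt(C)", {
  expect_equal(sample_transient_snrs(15, coil_config(1, snr_spread = 0)), 15)
  expect_equal(sample_transient_snrs(15, coil_config(4, snr_spread = 0)),
               rep(7.5, 4))
  s <- sample_transient_snrs(15, coil_config(8), seed = 5)
  expect_length(s, 8)
  big <- unlist(lapply(1:200, function(i)
    sample_transient_snrs(15, coil_config(8), seed = i)))
  expect_equal(mean(big), 15 / sqrt(8), tolerance = 0.02)
})

test_that("degenerate single-coil operator reduces to plain noise addition", {
  g <- toy_grid()
  fid <- toy_metab_fid()
  ref <- ref_height_of(fid)
  cfg <- coil_config(1, sens_sd = 0, snr_spread = 0,
                     drift_freq_range = 0, drift_phase_range = 0)
  ts <- make_transients(fid, cfg, 15, ref, g$t, seed = 11)
  direct <- add_noise(fid, 15, ref, seed = ts$ground_truth$noise_seed[1])
  expect_identical(ts$fids[, 1], direct$fid)
  expect_identical(combine_transients(ts), ts$fids[, 1])
})

test_that("stored per-transient ground truth rebuilds each transient exactly", {
  g <- toy_grid()
  fid <- toy_metab_fid()
  ref <- ref_height_of(fid)
  cfg <- coil_config(4)
  ts <- make_transients(fid, cfg, 15, ref, g$t, seed = 21)
  for (c in 1:4) {
    rebuilt <- apply_transient_params(fid, ts$ground_truth[c, ], ref, g$t)
    expect_identical(rebuilt, ts$fids[, c])
  }
  # negating the stored drifts re-aligns the transients to within noise
  for (c in 1:4) {
    aligned <- apply_phase0(apply_freq_shift(ts$fids[, c],
                                             -ts$ground_truth$dfreq_hz[c], g$t),
                            -ts$ground_truth$dphase_deg[c])
    resid <- aligned - ts$ground_truth$sensitivity[c] * fid
    expect_lt(sd(Re(resid)), 3 * mrsforge:::noise_sd_time(ts$sigma[c], length(fid)))
  }
})

test_that("averaging C transients recovers the sqrt(C) SNR gain", {
  g <- toy_grid()
  fid <- toy_metab_fid()
  ref <- ref_height_of(fid)
  for (C in c(2, 4, 8)) {
    cfg <- coil_config(C, sens_sd = 0, snr_spread = 0,
                       drift_freq_range = 0, drift_phase_range = 0)
    target_transient_snr <- 15 / sqrt(C)
    ratios <- vapply(1:50, function(r) {
      ts <- make_transients(fid, cfg, 15, ref, g$t, seed = 1000 * C + r)
      measure_snr(mrsforge:::spec_from_td(combine_transients(ts)), g$ppm) /
        target_transient_snr
    }, numeric(1))
    expect_gt(mean(ratios), 0.9 * sqrt(C))
    expect_lt(mean(ratios), 1.1 * sqrt(C))
  }
})

test_that("weighted combination modes agree and respect zero weights", {
  g <- toy_grid(256L)
  fid <- toy_basis(g)$fids[, "NAA"]
  cfg <- coil_config(3, sens_sd = 0, snr_spread = 0,
                     drift_freq_range = 0, drift_phase_range = 0)
  ts <- make_transients(fid, cfg, Inf, 1, g$t, seed = 2)
  # noiseless identical transients: any normalised combination equals one input
  expect_equal(combine_transients(ts), ts$fids[, 1], tolerance = 1e-12)
  expect_equal(combine_transients(ts, weights = c(2, 1, 1), mode = "average"),
               combine_transients(ts, weights = c(2, 1, 1), mode = "sum"),
               tolerance = 1e-14)
  expect_identical(combine_transients(ts, weights = c(0, 1, 0)), ts$fids[, 2])
  expect_error(combine_transients(ts, weights = c(0, 0, 0)), "zero")
})

test_that("inter-coil noise correlation follows the requested matrix", {
  g <- toy_grid(4096L)
  fid <- complex(real = numeric(4096))
  R <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  cfg <- coil_config(2, sens_sd = 0, snr_spread = 0, drift_freq_range = 0,
                     drift_phase_range = 0, noise_correlation = R)
  ts <- make_transients(fid + 1e-9, cfg, 10, 1, g$t, seed = 8)
  emp <- cor(Re(ts$fids[, 1]), Re(ts$fids[, 2]))
  expect_lt(abs(emp - 0.6), 0.05)
  expect_error(coil_config(2, noise_correlation = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})
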