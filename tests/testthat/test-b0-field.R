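test_that("sub-voxel grid shape is the voxel-size quotient floored at 1", {
  expect_identical(grid_shape_from_voxels(c(20, 20, 20), c(1, 1, 1)),
                   c(20L, 20L, 20L))
  expect_identical(grid_shape_from_voxels(c(20, 10, 8), c(2, 2, 2)),
                   c(10L, 5L, 4L))
  expect_identical(grid_shape_from_voxels(c(1, 1, 1), c(2, 2, 2)),
                   c(1L, 1L, 1L))
  expect_error(grid_shape_from_voxels(c(0, 1, 1), c(1, 1, 1)), "positive")
})

test_that("linear field maps have the stated mean, centre and extremes", {
  # degenerate gradient: constant map
  m0 <- simulate_field_map(b0_params(mu = -3, grid_shape = c(3, 3, 3)))
  expect_true(all(m0$offsets == -3))

  # isotropic delta = 3 Hz: sampled extreme approaches mu + dx + dy + dz
  # from inside (midpoint cell-centre sampling at (G-1)/G of the half-range)
  p <- b0_params(mu = 10, delta = 3, grid_shape = c(9, 9, 9))
  mp <- simulate_field_map(p)
  expect_equal(max(mp$offsets), 10 + 3 * 1.5 * (9 - 1) / 9, tolerance = 1e-12)
  expect_equal(mp$offsets[5, 5, 5], 10)  # odd grid centre = mu

  # voxel mean equals mu for arbitrary params (brute-force mean oracle)
  set.seed(11)
  for (i in 1:5) {
    p <- b0_params(dx = runif(1, 0, 5), dy = runif(1, 0, 5),
                   dz = runif(1, 0, 5), mu = runif(1, -20, 20),
                   grid_shape = sample(1:8, 3, replace = TRUE))
    mp <- simulate_field_map(p)
    expect_equal(mean(mp$offsets), p$mu, tolerance = 1e-10)
  }
})

test_that("modulator equals the brute-force sub-voxel sum and is normalised", {
  g <- toy_grid(256L)
  p <- b0_params(dx = 1.2, dy = 0.7, dz = 2.1, mu = -3, grid_shape = c(4, 3, 5))
  map <- simulate_field_map(p)
  m <- b0_modulator(map, g$t)
  brute <- vapply(g$t, function(tt) mean(exp(-2i * pi * as.numeric(map$offsets) * tt)),
                  complex(1))
  expect_equal(m, brute, tolerance = 1e-12)
  expect_equal(Mod(m[1]), 1)
  expect_true(all(Mod(m) <= 1 + 1e-12))

  # constant map: pure phase ramp, unit magnitude
  mc <- b0_modulator(simulate_field_map(b0_params(mu = 7, grid_shape = c(1, 1, 1))), g$t)
  expect_equal(mc, exp(-2i * pi * 7 * g$t), tolerance = 1e-12)
  expect_equal(Mod(mc), rep(1, length(g$t)), tolerance = 1e-12)

  # separable 3D map = product of per-axis 1D modulators
  p3 <- b0_params(dx = 2, dy = 1, dz = 0.5, grid_shape = c(5, 4, 3))
  m3 <- b0_modulator(simulate_field_map(p3), g$t)
  m1 <- function(d, gg) b0_modulator(simulate_field_map(
    b0_params(dx = d, grid_shape = c(gg, 1, 1))), g$t)
  expect_equal(m3, m1(2, 5) * m1(1, 4) * m1(0.5, 3), tolerance = 1e-12)
})

test_that("1D modulator approaches sinc damping in the continuum limit", {
  g <- toy_grid()
  dx <- 2
  m <- b0_modulator(simulate_field_map(b0_params(dx = dx, grid_shape = c(101, 1, 1))),
                    g$t)
  sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)
  expect_lt(max(abs(m - sinc(2 * pi * dx * g$t))), 0.01)
})

test_that("applying a field map shifts by the mean offset and damps with spread", {
  g <- toy_grid()
  b <- toy_basis(g)
  fid <- b$fids[, "NAA"]
  bin_hz <- g$spectral_width / g$n_points

  # constant mu = 10 Hz map displaces the singlet by +10 Hz
  m <- b0_modulator(simulate_field_map(b0_params(mu = 10, grid_shape = c(3, 3, 3))), g$t)
  shift_hz <- (peak_ppm(apply_b0(fid, m), g) - peak_ppm(fid, g)) *
    g$carrier_frequency
  expect_lt(abs(shift_hz - 10), bin_hz)

  # mean-offset equivalence for a heterogeneous map
  p <- b0_params(dx = 2, dy = 1.5, dz = 1, mu = -6, grid_shape = c(7, 7, 7))
  m2 <- b0_modulator(simulate_field_map(p), g$t)
  shift2 <- (peak_ppm(apply_b0(fid, m2), g) - peak_ppm(fid, g)) *
    g$carrier_frequency
  expect_lt(abs(shift2 - (-6)), bin_hz)

  # increasing heterogeneity at fixed mu: spectral max non-increasing
  peaks <- vapply(c(0.5, 3, 7, 15), function(delta) {
    mm <- b0_modulator(simulate_field_map(
      b0_params(mu = 10, delta = delta, grid_shape = c(11, 11, 11))), g$t)
    max(Re(mrsforge:::spec_from_td(apply_b0(fid, mm))))
  }, numeric(1))
  expect_true(all(diff(peaks) <= 0))

  expect_error(apply_b0(fid, m[-1]), "length")
})
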