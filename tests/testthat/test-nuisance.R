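test_that("bounded walk respects bounds, trends and seeding", {
  # degenerate noise, flat trend: exactly zero
  cfg0 <- walk_config("baseline", std = 0, start = 0, end = 0,
                      lower_bound = -1, upper_bound = 1, length = 64L)
  expect_identical(bounded_smoothed_walk(cfg0, seed = 1), rep(0, 64))

  # degenerate noise, sloped trend: the straight line away from the kernel edges
  cfg1 <- walk_config("baseline", std = 0, start = 0, end = 1,
                      lower_bound = -2, upper_bound = 2, length = 256L,
                      window_size = 0.02)
  w <- bounded_smoothed_walk(cfg1, seed = 1)
  k <- round(0.02 * 256)
  interior <- (k + 1):(256 - k)
  expect_equal(w[interior], seq(0, 1, length.out = 256)[interior],
               tolerance = 1e-12)

  # seeded determinism
  cfg <- walk_config("residual_water", std = 1)
  expect_identical(bounded_smoothed_walk(cfg, 99), bounded_smoothed_walk(cfg, 99))
  expect_false(identical(bounded_smoothed_walk(cfg, 99),
                         bounded_smoothed_walk(cfg, 100)))

  expect_error(walk_config("baseline", lower_bound = 1, upper_bound = -1),
               "lower_bound")
})

test_that("walk outputs stay within bounds for many random configurations", {
  set.seed(2024)
  for (i in 1:1000) {
    lb <- runif(1, -5, 0); ub <- lb + runif(1, 0.5, 5)
    cfg <- walk_config(sample(c("baseline", "residual_water"), 1),
                       start = runif(1, lb, ub), end = runif(1, lb, ub),
                       std = runif(1, 0, 3), lower_bound = lb, upper_bound = ub,
                       length = sample(16:256, 1),
                       window_size = runif(1, 0.01, 1))
    w <- bounded_smoothed_walk(cfg, seed = i)
    expect_true(min(w) >= lb - 1e-12 && max(w) <= ub + 1e-12)
  }
})

test_that("baseline profile is smoother than the residual-water profile", {
  tv <- function(x) sum(abs(diff(x)))
  for (seed in c(1, 7, 21)) {
    wb <- bounded_smoothed_walk(walk_config("baseline", std = 1), seed)
    ww <- bounded_smoothed_walk(walk_config("residual_water", std = 1), seed)
    expect_lt(tv(wb), tv(ww))
  }
})

test_that("complex completion yields the Hilbert (dispersion) partner", {
  # zero in, zero out
  expect_identical(make_complex_nuisance(numeric(32)),
                   complex(real = numeric(32), imaginary = numeric(32)))

  # Lorentzian absorption -> dispersion closed-form pair, away from the edges
  f <- seq(-300, 300, length.out = 2048)
  gam <- 3
  absn <- gam / (gam^2 + f^2)
  disp <- f / (gam^2 + f^2)
  q <- make_complex_nuisance(absn)
  i <- abs(f) < 180
  expect_lt(max(abs(Im(q)[i] - disp[i])) / max(abs(disp)), 0.02)

  # two quarter turns = half turn: quadrature twice negates the curve
  k <- 0:127  # integer cycle counts: no DC or Nyquist content to annihilate
  x <- sin(2 * pi * 3 * k / 128) + 0.3 * cos(2 * pi * 10 * k / 128)
  qq <- mrsforge:::quadrature_partner(mrsforge:::quadrature_partner(x))
  expect_equal(qq, -x, tolerance = 1e-10)
})

test_that("resampling maps spans onto the grid and round-trips smooth curves", {
  target <- seq(0, 10, length.out = 501)
  # identical axes: identity
  x <- seq(0, 10, length.out = 501)
  curve <- exp(-(x - 5)^2)
  expect_equal(resample_to_grid(curve, c(0, 10), target), curve, tolerance = 1e-12)

  # constant curve: constant on overlap, zero outside the span
  out <- resample_to_grid(rep(2, 101), c(2, 4), target)
  expect_true(all(out[target >= 2 & target <= 4] == 2))
  expect_true(all(out[target < 2 | target > 4] == 0))

  # downsample-then-upsample of a smooth curve: relative L2 error < 1%
  fine <- seq(1, 9, length.out = 801)
  smooth <- exp(-(fine - 4)^2 / 2) + 0.5 * sin(fine)
  coarse <- resample_to_grid(smooth, c(1, 9), seq(1, 9, length.out = 401))
  back <- resample_to_grid(coarse, c(1, 9), fine)
  expect_lt(sqrt(sum((back - smooth)^2) / sum(smooth^2)), 0.01)

  expect_error(resample_to_grid(1:10, c(20, 30), seq(0, 10, length.out = 11)),
               "overlap")
})

test_that("nuisance scaling matches magnitude to the spectrum", {
  curve <- complex(real = c(0.1, -0.4, 0.2), imaginary = c(0, 0.3, -0.1))
  out <- scale_nuisance(curve, spectrum_max = 2, scale = 0.5)
  expect_equal(max(Mod(out)), 1, tolerance = 1e-12)
  expect_identical(scale_nuisance(curve, 2, 0), curve * 0)
  expect_equal(scale_nuisance(curve, 2, 1), 2 * scale_nuisance(curve, 2, 0.5),
               tolerance = 1e-12)
  expect_error(scale_nuisance(curve * 0, 2, 0.5), "all-zero")
})
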