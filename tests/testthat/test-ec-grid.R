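test_that("module occupancy follows the stated population fractions", {
  pop <- sample_grid_population(900, seed = 1)
  counts <- tabulate(vapply(pop, `[[`, integer(1), "module"), nbins = 4)
  expected <- 900 * c(0.435, 0.435, 0.065, 0.065)
  # within 4 binomial standard deviations of the expectation
  sds <- sqrt(900 * c(.435, .435, .065, .065) * (1 - c(.435, .435, .065, .065)))
  expect_true(all(abs(counts - expected) < 4 * sds))
})

test_that("field radius is exactly 0.32 lambda and fields never overlap", {
  pop <- sample_grid_population(50, seed = 2)
  for (cell in pop) {
    expect_identical(cell$radius, 0.32 * cell$spacing)
    d <- dist(cell$centers)
    expect_gt(min(d), 2 * cell$radius)  # lattice spacing lambda > 0.64 lambda
  }
})

test_that("sampled temporal parameters follow the stated uniform laws", {
  pop <- sample_grid_population(2000, seed = 3)
  kphi <- vapply(pop, `[[`, numeric(1), "kphi")
  phi0 <- vapply(pop, `[[`, numeric(1), "phi0")
  dphi <- vapply(pop, `[[`, numeric(1), "dphi")
  expect_true(all(kphi >= 0.8 & kphi <= 1.2))
  expect_lt(abs(mean(kphi) - 1), 0.01)        # mean of U[0.8, 1.2]
  expect_lt(abs(sd(kphi) - 0.4 / sqrt(12)), 0.01)
  expect_true(all(phi0 >= 300 & phi0 <= 340))
  expect_true(all(dphi >= 300 & dphi <= 340))
  expect_true(all(vapply(pop, `[[`, numeric(1), "freq") == 10))
  expect_true(all(vapply(pop, function(cl) min(cl$amplitudes), numeric(1)) > 0))
})

test_that("spatial rate follows the truncated exponential bump", {
  cell <- make_grid_cell(spacing = 0.5, orientation = 12,
                         offset = c(0.21, 0.34), amplitude = 1.3)
  ctr <- cell$centers[which.min((cell$centers[, 1] - 0.5)^2 +
                                  (cell$centers[, 2] - 0.5)^2), ]
  expect_equal(grid_spatial_rate(cell, ctr), 1.3)
  R <- cell$radius
  expect_equal(grid_spatial_rate(cell, ctr + c(R - 1e-12, 0)), 1.3 / 5,
               tolerance = 1e-6)
  expect_identical(grid_spatial_rate(cell, ctr + c(R * 1.01, 0)), 0)
})

test_that("phase falls linearly from phi0 to phi0 - dphi along a center pass", {
  cell <- make_grid_cell(spacing = 0.5, phi0 = 320, dphi = 300,
                         offset = c(0.5, 0.5))
  ctr <- c(0.5, 0.5)
  R <- cell$radius  # 0.16 m
  eps <- 1e-9
  expect_equal(grid_phase(cell, ctr - c(R - eps, 0), 0), 320,
               tolerance = 1e-5)
  expect_equal(grid_phase(cell, ctr, 0), 170)  # phi0 - dphi/2
  expect_equal(grid_phase(cell, ctr + c(R - eps, 0), 0), (320 - 300) %% 360,
               tolerance = 1e-5)
  # exact linearity: Pearson correlation -1
  xs <- seq(0.5 - R + 0.005, 0.5 + R - 0.005, by = 0.01)
  ph <- vapply(xs, function(x) grid_phase(cell, c(x, 0.5), 0), numeric(1))
  expect_equal(cor(xs, ph), -1, tolerance = 1e-12)
  expect_error(grid_phase(cell, ctr + c(2 * R, 0), 0), "outside")
  expect_error(grid_phase(cell, ctr + c(0, R * (1 - 1e-14)), 0), "chord")
})

test_that("spatiotemporal response is the spatial rate times theta modulation", {
  cell0 <- make_grid_cell(spacing = 0.5, kphi = 0, offset = c(0.5, 0.5))
  r <- c(0.55, 0.52)
  for (t in c(0, 0.037, 0.8))
    expect_equal(grid_response(cell0, r, t, 0), grid_spatial_rate(cell0, r))
  cell <- make_grid_cell(spacing = 0.5, kphi = 1, offset = c(0.5, 0.5))
  expect_equal(grid_response(cell, r, 0.123, 1), grid_response(cell, r, 0.223, 1))
  tt <- seq(0, 0.0999, by = 1e-4)
  resp <- vapply(tt, function(t) grid_response(cell, r, t, 0), numeric(1))
  fs <- grid_spatial_rate(cell, r)
  expect_equal(max(resp), fs, tolerance = 1e-5)
  expect_equal(min(resp), fs * exp(-2 * 1), tolerance = 1e-5)
})

test_that("phase is invariant under joint translation and rotation", {
  cell <- make_grid_cell(spacing = 0.5, offset = c(0.3, 0.4))
  ctr <- cell$centers[which.min(rowSums((cell$centers -
                                           rep(c(.5, .5), each = nrow(cell$centers)))^2)), ]
  r <- ctr + c(0.05, -0.03)
  h <- 0.7
  ph0 <- grid_phase(cell, r, h)
  # translate the whole construction by one lattice vector: same phase
  a1 <- cell$spacing * c(cos(cell$orientation * pi / 180),
                         sin(cell$orientation * pi / 180))
  expect_equal(grid_phase(cell, r + a1, h), ph0, tolerance = 1e-8)
  # rotate lattice, position and heading jointly by 25 degrees about origin
  psi <- 25 * pi / 180
  Rot <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2)
  cell_rot <- make_grid_cell(spacing = 0.5, orientation = 25,
                             offset = drop(Rot %*% c(0.3, 0.4)))
  expect_equal(grid_phase(cell_rot, drop(Rot %*% r), h + psi), ph0,
               tolerance = 1e-6)
})

test_that("rate maps are periodic under lattice-vector offset shifts", {
  base <- make_grid_cell(spacing = 0.4, orientation = 17, offset = c(0.1, 0.2))
  a1 <- 0.4 * c(cos(17 * pi / 180), sin(17 * pi / 180))
  shifted <- make_grid_cell(spacing = 0.4, orientation = 17,
                            offset = c(0.1, 0.2) + a1)
  pts <- expand.grid(x = seq(0.05, 0.95, by = 0.06),
                     y = seq(0.05, 0.95, by = 0.06))
  r1 <- apply(pts, 1, function(p) grid_spatial_rate(base, p))
  r2 <- apply(pts, 1, function(p) grid_spatial_rate(shifted, p))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("the vectorized evaluator matches the scalar reference exactly", {
  set.seed(4)
  pop <- sample_grid_population(5, seed = 4)
  xs <- runif(300); ys <- runif(300); ts <- runif(300, 0, 2)
  hs <- runif(300, 0, 2 * pi)
  bulk <- grid_population_rates(pop, xs, ys, ts, hs)
  for (k in seq_along(pop)) {
    ref <- mapply(function(x, y, t, h) grid_response(pop[[k]], c(x, y), t, h),
                  xs, ys, ts, hs)
    expect_equal(bulk[k, ], unname(ref), tolerance = 1e-12)
  }
})
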