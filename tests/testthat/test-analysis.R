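test_that("binning averages responses per visited bin", {
  # 3 samples falling in 2 bins of a 40x40 lattice: hand-computed means
  S <- matrix(c(1, 2, 4), nrow = 1)
  x <- c(0.01, 0.02, 0.90)   # bins (1,1), (1,1), (37,19)
  y <- c(0.01, 0.015, 0.46)
  rm <- bin_responses(S, x, y)
  expect_equal(rm$maps[1, 1, 1], mean(c(1, 2)))
  expect_equal(rm$maps[37, 19, 1], 4)
  expect_equal(rm$occupancy[1, 1], 2)
  expect_equal(sum(rm$occupancy), 3)
  expect_true(is.na(rm$maps[2, 2, 1]))
  expect_equal(dim(rm$maps), c(40, 40, 1))
})

test_that("a constant unit fills every visited bin with its rate", {
  tr <- simulate_trajectory(trajectory_params(duration = 60, seed = 1))
  S <- matrix(1, nrow = 1, ncol = nrow(tr))
  rm <- bin_responses(S, tr$x, tr$y)
  visited <- rm$occupancy > 0
  expect_true(all(rm$maps[, , 1][visited] == 1))
  expect_true(all(is.na(rm$maps[, , 1][!visited])))
})

test_that("the spatial fit recovers noiseless bump parameters", {
  bc <- (1:40 - 0.5) * 0.025
  g <- outer(bc, bc, function(x, y)
    2 * exp(-log(5) * ((x - 0.5)^2 + (y - 0.5)^2) / 0.10^2))
  fit <- fit_spatial_field(g, 0.025)
  expect_equal(fit$amplitude, 2, tolerance = 1e-3)
  expect_equal(fit$cx, 0.5, tolerance = 1e-3)
  expect_equal(fit$cy, 0.5, tolerance = 1e-3)
  expect_equal(fit$radius, 0.10, tolerance = 1e-3)
  expect_lt(fit$fit_error, 1e-6)
})

test_that("degenerate maps are flagged rather than fitted", {
  z <- matrix(0, 40, 40)
  fit <- fit_spatial_field(z)
  expect_false(fit$converged)
  expect_equal(fit$amplitude, 0)
  few <- matrix(NA_real_, 40, 40); few[1:5] <- 1
  expect_false(fit_spatial_field(few)$converged)
})

test_that("a two-bump map cannot be fitted by a single field", {
  bc <- (1:40 - 0.5) * 0.025
  g <- outer(bc, bc, function(x, y)
    exp(-log(5) * ((x - 0.25)^2 + (y - 0.25)^2) / 0.08^2) +
      exp(-log(5) * ((x - 0.75)^2 + (y - 0.75)^2) / 0.08^2))
  fit <- fit_spatial_field(g, 0.025)
  expect_gt(fit$fit_error, 0.4)   # rejected by the error criterion
})

test_that("place-cell selection applies the three criteria", {
  fits <- data.frame(
    cell = 1:5,
    amplitude = 1,
    cx = c(0.5, 1.05, 0.5, 0.5, 0.12),
    cy = c(0.5, 0.5, 0.5, 0.5, 0.95),
    radius = c(0.04, 0.08, 0.08, 0.08, 0.08),
    fit_error = c(0.1, 0.1, 0.39, 0.41, 0.1),
    converged = TRUE)
  sel <- select_place_cells(fits)
  expect_identical(sel$place, c(3L, 5L))  # small radius, outside center,
                                          # and large error all rejected
  expect_identical(sel$fully_inside, 3L)  # cell 5's disc crosses the wall
})

test_that("the temporal fit recovers known spatiotemporal parameters", {
  tt <- seq(0, 0.99, by = 0.01)
  v <- 2.68 * exp(0.69 * (cos(2 * pi * 10 * tt - 177.77 * pi / 180) - 1))
  fit <- fit_temporal_response(tt, v)
  expect_equal(fit$amplitude, 2.68, tolerance = 1e-3)
  expect_equal(fit$kphi, 0.69, tolerance = 1e-3)
  expect_equal(fit$freq, 10, tolerance = 1e-3)
  expect_equal(fit$phase, 177.77, tolerance = 1e-2)
  expect_lt(fit$fit_error, 1e-10)
  # wrap equivalence: 0 and 360 degrees describe the same response
  v0 <- 1.5 * exp(0.8 * (cos(2 * pi * 10 * tt) - 1))
  f0 <- fit_temporal_response(tt, v0)
  expect_true(min(f0$phase, 360 - f0$phase) < 1e-2)
})

test_that("flat traces are marked phase-invalid", {
  tt <- seq(0, 0.99, by = 0.01)
  fit <- fit_temporal_response(tt, rep(1.3, 100))
  expect_false(fit$valid)
  expect_true(is.na(fit$phase))
  expect_false(fit_temporal_response(tt, rep(0, 100))$valid)
  expect_error(fit_temporal_response(0.1, 1), "two periods")
})

test_that("normalized pdcd maps a chord to [0, 1]", {
  ctr <- c(0.5, 0.5); R <- 0.1; eps <- 1e-9
  # straight pass through the center
  expect_equal(normalized_pdcd(ctr - c(R - eps, 0), 0, ctr, R), 0,
               tolerance = 1e-6)
  expect_equal(normalized_pdcd(ctr, 0, ctr, R), 0.5)
  expect_equal(normalized_pdcd(ctr + c(R - eps, 0), 0, ctr, R), 1,
               tolerance = 1e-6)
  # off-center chord at perpendicular offset R/2 spans the same range
  Rp <- sqrt(R^2 - (R / 2)^2)
  expect_equal(normalized_pdcd(ctr + c(-Rp + eps, R / 2), 0, ctr, R), 0,
               tolerance = 1e-4)
  expect_equal(normalized_pdcd(ctr + c(Rp - eps, R / 2), 0, ctr, R), 1,
               tolerance = 1e-4)
  # reversing the heading maps x to 1 - x
  r <- ctr + c(0.03, 0.02)
  expect_equal(normalized_pdcd(r, pi, ctr, R),
               1 - normalized_pdcd(r, 0, ctr, R))
  expect_error(normalized_pdcd(ctr + c(0.2, 0), 0, ctr, R), "outside")
})

test_that("normalized pdcd increases monotonically along straight segments", {
  set.seed(2)
  for (i in 1:20) {
    ctr <- runif(2, 0.3, 0.7); R <- runif(1, 0.05, 0.2)
    h <- runif(1, 0, 2 * pi)
    c_off <- runif(1, -0.9, 0.9) * R
    u <- c(cos(h), sin(h)); perp <- c(-sin(h), cos(h))
    Rp <- sqrt(R^2 - c_off^2)
    d <- seq(-Rp * 0.99, Rp * 0.99, length.out = 25)
    vals <- vapply(d, function(dd)
      normalized_pdcd(ctr + dd * u + c_off * perp, h, ctr, R), numeric(1))
    expect_true(all(diff(vals) > 0))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("a relay unit reproduces the generative periodicity at a field", {
  relay <- single_cell_relay()
  tr <- response_trace_at(relay$model, relay$pop, c(0.5, 0.5), 0)
  expect_length(tr$times, 100)
  # period 0.1 s at the 10 ms cadence: once the leaky-integrator start-up
  # transient has decayed, every 10th sample repeats
  expect_equal(tr$S[1, 41:90], tr$S[1, 51:100], tolerance = 1e-4)
  expect_gt(max(tr$S[1, ]), 0)
  fit <- fit_temporal_response(tr$times, tr$S[1, ])
  expect_equal(fit$freq, 10, tolerance = 0.02)
  # far from every field the trace is identically zero
  far <- response_trace_at(relay$model, relay$pop, c(0.95, 0.95), 0)
  expect_true(all(far$S == 0))
})

test_that("phase precession measurement recovers the built-in precession", {
  relay <- single_cell_relay()
  fit <- data.frame(cell = 1, amplitude = 1, cx = 0.5, cy = 0.5,
                    radius = 0.12, fit_error = 0, converged = TRUE)
  p <- measure_precession(relay$model, relay$pop, 1, fit, seed = 3)
  expect_gte(p$n_samples, 5)
  expect_false(p$wrapped)
  expect_lt(p$correlation, -0.99)   # built-in precession is linear in pdcd
  expect_gt(p$entry_phase, p$exit_phase)
  expect_true(all(p$pdcd >= 0 & p$pdcd <= 1))
  # fields touching the wall are not measurable
  bad <- fit; bad$cx <- 0.05
  expect_error(measure_precession(relay$model, relay$pop, 1, bad),
               "entirely inside")
})
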