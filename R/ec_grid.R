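#' Default grid-module specification
#'
#' Four discrete grid modules with mean spacings 38.8, 48.4, 65 and 98.4 cm,
#' mean orientations 15, 30, 45 and 0 degrees, making up 43.5%, 43.5%, 6.5%
#' and 6.5% of the grid-cell population.  Within a module, each cell's
#' spacing is drawn from a normal distribution with s.d. 8 cm and its
#' orientation from a normal distribution with s.d. 3 degrees.
#'
#' @return a `data.frame` with one row per module and columns
#'   `mean_spacing` (m), `spacing_sd` (m), `mean_orientation` (deg),
#'   `orientation_sd` (deg), `fraction`.
#' @export
default_grid_modules <- function() {
  data.frame(mean_spacing = c(0.388, 0.484, 0.65, 0.984),
             spacing_sd = 0.08,
             mean_orientation = c(15, 30, 45, 0),
             orientation_sd = 3,
             fraction = c(0.435, 0.435, 0.065, 0.065))
}

# enumerate triangular-lattice field centers covering the arena plus a
# margin >= R, and attach one amplitude per field
.build_grid_lattice <- function(spacing, orient_rad, offset, radius,
                                arena_size) {
  a1 <- spacing * c(cos(orient_rad), sin(orient_rad))
  a2 <- spacing * c(cos(orient_rad + pi / 3), sin(orient_rad + pi / 3))
  B <- cbind(a1, a2)
  lo <- -radius - 1e-9
  hi <- arena_size + radius + 1e-9
  corners <- rbind(c(lo, lo), c(lo, hi), c(hi, lo), c(hi, hi))
  f <- t(solve(B, t(corners) - offset))
  imin <- floor(min(f[, 1])) - 1L; imax <- ceiling(max(f[, 1])) + 1L
  jmin <- floor(min(f[, 2])) - 1L; jmax <- ceiling(max(f[, 2])) + 1L
  ij <- expand.grid(i = imin:imax, j = jmin:jmax)
  cx <- offset[1] + ij$i * a1[1] + ij$j * a2[1]
  cy <- offset[2] + ij$i * a1[2] + ij$j * a2[2]
  keep <- cx >= lo & cx <= hi & cy >= lo & cy <= hi
  amp_mat <- matrix(NA_real_, nrow = imax - imin + 1L,
                    ncol = jmax - jmin + 1L)
  list(imin = imin, jmin = jmin, amp_mat = amp_mat,
       keep_i = ij$i[keep], keep_j = ij$j[keep],
       centers = cbind(x = cx[keep], y = cy[keep]))
}

#' Sample a population of spatiotemporal grid cells
#'
#' Each cell is assigned to a module with the stated probabilities, then its
#' spacing \eqn{\lambda} ~ N(module mean, 8 cm) (non-positive draws
#' resampled), orientation ~ N(module mean, 3 deg), spatial offset ~
#' U\[0, \eqn{\lambda})^2, per-field amplitude ~ N(1, 0.1) (non-positive
#' draws resampled), phase-modulation depth \eqn{k_\phi} ~ U\[0.8, 1.2\],
#' entry phase \eqn{\phi_0} and phase change \eqn{\Delta\phi} ~
#' U\[300, 340\] degrees, theta frequency 10 Hz, and field radius
#' \eqn{R = 0.32\lambda} (so neighboring fields never overlap).  Field
#' centers are the triangular-lattice vertices covering the arena expanded
#' by \eqn{R}, so edge fields contribute partial in-arena responses.
#'
#' @param n_cells number of grid cells.
#' @param modules module table as from [default_grid_modules()].
#' @param kphi_range,phi0_range,dphi_range uniform sampling ranges for
#'   \eqn{k_\phi} (unitless) and the phase parameters (degrees).
#' @param theta_freq theta frequency in Hz (default 10).
#' @param arena_size arena side length, m.
#' @param seed integer seed or `NULL`.
#' @return an object of class `grid_population`: a list of cells, each with
#'   fields `spacing`, `orientation` (deg), `offset`, `radius`, `centers`,
#'   `amplitudes`, `kphi`, `phi0`, `dphi`, `freq` plus the amplitude lookup
#'   lattice used by the fast evaluator.
#' @export
sample_grid_population <- function(n_cells,
                                   modules = default_grid_modules(),
                                   kphi_range = c(0.8, 1.2),
                                   phi0_range = c(300, 340),
                                   dphi_range = c(300, 340),
                                   theta_freq = 10,
                                   arena_size = 1,
                                   seed = NULL) {
  if (n_cells <= 0) stop("n_cells must be positive")
  if (nrow(modules) == 0) stop("at least one grid module is required")
  if (abs(sum(modules$fraction) - 1) > 1e-8)
    stop("module fractions must sum to 1")
  with_seed(seed, {
    mod_idx <- sample.int(nrow(modules), n_cells, replace = TRUE,
                          prob = modules$fraction)
    cells <- vector("list", n_cells)
    for (k in seq_len(n_cells)) {
      m <- modules[mod_idx[k], ]
      spacing <- -1
      while (spacing <= 0) spacing <- rnorm(1, m$mean_spacing, m$spacing_sd)
      orientation <- rnorm(1, m$mean_orientation, m$orientation_sd)
      offset <- runif(2, 0, spacing)
      radius <- 0.32 * spacing
      lat <- .build_grid_lattice(spacing, orientation * pi / 180, offset,
                                 radius, arena_size)
      nf <- nrow(lat$centers)
      amps <- rnorm(nf, 1, 0.1)
      while (any(amps <= 0)) amps[amps <= 0] <- rnorm(sum(amps <= 0), 1, 0.1)
      lat$amp_mat[cbind(lat$keep_i - lat$imin + 1L,
                        lat$keep_j - lat$jmin + 1L)] <- amps
      cells[[k]] <- list(spacing = spacing, orientation = orientation,
                         offset = offset, radius = radius, module = mod_idx[k],
                         centers = lat$centers, amplitudes = amps,
                         amp_mat = lat$amp_mat, imin = lat$imin,
                         jmin = lat$jmin,
                         kphi = runif(1, kphi_range[1], kphi_range[2]),
                         phi0 = runif(1, phi0_range[1], phi0_range[2]),
                         dphi = runif(1, dphi_range[1], dphi_range[2]),
                         freq = theta_freq)
    }
    structure(cells, arena_size = arena_size, class = "grid_population")
  })
}

#' Construct a single grid cell with explicit parameters
#'
#' Convenience constructor (bypassing population sampling) used for worked
#' examples and for the reference cell with \eqn{k_\phi = 1},
#' \eqn{\phi_0 = 320} deg, \eqn{\Delta\phi = 300} deg, \eqn{R = 0.16} m.
#' All field amplitudes are set to `amplitude`.
#'
#' @param spacing grid spacing \eqn{\lambda} in m; the field radius is
#'   `0.32 * spacing`.
#' @param orientation lattice orientation, degrees.
#' @param offset length-2 spatial offset in m.
#' @param kphi,phi0,dphi,freq temporal parameters (unitless, deg, deg, Hz).
#' @param amplitude common field amplitude.
#' @param arena_size arena side length, m.
#' @return a single-cell list in the `grid_population` cell layout.
#' @export
make_grid_cell <- function(spacing = 0.5, orientation = 0, offset = c(0, 0),
                           kphi = 1, phi0 = 320, dphi = 300, freq = 10,
                           amplitude = 1, arena_size = 1) {
  radius <- 0.32 * spacing
  lat <- .build_grid_lattice(spacing, orientation * pi / 180, offset,
                             radius, arena_size)
  nf <- nrow(lat$centers)
  amps <- rep(amplitude, nf)
  lat$amp_mat[cbind(lat$keep_i - lat$imin + 1L,
                    lat$keep_j - lat$jmin + 1L)] <- amps
  list(spacing = spacing, orientation = orientation, offset = offset,
       radius = radius, module = NA_integer_, centers = lat$centers,
       amplitudes = amps, amp_mat = lat$amp_mat, imin = lat$imin,
       jmin = lat$jmin, kphi = kphi, phi0 = phi0, dphi = dphi, freq = freq)
}

.nearest_field <- function(cell, r) {
  d2 <- (cell$centers[, 1] - r[1])^2 + (cell$centers[, 2] - r[2])^2
  k <- which.min(d2)
  list(index = k, center = cell$centers[k, ], dist2 = d2[k])
}

#' Spatial firing rate of a grid cell
#'
#' Within distance \eqn{R} of the nearest field center \eqn{r_c} the rate is
#' \eqn{\alpha_c \exp(-\ln 5\, \|r - r_c\|^2 / R^2)} (so the rate at
#' distance \eqn{R} is \eqn{\alpha_c/5}); beyond \eqn{R} the rate is zero.
#'
#' @param cell one grid cell.
#' @param r position, length-2 (m).
#' @return non-negative firing rate.
#' @export
grid_spatial_rate <- function(cell, r) {
  nf <- .nearest_field(cell, r)
  if (nf$dist2 >= cell$radius^2) return(0)
  amp <- cell$amplitudes[nf$index]
  amp * exp(-log(5) * nf$dist2 / cell$radius^2)
}

#' Firing phase of a grid cell at a position and running direction
#'
#' The phase falls linearly with the projected distance along the current
#' running direction (pdcd) across the chord through the field: with
#' \eqn{d} the signed projection of \eqn{r - r_c} onto the unit heading,
#' \eqn{c} the perpendicular offset of the running line from the field
#' center and \eqn{R' = \sqrt{R^2 - c^2}} the half-chord length, the phase
#' is \eqn{\phi_0 - \Delta\phi\,(d + R')/(2R')}, reported modulo 360 in
#' \[0, 360) degrees.  Entry (at \eqn{d = -R'}) gives \eqn{\phi_0}; exit
#' gives \eqn{\phi_0 - \Delta\phi}.
#'
#' @param cell one grid cell.
#' @param r position, length-2 (m); must lie inside a field.
#' @param heading running direction: either an angle in radians or a
#'   length-2 vector (normalized internally).
#' @return phase in degrees, in \[0, 360).
#' @export
grid_phase <- function(cell, r, heading) {
  if (length(heading) == 1) heading <- c(cos(heading), sin(heading))
  nh <- sqrt(sum(heading^2))
  if (nh == 0) stop("heading must be non-zero")
  u <- heading / nh
  nf <- .nearest_field(cell, r)
  if (nf$dist2 >= cell$radius^2)
    stop("position lies outside every firing field of this cell")
  dr <- r - nf$center
  d <- sum(dr * u)
  cperp <- -dr[1] * u[2] + dr[2] * u[1]
  R2p <- cell$radius^2 - cperp^2
  if (R2p <= 1e-12 * cell$radius^2)
    stop("degenerate chord: the running line is tangent to the field")
  Rp <- sqrt(R2p)
  unname((cell$phi0 - cell$dphi * (d + Rp) / (2 * Rp)) %% 360)
}

#' Spatiotemporal firing rate of a grid cell
#'
#' Product of the spatial rate and the phase modulation
#' \eqn{\exp(k_\phi(\cos(2\pi F t - \phi(r)) - 1))}; zero outside fields,
#' and equal to the spatial rate when \eqn{k_\phi = 0}.
#'
#' @inheritParams grid_phase
#' @param t time in seconds.
#' @return non-negative firing rate.
#' @export
grid_response <- function(cell, r, t, heading) {
  fs <- grid_spatial_rate(cell, r)
  if (fs == 0) return(0)
  if (cell$kphi == 0) return(fs)
  phi <- grid_phase(cell, r, heading) * pi / 180
  fs * exp(cell$kphi * (cos(2 * pi * cell$freq * t - phi) - 1))
}

# bulk evaluation of one cell at many samples (C++ path)
.grid_cell_rates <- function(cell, x, y, t, hx, hy, spatial_only = FALSE) {
  grid_rates_cpp(cell$spacing, cell$orientation * pi / 180,
                 cell$offset[1], cell$offset[2],
                 cell$amp_mat, cell$imin, cell$jmin,
                 cell$kphi, cell$phi0, cell$dphi, cell$freq, cell$radius,
                 x, y, t, hx, hy, spatial_only)
}

#' Firing rates of a grid population along a sample sequence
#'
#' @param population a `grid_population`.
#' @param x,y positions (m), vectors of equal length.
#' @param t times (s).
#' @param heading headings in radians (recycled to length of `x`).
#' @param spatial_only if `TRUE`, omit the phase modulation.
#' @return matrix `length(population) x length(x)` of firing rates.
#' @export
grid_population_rates <- function(population, x, y, t, heading,
                                  spatial_only = FALSE) {
  n <- length(x)
  heading <- rep_len(heading, n)
  t <- rep_len(t, n)
  hx <- cos(heading); hy <- sin(heading)
  out <- matrix(0, nrow = length(population), ncol = n)
  for (k in seq_along(population))
    out[k, ] <- .grid_cell_rates(population[[k]], x, y, t, hx, hy,
                                 spatial_only)
  out
}
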