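#' Bin per-sample responses into occupancy-averaged rate maps
#'
#' @param S response matrix, `n_cells x n_samples`.
#' @param x,y sample positions (m).
#' @param n_bins bins per side (default 40, i.e. 2.5 cm bins in a 1 m
#'   arena).
#' @param arena_size arena side length, m.
#' @return an object of class `rate_maps`: a list with `maps`
#'   (`n_bins x n_bins x n_cells` array, first index along x), `occupancy`
#'   (`n_bins x n_bins` visit counts; bins with count 0 are unvisited and
#'   hold `NA` in the maps), and `bin_size`.
#' @export
bin_responses <- function(S, x, y, n_bins = 40, arena_size = 1) {
  h <- arena_size / n_bins
  ix <- pmin(pmax(floor(x / h) + 1L, 1L), n_bins)
  iy <- pmin(pmax(floor(y / h) + 1L, 1L), n_bins)
  bin <- (iy - 1L) * n_bins + ix
  counts <- tabulate(bin, nbins = n_bins^2)
  sums <- rowsum(t(S), bin, reorder = FALSE)
  n_cells <- nrow(S)
  maps <- array(NA_real_, dim = c(n_bins, n_bins, n_cells))
  visited <- counts > 0
  flat <- matrix(NA_real_, n_bins^2, n_cells)
  flat[as.integer(rownames(sums)), ] <- sums / counts[as.integer(rownames(sums))]
  for (k in seq_len(n_cells)) maps[, , k] <- matrix(flat[, k], n_bins, n_bins)
  structure(list(maps = maps, occupancy = matrix(counts, n_bins, n_bins),
                 bin_size = h, arena_size = arena_size),
            class = "rate_maps")
}

#' Recover rate maps of the modelled hippocampal cells
#'
#' Runs inference (no learning) along a test trajectory and averages each
#' cell's response over the samples falling in each bin of an
#' `n_bins x n_bins` lattice.
#'
#' @param model a trained `sparse_coding_model`.
#' @param population the `ec_population` used for training.
#' @param trajectory a test `rat_trajectory` (distinct from training).
#' @param n_bins bins per side (default 40).
#' @param chunk_size passed to [run_session()].
#' @return a `rate_maps` object.
#' @export
recover_rate_maps <- function(model, population, trajectory, n_bins = 40,
                              chunk_size = 20000L) {
  ses <- run_session(model, population, trajectory, learn = FALSE,
                     keep_s = TRUE, chunk_size = chunk_size)
  bin_responses(ses$S, trajectory$x, trajectory$y, n_bins = n_bins,
                arena_size = population$arena_size)
}

#' Fit a single-bump spatial receptive-field model to a rate map
#'
#' Nonlinear least squares of
#' \eqn{\hat f_s(r) = \hat\alpha_c \exp(-\ln 5\,\|r - \hat r_c\|^2 /
#' \hat R^2)} over the visited bins (unvisited bins are excluded, not
#' imputed).  The fitting error is the ratio of the summed squared residual
#' to the summed squared map.  Optimizer start: amplitude = map maximum,
#' center = arg-max bin, radius = 2 bins.
#'
#' @param map a `n_bins x n_bins` matrix (NA for unvisited bins).
#' @param bin_size bin side length, m.
#' @return a one-row `data.frame` with `amplitude`, `cx`, `cy`, `radius`
#'   (m), `fit_error`, `converged`.
#' @export
fit_spatial_field <- function(map, bin_size = 0.025) {
  n_bins <- nrow(map)
  centers <- (seq_len(n_bins) - 0.5) * bin_size
  df <- data.frame(x = rep(centers, times = n_bins),
                   y = rep(centers, each = n_bins),
                   z = as.vector(map))
  df <- df[is.finite(df$z), ]
  fail <- data.frame(amplitude = 0, cx = NA_real_, cy = NA_real_,
                     radius = NA_real_, fit_error = Inf, converged = FALSE)
  if (nrow(df) < 10) return(fail)
  ss <- sum(df$z^2)
  if (ss == 0)  # silent cell: degenerate flat fit
    return(data.frame(amplitude = 0, cx = NA_real_, cy = NA_real_,
                      radius = NA_real_, fit_error = 0, converged = FALSE))
  imax <- which.max(df$z)
  L <- n_bins * bin_size
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ a * exp(-log(5) * ((x - cx)^2 + (y - cy)^2) / r^2),
      data = df,
      start = list(a = max(df$z), cx = df$x[imax], cy = df$y[imax],
                   r = 2 * bin_size),
      lower = c(a = 0, cx = -L / 2, cy = -L / 2, r = bin_size / 10),
      upper = c(a = Inf, cx = 1.5 * L, cy = 1.5 * L, r = 2 * L),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  p <- coef(fit)
  data.frame(amplitude = p[["a"]], cx = p[["cx"]], cy = p[["cy"]],
             radius = p[["r"]], fit_error = sum(resid(fit)^2) / ss,
             converged = TRUE)
}

#' Fit spatial fields for every cell of a `rate_maps` object
#'
#' @param maps a `rate_maps` object.
#' @return a `data.frame`, one row per cell (column `cell` first).
#' @export
fit_all_spatial <- function(maps) {
  n_cells <- dim(maps$maps)[3]
  out <- do.call(rbind, lapply(seq_len(n_cells), function(k)
    fit_spatial_field(maps$maps[, , k], maps$bin_size)))
  cbind(cell = seq_len(n_cells), out)
}

#' Select place cells from spatial fits
#'
#' A modelled hippocampal cell is a place cell when (1) the fitted center
#' lies inside the arena, (2) the fitted radius exceeds `min_radius`
#' (default 5 cm), and (3) the fitting error is below `max_error`
#' (default 40%).  Also reports the subset whose entire fitted field (the
#' disc of radius \eqn{\hat R} around \eqn{\hat r_c}) lies inside the
#' arena, as required for phase-precession measurement.
#'
#' @param fits a `data.frame` as from [fit_all_spatial()].
#' @param arena_size arena side length, m.
#' @param min_radius minimum fitted radius, m (default 0.05).
#' @param max_error maximum fitting error (default 0.4).
#' @return a list with integer vectors `place` and `fully_inside`
#'   (cell indices; `fully_inside` is a subset of `place`).
#' @export
select_place_cells <- function(fits, arena_size = 1, min_radius = 0.05,
                               max_error = 0.4) {
  ok <- fits$converged &
    is.finite(fits$cx) & is.finite(fits$cy) &
    fits$cx >= 0 & fits$cx <= arena_size &
    fits$cy >= 0 & fits$cy <= arena_size &
    fits$radius > min_radius &
    fits$fit_error < max_error
  ok[is.na(ok)] <- FALSE
  inside <- ok &
    fits$cx - fits$radius >= 0 & fits$cx + fits$radius <= arena_size &
    fits$cy - fits$radius >= 0 & fits$cy + fits$radius <= arena_size
  list(place = fits$cell[ok], fully_inside = fits$cell[inside])
}

#' Response of model cells over time at a fixed location
#'
#' Holds the position and heading fixed, advances time at the trajectory
#' cadence (10 ms), feeds the time-varying EC rates through LCA inference
#' (membrane state carried across samples within the trace, starting from
#' zero), and records the responses.
#'
#' @param model a trained `sparse_coding_model`.
#' @param population the matching `ec_population`.
#' @param r fixed position, length-2 (m).
#' @param heading heading in radians (or a length-2 direction vector).
#' @param duration trace duration, s (default 1).
#' @param dt sample spacing, s (default 0.01).
#' @param t0 time of the first sample, s (default 0; phases are referenced
#'   to the common theta clock).
#' @return a list with `times` and `S` (`n_cells x n_samples`).
#' @export
response_trace_at <- function(model, population, r, heading, duration = 1,
                              dt = 0.01, t0 = 0) {
  if (length(heading) == 2) heading <- atan2(heading[2], heading[1])
  times <- t0 + seq(0, duration - dt / 2, by = dt)
  n <- length(times)
  I <- ec_rate_matrix(population, rep(r[1], n), rep(r[2], n), times,
                      rep(heading, n))
  res <- lca_run_cpp(model$A, I, numeric(model$n_cells), model$tau,
                     model$beta, model$dt_model, model$n_inner, 0,
                     FALSE, TRUE)
  list(times = times, S = res$S)
}

#' Fit the spatiotemporal response model to a 1 s trace
#'
#' Nonlinear least squares of
#' \eqn{\hat f(t) = \hat\alpha \exp(\hat k_\phi(\cos(2\pi\hat F t -
#' \hat\phi) - 1))}.  The fitting error is the ratio of the summed squared
#' residual to the summed squared trace; the fitted phase is reported in
#' degrees in \[0, 360).  Start values: amplitude = trace maximum,
#' \eqn{k_\phi} = 1, \eqn{F} = 10 Hz, phase from the arg-max sample time;
#' \eqn{F} is constrained to \[5, 20\] Hz.  A flat or silent trace is
#' flagged invalid (phase undefined).
#'
#' @param times sample times, s.
#' @param values non-negative response samples.
#' @param freq_start initial frequency guess, Hz (default 10).
#' @return a one-row `data.frame` with `amplitude`, `kphi`, `freq` (Hz),
#'   `phase` (deg), `fit_error`, `valid`.
#' @export
fit_temporal_response <- function(times, values, freq_start = 10) {
  stopifnot(length(times) == length(values))
  fail <- data.frame(amplitude = max(values, 0), kphi = 0, freq = NA_real_,
                     phase = NA_real_, fit_error = Inf, valid = FALSE)
  if (length(times) < 2 || diff(range(times)) < 2 / freq_start)
    stop("trace must cover at least two periods of the initial frequency")
  ss <- sum(values^2)
  if (ss == 0 || sd(values) < 1e-12 * max(abs(values), 1)) {
    fail$fit_error <- if (ss == 0) 0 else Inf
    return(fail)
  }
  tpk <- times[which.max(values)]
  start_phase <- (2 * pi * freq_start * tpk) %% (2 * pi)
  df <- data.frame(t = times, v = values)
  fit <- NULL
  # a start phase landing exactly on a sampling-degenerate point can give a
  # singular initial Jacobian; nudge the starts until the optimizer engages
  for (jit in list(c(0, 0), c(0.3, 0.02), c(-0.3, -0.02), c(1.0, 0.05))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ a * exp(k * (cos(2 * pi * f * t - p) - 1)),
        data = df,
        start = list(a = max(values), k = 1,
                     f = freq_start * (1 + jit[2]),
                     p = start_phase + jit[1]),
        lower = c(a = 0, k = 0, f = 5, p = -4 * pi),
        upper = c(a = Inf, k = 50, f = 20, p = 4 * pi),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(fail)
  p <- coef(fit)
  phase_deg <- (p[["p"]] * 180 / pi) %% 360
  valid <- p[["k"]] > 1e-3  # k ~ 0 means no temporal modulation: phase undefined
  data.frame(amplitude = p[["a"]], kphi = p[["k"]], freq = p[["f"]],
             phase = if (valid) phase_deg else NA_real_,
             fit_error = sum(resid(fit)^2) / ss, valid = valid)
}

#' Normalized projected distance along the current running direction
#'
#' Using the chord construction of the grid-cell phase model with the
#' fitted field (center, radius): with \eqn{d} the signed projection of
#' \eqn{r - \hat r_c} onto the unit heading and \eqn{R' =
#' \sqrt{\hat R^2 - c^2}} the half-chord (c = perpendicular offset of the
#' running line), returns \eqn{(d + R')/(2R') \in [0, 1]}: 0 at field
#' entry, 1 at exit, monotone along any straight in-field segment.
#'
#' @param r position, length-2 (m), inside the fitted field.
#' @param heading heading in radians (or a length-2 direction vector).
#' @param center fitted field center, length-2 (m).
#' @param radius fitted field radius, m.
#' @return unitless value in \[0, 1\].
#' @export
normalized_pdcd <- function(r, heading, center, radius) {
  if (length(heading) == 1) heading <- c(cos(heading), sin(heading))
  u <- heading / sqrt(sum(heading^2))
  dr <- r - center
  if (sum(dr^2) >= radius^2) stop("position lies outside the fitted field")
  d <- sum(dr * u)
  cperp <- -dr[1] * u[2] + dr[2] * u[1]
  R2p <- radius^2 - cperp^2
  if (R2p <= 1e-12 * radius^2)
    stop("degenerate chord: running line tangent to field")
  (d + sqrt(R2p)) / (2 * sqrt(R2p))
}

#' Measure theta phase precession of one learnt place cell
#'
#' A virtual rat enters the fitted field from its left side at the center
#' height, initially heading rightward, and follows a curved trajectory
#' with the standard foraging dynamics.  At every 10 ms position inside the
#' fitted field, the cell's response over 1 s at that fixed location is
#' generated and fitted with the spatiotemporal response model; the fitted
#' phase is recorded against the normalized pdcd at that sample.  The entry
#' (exit) phase is the fitted phase at the first (last) valid in-field
#' sample, and the precession strength is the Pearson correlation between
#' phase and normalized pdcd.  If the trajectory yields fewer than
#' `min_samples` in-field samples it is redrawn (bounded retries).  Phase
#' series that wrap through 0/360 mid-field (any +180 degree jump between
#' consecutive samples) are flagged `wrapped` and their correlation is not
#' interpretable as precession strength.
#'
#' @param model a trained `sparse_coding_model`.
#' @param population the matching `ec_population`.
#' @param cell index of the cell to analyze.
#' @param fit the cell's row from [fit_all_spatial()] (field must lie
#'   entirely inside the arena).
#' @param trajectory_params a [trajectory_params()] object providing the
#'   foraging dynamics (its duration is ignored); default standard.
#' @param seed integer seed for the measurement trajectory.
#' @param min_samples minimum in-field samples (default 5).
#' @param max_retries trajectory redraws allowed (default 20).
#' @return an object of class `precession_summary`: list with `pdcd`,
#'   `phases` (deg), `x`, `y`, `entry_phase`, `exit_phase`, `correlation`,
#'   `wrapped`, `n_samples`, `temporal_fits` (per-sample fit table).
#' @export
measure_precession <- function(model, population, cell, fit,
                               trajectory_params = NULL, seed = NULL,
                               min_samples = 5, max_retries = 20) {
  center <- c(fit$cx, fit$cy)
  radius <- fit$radius
  L <- population$arena_size
  if (any(center - radius < 0) || any(center + radius > L))
    stop("the fitted field must lie entirely inside the arena")
  if (is.null(trajectory_params))
    trajectory_params <- trajectory_params(duration = 1)
  # enough time to cross the field several times over
  cross_t <- max(4 * 2 * radius / trajectory_params$mean_speed, 1)
  base_seed <- if (is.null(seed)) sample.int(1e6, 1) else seed
  for (try in seq_len(max_retries)) {
    tp <- trajectory_params
    tp$duration <- cross_t
    tp$seed <- base_seed + (try - 1L) * 7919L
    traj <- simulate_trajectory(tp, start = c(center[1] - radius, center[2]),
                                start_heading = 0)
    d2 <- (traj$x - center[1])^2 + (traj$y - center[2])^2
    inside <- d2 < radius^2
    if (!any(inside)) next
    first_in <- which(inside)[1]
    after <- which(!inside & seq_len(nrow(traj)) > first_in)
    last_in <- if (length(after)) after[1] - 1L else nrow(traj)
    idx <- first_in:last_in
    idx <- idx[inside[idx]]
    if (length(idx) >= min_samples) {
      traj <- traj[idx, , drop = FALSE]
      break
    }
    traj <- NULL
  }
  if (is.null(traj))
    stop("could not generate a trajectory with enough in-field samples")
  n <- nrow(traj)
  pdcd <- phases <- numeric(n)
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    r <- c(traj$x[i], traj$y[i])
    pdcd[i] <- normalized_pdcd(r, traj$theta[i], center, radius)
    tr <- response_trace_at(model, population, r, traj$theta[i])
    fits[[i]] <- fit_temporal_response(tr$times, tr$S[cell, ])
  }
  fits <- do.call(rbind, fits)
  ok <- fits$valid
  res <- list(pdcd = pdcd[ok], phases = fits$phase[ok],
              x = traj$x[ok], y = traj$y[ok],
              entry_phase = NA_real_, exit_phase = NA_real_,
              correlation = NA_real_, wrapped = FALSE,
              n_samples = sum(ok), temporal_fits = fits)
  if (sum(ok) >= 2) {
    res$entry_phase <- res$phases[1]
    res$exit_phase <- res$phases[length(res$phases)]
    res$wrapped <- any(diff(res$phases) > 180)
    if (sd(res$phases) > 0 && sd(res$pdcd) > 0)
      res$correlation <- cor(res$pdcd, res$phases)
  }
  class(res) <- "precession_summary"
  res
}

#' @export
print.precession_summary <- function(x, ...) {
  cat("Phase precession summary:", x$n_samples, "in-field samples\n")
  cat(sprintf("  entry phase %.1f deg, exit phase %.1f deg\n",
              x$entry_phase, x$exit_phase))
  cat(sprintf("  phase vs normalized pdcd correlation: %.4f%s\n",
              x$correlation, if (isTRUE(x$wrapped)) " (phase wrap!)" else ""))
  invisible(x)
}

#' Write rate maps as delimited text
#'
#' One `<prefix>_cell<k>.tsv` per cell (40 x 40 grid, NA for unvisited
#' bins) plus `<prefix>_occupancy.tsv`.
#'
#' @param maps a `rate_maps` object.
#' @param prefix file-path prefix.
#' @export
write_rate_maps <- function(maps, prefix) {
  for (k in seq_len(dim(maps$maps)[3]))
    write.table(maps$maps[, , k], sprintf("%s_cell%03d.tsv", prefix, k),
                sep = "\t", row.names = FALSE, col.names = FALSE)
  write.table(maps$occupancy, paste0(prefix, "_occupancy.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
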