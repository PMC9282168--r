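#' Parameters of the random-foraging trajectory
#'
#' The virtual rat's path follows
#' \deqn{dr_t/dt = v_t [\cos\theta_t, \sin\theta_t],}
#' where the heading \eqn{\theta_t} is a Wiener process with tortuosity
#' \eqn{\sigma_\theta} (increments \eqn{N(0, \sigma_\theta^2\,dt)}) and the
#' speed \eqn{v_t} follows an Ornstein--Uhlenbeck process with long-term
#' mean `mean_speed`, relaxation time `speed_relax_time` and stationary
#' standard deviation `speed_noise_sd`, clipped at zero.  Within
#' `wall_margin` of a wall while heading into it, the heading is replaced by
#' the wall-parallel direction nearer the current heading (perpendicular
#' ties broken toward the arena center); a step that would leave the arena
#' has its heading increment redrawn (speed kept), up to 1000 attempts.
#'
#' @param duration trajectory duration in seconds.
#' @param sigma_theta tortuosity, radians (default 1).
#' @param mean_speed long-term mean running speed, m/s (default 0.30).
#' @param dt time step, s (default 0.01, i.e. 100 Hz).
#' @param arena_size side length of the square arena, m (default 1).
#' @param wall_margin wall-avoidance margin, m (default 0.02).
#' @param speed_relax_time OU relaxation time of the speed, s (default 0.5).
#' @param speed_noise_sd stationary s.d. of the OU speed, m/s (default 0.08).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an object of class `trajectory_params`.
#' @export
trajectory_params <- function(duration,
                              sigma_theta = 1,
                              mean_speed = 0.30,
                              dt = 0.01,
                              arena_size = 1,
                              wall_margin = 0.02,
                              speed_relax_time = 0.5,
                              speed_noise_sd = 0.08,
                              seed = NULL) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a positive number of seconds")
  if (dt <= 0) stop("dt must be positive")
  if (sigma_theta < 0) stop("sigma_theta must be non-negative")
  if (wall_margin >= arena_size / 2)
    stop("wall_margin must be smaller than half the arena size")
  structure(list(duration = duration, sigma_theta = sigma_theta,
                 mean_speed = mean_speed, dt = dt, arena_size = arena_size,
                 wall_margin = wall_margin,
                 speed_relax_time = speed_relax_time,
                 speed_noise_sd = speed_noise_sd, seed = seed),
            class = "trajectory_params")
}

# wall rule: close to a wall and heading into it -> heading parallel to the
# wall, choosing the parallel orientation nearer the current heading;
# perpendicular approaches break the tie toward the arena-center side
.apply_wall_rule <- function(x, y, th, L, margin) {
  ang_dist <- function(a, b) abs(atan2(sin(a - b), cos(a - b)))
  pick_parallel <- function(th, p1, p2, toward_center) {
    d1 <- ang_dist(th, p1); d2 <- ang_dist(th, p2)
    if (abs(d1 - d2) < 1e-12) toward_center else if (d1 < d2) p1 else p2
  }
  hpi <- pi / 2
  if (x < margin && cos(th) < 0)
    th <- pick_parallel(th, hpi, -hpi, if (y < L / 2) hpi else -hpi)
  if (x > L - margin && cos(th) > 0)
    th <- pick_parallel(th, hpi, -hpi, if (y < L / 2) hpi else -hpi)
  if (y < margin && sin(th) < 0)
    th <- pick_parallel(th, 0, pi, if (x < L / 2) 0 else pi)
  if (y > L - margin && sin(th) > 0)
    th <- pick_parallel(th, 0, pi, if (x < L / 2) 0 else pi)
  th
}

#' Simulate a random-foraging trajectory
#'
#' @param params a [trajectory_params()] object.
#' @param start optional starting position (length-2, m); defaults to the
#'   arena center.
#' @param start_heading optional initial heading in radians; defaults to a
#'   uniform random direction.
#' @return a `data.frame` of class `rat_trajectory` with columns
#'   `t`, `x`, `y`, `theta`, `speed`; one row every `dt` seconds
#'   (`duration/dt + 1` rows), all positions inside the arena.
#' @examples
#' tr <- simulate_trajectory(trajectory_params(duration = 10, seed = 1))
#' range(tr$x); mean(tr$speed)
#' @export
simulate_trajectory <- function(params, start = NULL, start_heading = NULL) {
  stopifnot(inherits(params, "trajectory_params"))
  with_seed(params$seed, {
    L <- params$arena_size
    dt <- params$dt
    n <- round(params$duration / dt) + 1L
    x <- y <- th <- v <- numeric(n)
    x[1] <- if (is.null(start)) L / 2 else start[1]
    y[1] <- if (is.null(start)) L / 2 else start[2]
    if (x[1] < 0 || x[1] > L || y[1] < 0 || y[1] > L)
      stop("start position lies outside the arena")
    th[1] <- if (is.null(start_heading)) runif(1, 0, 2 * pi) else start_heading
    v[1] <- params$mean_speed
    relax <- params$speed_relax_time
    # OU with stationary s.d. speed_noise_sd: dv = (v.bar - v) dt/relax
    #   + speed_noise_sd * sqrt(2 dt / relax) * N(0,1)
    ou_noise <- params$speed_noise_sd * sqrt(2 * dt / relax)
    sig_dw <- params$sigma_theta * sqrt(dt)
    for (i in 2:n) {
      vi <- v[i - 1] + (params$mean_speed - v[i - 1]) * dt / relax +
        ou_noise * rnorm(1)
      vi <- max(vi, 0)
      ok <- FALSE
      for (attempt in 1:1000) {
        ti <- th[i - 1] + sig_dw * rnorm(1)
        ti <- .apply_wall_rule(x[i - 1], y[i - 1], ti, L, params$wall_margin)
        nx <- x[i - 1] + vi * dt * cos(ti)
        ny <- y[i - 1] + vi * dt * sin(ti)
        if (nx >= 0 && nx <= L && ny >= 0 && ny <= L) { ok <- TRUE; break }
        if (params$sigma_theta == 0) break  # redrawing cannot help
      }
      if (!ok)
        stop("could not generate a valid step after 1000 resamples ",
             "(degenerate geometry near (", signif(x[i - 1], 3), ", ",
             signif(y[i - 1], 3), "))")
      x[i] <- nx; y[i] <- ny; th[i] <- ti; v[i] <- vi
    }
    out <- data.frame(t = (seq_len(n) - 1) * dt, x = x, y = y,
                      theta = th, speed = v)
    attr(out, "params") <- params
    class(out) <- c("rat_trajectory", "data.frame")
    out
  })
}

#' Write / read a trajectory as delimited text
#'
#' Columns `t, x, y, theta, speed`, tab-separated, with a header line.
#'
#' @param trajectory a `rat_trajectory` data frame.
#' @param path file path.
#' @return `read_trajectory` returns a `rat_trajectory` data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  write.table(as.data.frame(trajectory), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("t", "x", "y", "theta", "speed") %in% names(out)))
  class(out) <- c("rat_trajectory", "data.frame")
  out
}
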