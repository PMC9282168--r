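# 1-D Gaussian smoothing matrix with reflective boundary handling; the
# separable 2-D smoothing of an n x n lattice is K %*% M %*% t(K)
.gaussian_reflect_matrix <- function(n, sigma_cells) {
  half <- max(1L, ceiling(3 * sigma_cells))
  off <- -half:half
  w <- exp(-off^2 / (2 * sigma_cells^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    # reflect indices about the edges (1 and n)
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > n, 2 * n - j, j)
    for (q in seq_along(j)) K[i, j[q]] <- K[i, j[q]] + w[q]
  }
  K
}

#' Generate EC weakly spatial cells
#'
#' Each cell's rate map is built by drawing i.i.d. U(0, 1) values on a
#' regular lattice over the arena, smoothing with a Gaussian kernel
#' (s.d. `smoothing_sigma`, reflective boundaries so edges are not dimmed),
#' and rescaling affinely so the map spans exactly \[0, `max_rate`\].
#' Rates at arbitrary positions are obtained by bilinear interpolation
#' between lattice nodes (placed at the centers of the lattice cells).
#'
#' @param n_cells number of weakly spatial cells (may be 0).
#' @param resolution lattice nodes per side (default 100, i.e. 1 cm).
#' @param smoothing_sigma Gaussian kernel s.d. in meters (default 0.06).
#' @param arena_size arena side length, m.
#' @param max_rate maximum rate after rescaling (default 0.1).
#' @param seed integer seed or `NULL`.
#' @return an object of class `weak_cells`: a `resolution x resolution x
#'   n_cells` array with attributes `arena_size` and `max_rate`.
#' @export
make_weakly_spatial_cells <- function(n_cells, resolution = 100,
                                      smoothing_sigma = 0.06,
                                      arena_size = 1, max_rate = 0.1,
                                      seed = NULL) {
  if (n_cells < 0) stop("n_cells must be non-negative")
  h <- arena_size / resolution
  if (smoothing_sigma < 2 * h)
    stop("lattice too coarse: smoothing_sigma must span at least 2 cells")
  maps <- array(0, dim = c(resolution, resolution, max(n_cells, 0)))
  if (n_cells > 0) {
    K <- .gaussian_reflect_matrix(resolution, smoothing_sigma / h)
    with_seed(seed, {
      for (k in seq_len(n_cells)) {
        m <- K %*% matrix(runif(resolution^2), resolution) %*% t(K)
        m <- m - min(m)
        maps[, , k] <- m / max(m) * max_rate
      }
    })
  }
  structure(maps, arena_size = arena_size, max_rate = max_rate,
            class = "weak_cells")
}

#' Firing rates of weakly spatial cells at positions
#'
#' @param cells a `weak_cells` object.
#' @param x,y positions (m), equal-length vectors inside the arena.
#' @return matrix `n_cells x length(x)`.
#' @export
weak_rates <- function(cells, x, y) {
  dims <- dim(cells)
  res <- dims[1]; n_cells <- dims[3]
  n <- length(x)
  out <- matrix(0, nrow = n_cells, ncol = n)
  if (n_cells == 0 || n == 0) return(out)
  L <- attr(cells, "arena_size")
  h <- L / res
  # lattice node i sits at (i - 0.5) * h; clamp queries to the node span
  gx <- pmin(pmax(x / h + 0.5, 1), res)
  gy <- pmin(pmax(y / h + 0.5, 1), res)
  i0 <- pmin(floor(gx), res - 1); j0 <- pmin(floor(gy), res - 1)
  wx <- gx - i0; wy <- gy - j0
  arr <- unclass(cells)
  for (k in seq_len(n_cells)) {
    m <- arr[, , k]
    out[k, ] <- m[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
      m[cbind(i0 + 1, j0)] * wx * (1 - wy) +
      m[cbind(i0, j0 + 1)] * (1 - wx) * wy +
      m[cbind(i0 + 1, j0 + 1)] * wx * wy
  }
  out
}
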