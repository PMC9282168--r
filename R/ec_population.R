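#' Combine weakly spatial and grid cells into one EC input population
#'
#' The ordering contract is fixed for the life of a model: the input vector
#' concatenates the weakly spatial rates first, then the grid rates, so in
#' the learnt dictionary the top rows are weakly-spatial weights and the
#' bottom rows are grid weights.
#'
#' @param grid a `grid_population`.
#' @param weak a `weak_cells` object, or `NULL` for none.
#' @return an object of class `ec_population` with elements `weak`, `grid`,
#'   `n_weak`, `n_grid`, `n_inputs`, `arena_size`.
#' @export
ec_population <- function(grid, weak = NULL) {
  stopifnot(inherits(grid, "grid_population"))
  n_weak <- if (is.null(weak)) 0L else dim(weak)[3]
  structure(list(weak = weak, grid = grid,
                 n_weak = n_weak, n_grid = length(grid),
                 n_inputs = n_weak + length(grid),
                 arena_size = attr(grid, "arena_size")),
            class = "ec_population")
}

#' EC input rates at a single (position, time, heading)
#'
#' @param population an `ec_population`.
#' @param r position, length-2 (m), inside the arena.
#' @param t time, s.
#' @param heading heading in radians (or length-2 direction vector).
#' @return numeric vector of length `n_inputs` (weakly spatial first).
#' @export
ec_rates <- function(population, r, t, heading) {
  L <- population$arena_size
  if (r[1] < 0 || r[1] > L || r[2] < 0 || r[2] > L)
    stop("position lies outside the arena")
  if (length(heading) == 2) heading <- atan2(heading[2], heading[1])
  drop(ec_rate_matrix(population, r[1], r[2], t, heading))
}

#' EC input rates along a sample sequence
#'
#' @inheritParams ec_rates
#' @param x,y,t,heading equal-length vectors (heading in radians).
#' @return matrix `n_inputs x length(x)`, weakly spatial rows first.
#' @export
ec_rate_matrix <- function(population, x, y, t, heading) {
  gr <- grid_population_rates(population$grid, x, y, t, heading)
  if (population$n_weak > 0)
    rbind(weak_rates(population$weak, x, y), gr)
  else gr
}
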