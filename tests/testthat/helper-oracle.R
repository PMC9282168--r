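# Independent fixed-point oracle for the LCA dynamics: brute-force
# enumeration over support patterns.  A support P is consistent when
#   G[P,P] s_P = b_P - beta  with  s_P > 0,   and
#   u_i = b_i - (G s)_i + s_i <= beta  for every i outside P,
# where G = A'A and b = A'I.  For small dictionaries the consistent
# pattern is the unique non-negative sparse-coding fixed point.
lca_fixed_point_enum <- function(A, input, beta) {
  G <- crossprod(A)
  b <- drop(crossprod(A, input))
  n <- ncol(A)
  for (mask in 0:(2^n - 1)) {
    P <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0)
    s <- numeric(n)
    if (length(P)) {
      sP <- tryCatch(solve(G[P, P, drop = FALSE], b[P] - beta),
                     error = function(e) NULL)
      if (is.null(sP) || any(sP <= 1e-12)) next
      s[P] <- sP
    }
    Q <- setdiff(seq_len(n), P)
    u <- b - G %*% s + s
    if (all(u[Q] <= beta + 1e-9)) return(s)
  }
  NULL
}

# single-grid-cell population with a field centered at `center`, plus the
# trivial one-unit model that relays it (A = 1, so s = max(I - beta, 0) at
# the fixed point); used to exercise the analysis chain without training
single_cell_relay <- function(center = c(0.5, 0.5), spacing = 0.5,
                              kphi = 1, phi0 = 320, dphi = 300) {
  cell <- make_grid_cell(spacing = spacing, orientation = 0, offset = center,
                         kphi = kphi, phi0 = phi0, dphi = dphi)
  pop <- ec_population(structure(list(cell), arena_size = 1,
                                 class = "grid_population"))
  model <- sparse_coding_model(1, 1, seed = 1)
  model$A <- matrix(1, 1, 1)
  list(cell = cell, pop = pop, model = model)
}
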