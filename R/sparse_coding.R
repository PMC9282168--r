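#' Initialize a non-negative sparse-coding model
#'
#' The feedforward dictionary `A` (`n_inputs x n_cells`) is initialized
#' entrywise from U(0, 1) and each column normalized to unit Euclidean
#' norm.  Responses are computed by the locally competitive algorithm
#' \deqn{\tau \dot u = -u + A^T I - (A^T A - 1)s, \quad s = \max(u - \beta, 0),}
#' integrated by forward Euler with step `dt_model`, and the dictionary is
#' learnt online by \eqn{\Delta A = \eta (I - A s) s^T} with \eqn{A \ge 0}
#' and unit-norm columns.  The lateral competition matrix
#' \eqn{W = A^T A - 1} is always derived from `A`, never stored.
#'
#' @param n_inputs,n_cells dictionary dimensions.
#' @param tau membrane time constant, s (default 0.010).
#' @param beta firing threshold (default 0.3).
#' @param dt_model integration step of the dynamics, s (default 2e-4).
#' @param n_inner LCA iterations per trajectory step (default 50,
#'   i.e. one 10 ms trajectory step).
#' @param eta learning rate (default 0.01).
#' @param seed integer seed or `NULL`.
#' @return an object of class `sparse_coding_model`.
#' @export
sparse_coding_model <- function(n_inputs, n_cells, tau = 0.010, beta = 0.3,
                                dt_model = 2e-4, n_inner = 50L, eta = 0.01,
                                seed = NULL) {
  if (n_inputs <= 0 || n_cells <= 0) stop("dimensions must be positive")
  A <- with_seed(seed, matrix(runif(n_inputs * n_cells), n_inputs, n_cells))
  A <- normalize_columns(A)
  structure(list(A = A, n_inputs = n_inputs, n_cells = n_cells,
                 tau = tau, beta = beta, dt_model = dt_model,
                 n_inner = as.integer(n_inner), eta = eta,
                 learning_enabled = TRUE),
            class = "sparse_coding_model")
}

#' Normalize matrix columns to unit Euclidean norm
#'
#' All-zero columns are left zero.
#'
#' @param A a numeric matrix.
#' @return the column-normalized matrix.
#' @export
normalize_columns <- function(A) {
  nrm <- sqrt(colSums(A^2))
  nrm[nrm == 0] <- 1
  sweep(A, 2, nrm, "/")
}

#' Zero-initialized model state
#'
#' @param model a `sparse_coding_model`.
#' @return a list with membrane potentials `u` and rates `s`, both zero.
#' @export
zero_state <- function(model) {
  list(u = numeric(model$n_cells), s = numeric(model$n_cells))
}

#' Run LCA inference on one input vector
#'
#' Runs `n_inner` forward-Euler steps of the LCA dynamics starting from the
#' supplied state (the membrane state carries over between trajectory
#' steps within a session); `s` is recomputed from `u` inside every step.
#'
#' @param model a `sparse_coding_model`.
#' @param input non-negative input vector of length `n_inputs`.
#' @param state a state as from [zero_state()]; defaults to zero.
#' @param n_inner number of Euler steps (defaults to the model's).
#' @return the updated state, a list with `u` and `s`.
#' @export
lca_infer <- function(model, input, state = NULL, n_inner = model$n_inner) {
  if (length(input) != model$n_inputs)
    stop("input has length ", length(input), " but the model expects ",
         model$n_inputs)
  if (is.null(state)) state <- zero_state(model)
  res <- lca_run_cpp(model$A, matrix(input, ncol = 1), state$u,
                     model$tau, model$beta, model$dt_model,
                     as.integer(n_inner), 0, FALSE, FALSE)
  list(u = drop(res$u), s = drop(res$s))
}

#' Apply one Hebbian dictionary update
#'
#' \eqn{A \leftarrow A + \eta (I - A s) s^T}, then negative entries are
#' clipped to zero and columns renormalized to unit norm.  Applied once per
#' trajectory step, after the LCA iterations.
#'
#' @param model a `sparse_coding_model`.
#' @param input the input vector used for inference.
#' @param s the converged rates from [lca_infer()].
#' @return the model with updated dictionary.
#' @export
update_weights <- function(model, input, s) {
  if (all(s == 0)) return(model)  # rank-1 update vanishes exactly
  A <- model$A + model$eta * tcrossprod(input - model$A %*% s, s)
  A[A < 0] <- 0
  model$A <- normalize_columns(A)
  model
}

#' Inactivate a set of input rows
#'
#' Zeroes the designated dictionary rows (severing those inputs), then
#' renormalizes each column to unit norm and disables learning.  A column
#' left entirely zero is reported and kept at zero.
#'
#' @param model a `sparse_coding_model`.
#' @param rows integer row indices to zero (e.g. the grid-cell block).
#' @return the modified model, with `learning_enabled = FALSE`.
#' @export
inactivate_inputs <- function(model, rows) {
  if (length(rows) == 0) return(model)
  if (any(rows < 1 | rows > model$n_inputs)) stop("row indices out of range")
  A <- model$A
  A[rows, ] <- 0
  dead <- which(colSums(A^2) == 0)
  if (length(dead))
    warning(length(dead), " column(s) entirely zeroed by inactivation: ",
            paste(utils::head(dead, 5), collapse = ", "))
  model$A <- normalize_columns(A)
  model$learning_enabled <- FALSE
  model
}

#' Run a model session along a trajectory
#'
#' Evaluates the EC input at every trajectory sample and advances the LCA
#' dynamics (50 Euler steps per 10 ms sample by default), optionally
#' applying one dictionary update per sample.  Input evaluation and
#' dynamics run in chunks to bound memory.  The membrane state is reset at
#' session start (configurable) and carries over across samples and chunks.
#'
#' @param model a `sparse_coding_model`.
#' @param population an `ec_population` with `n_inputs` matching the model.
#' @param trajectory a `rat_trajectory`.
#' @param learn whether to update the dictionary (forced off if learning
#'   was disabled by [inactivate_inputs()]).
#' @param keep_s whether to return the full response matrix
#'   (`n_cells x nrow(trajectory)`).
#' @param chunk_size samples per chunk (default 20000).
#' @param state carried-over state, or `NULL` to start from zero.
#' @param progress print a line per chunk with the running mean
#'   reconstruction error.
#' @return a list with the (updated) `model`, final `state`, per-sample
#'   squared reconstruction error `recon_error`, and `S` if requested.
#' @export
run_session <- function(model, population, trajectory, learn = TRUE,
                        keep_s = FALSE, chunk_size = 20000L, state = NULL,
                        progress = FALSE) {
  stopifnot(inherits(model, "sparse_coding_model"),
            inherits(population, "ec_population"))
  if (population$n_inputs != model$n_inputs)
    stop("population provides ", population$n_inputs,
         " inputs but the model expects ", model$n_inputs)
  learn <- learn && model$learning_enabled
  n <- nrow(trajectory)
  if (n == 0) stop("trajectory has no samples")
  if (is.null(state)) state <- zero_state(model)
  u <- state$u
  A <- model$A
  S <- if (keep_s) matrix(0, model$n_cells, n) else NULL
  err <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (st in starts) {
    en <- min(st + chunk_size - 1L, n)
    idx <- st:en
    I <- ec_rate_matrix(population, trajectory$x[idx], trajectory$y[idx],
                        trajectory$t[idx], trajectory$theta[idx])
    res <- lca_run_cpp(A, I, u, model$tau, model$beta, model$dt_model,
                       model$n_inner, model$eta, learn, keep_s)
    A <- res$A
    u <- drop(res$u)
    err[idx] <- res$err
    if (keep_s) S[, idx] <- res$S
    if (progress)
      message(sprintf("  t = %7.1f s  mean ||I - As||^2 = %.4f",
                      trajectory$t[en], mean(res$err)))
  }
  model$A <- A
  out <- list(model = model,
              state = list(u = u, s = pmax(u - model$beta, 0)),
              recon_error = err)
  if (keep_s) out$S <- S
  out
}

#' Write / read a model checkpoint
#'
#' The dictionary is stored as a tab-delimited matrix and the
#' hyperparameters as a DCF header file alongside it.
#'
#' @param model a `sparse_coding_model`.
#' @param path directory to create/use.
#' @return `read_model` returns a `sparse_coding_model`.
#' @export
write_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.table(model$A, file.path(path, "A.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE)
  meta <- data.frame(n_inputs = model$n_inputs, n_cells = model$n_cells,
                     tau = model$tau, beta = model$beta,
                     dt_model = model$dt_model, n_inner = model$n_inner,
                     eta = model$eta,
                     learning_enabled = model$learning_enabled)
  write.dcf(meta, file.path(path, "meta.dcf"))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  meta <- as.data.frame(read.dcf(file.path(path, "meta.dcf")),
                        stringsAsFactors = FALSE)
  A <- as.matrix(read.table(file.path(path, "A.tsv"), sep = "\t"))
  dimnames(A) <- NULL
  structure(list(A = A, n_inputs = as.integer(meta$n_inputs),
                 n_cells = as.integer(meta$n_cells),
                 tau = as.numeric(meta$tau), beta = as.numeric(meta$beta),
                 dt_model = as.numeric(meta$dt_model),
                 n_inner = as.integer(meta$n_inner),
                 eta = as.numeric(meta$eta),
                 learning_enabled = as.logical(meta$learning_enabled)),
            class = "sparse_coding_model")
}
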