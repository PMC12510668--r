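# Independent oracles used by the solver tests.

# Objective of the nonnegative quadratic program.
nnqp_objective <- function(r, D, y, T) {
  sum((y - D %*% r)^2) + 2 * sum(T * r)
}

# Brute-force oracle: enumerate every candidate support of size <= Y, solve the
# unconstrained stationarity system on it, keep feasible (nonnegative)
# candidates, and return the best objective. The optimum of the QP has support
# of at most Y for generic D, so the optimal support is among those enumerated;
# every candidate is feasible, so the minimum equals the true optimum.
brute_force_nnqp <- function(D, y, T) {
  N <- ncol(D)
  Y <- nrow(D)
  DtD <- crossprod(D)
  rhs <- drop(crossprod(D, y)) - T
  best_obj <- nnqp_objective(rep(0, N), D, y, T)
  best_r <- rep(0, N)
  for (k in seq_len(Y)) {
    sets <- utils::combn(N, k)
    for (q in seq_len(ncol(sets))) {
      S <- sets[, q]
      s <- tryCatch(solve(DtD[S, S, drop = FALSE], rhs[S]),
                    error = function(e) NULL)
      if (is.null(s) || any(s < 0)) next
      r <- rep(0, N)
      r[S] <- s
      obj <- nnqp_objective(r, D, y, T)
      if (obj < best_obj) {
        best_obj <- obj
        best_r <- r
      }
    }
  }
  list(r = best_r, objective = best_obj)
}

# Unit-column random decoder.
random_unit_decoder <- function(Y, N, seed) {
  set.seed(seed)
  D <- matrix(rnorm(Y * N), Y, N)
  sweep(D, 2, sqrt(colSums(D^2)), "/")
}

# Y x N matrix with orthonormal rows (so the pseudo-inverse encoder has
# orthonormal columns).
orthonormal_row_decoder <- function(Y, N, seed) {
  set.seed(seed)
  A <- matrix(rnorm(N * Y), N, Y)
  t(qr.Q(qr(A)))
}
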