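#' Sample decoder weights for the autoencoder network
#'
#' The network's only structural parameters are the decoding weights
#' \eqn{D \in R^{Y \times N}} (columns = neurons' tuning vectors). Columns are
#' drawn Gaussian and then normalized according to the code scheme:
#'
#' * `"M"` (mixed): every column has unit norm. Tuning vectors lie on the
#'   (Y-1)-sphere; neurons can be tuned to arbitrary mixtures of variables.
#' * `"C"` (conjunctive): every consecutive 2-row pair of every column has norm
#'   \eqn{1/\sqrt{Y/2}} (hence unit columns). Tuning vectors lie on a torus:
#'   every neuron is tuned with equal magnitude to every circular variable.
#' * `"CM"` (conjunctive-mixed): the positional rows are conjunctive-normalized
#'   within their block, the cognitive rows are left mixed, and the two blocks
#'   are normalized to \eqn{\|D_i^P\| = \|D_i^C\| = 1/\sqrt{2}} so that spatial
#'   tuning survives as the number of cognitive variables grows.
#' * `"pM"` (pure and mixed): the first `pure_P` neurons are purely positional
#'   (zero cognitive block), the next `pure_C` purely cognitive (zero
#'   positional block), the rest mixed; used for the reward-coding example.
#'
#' @param Y Embedding dimensionality (rows of D).
#' @param N Number of neurons (columns), N >= Y.
#' @param code One of `"M"`, `"C"`, `"CM"`, `"pM"`.
#' @param seed Integer seed.
#' @param p_rows Number of leading rows forming the positional block (needed
#'   for `"CM"` and `"pM"`).
#' @param pure_P,pure_C Counts of pure-positional / pure-cognitive neurons
#'   (`"pM"` only).
#' @param identity If `TRUE`, returns the full-dimensional special case
#'   D = Id_N (Y must equal N); used for full-D multi-chart remapping.
#' @return A `network_model` object: list with `D`, `E` (right pseudo-inverse),
#'   `T` (thresholds), `code`, `p_rows`.
#' @export
sample_decoder <- function(Y, N, code = c("M", "C", "CM", "pM"), seed = 1L,
                           p_rows = NULL, pure_P = 0L, pure_C = 0L,
                           identity = FALSE) {
  code <- match.arg(code)
  if (identity) {
    if (Y != N) stop("identity decoder requires Y = N")
    D <- diag(N)
    return(new_network_model(D, code = "M", p_rows = p_rows))
  }
  if (N < Y) stop("need at least as many neurons as embedding dimensions")
  rng <- local_seed(seed)
  on.exit(rng())
  D <- matrix(stats::rnorm(Y * N), Y, N)
  D <- switch(code,
    M = normalize_columns(D),
    C = {
      if (Y %% 2L != 0L) stop("conjunctive code requires even Y")
      normalize_pairs(D, 1 / sqrt(Y / 2))
    },
    CM = {
      if (is.null(p_rows)) stop("CM code requires p_rows")
      if (p_rows %% 2L != 0L || p_rows <= 0L || p_rows >= Y) {
        stop("CM code requires an even positional block strictly inside D")
      }
      Dp <- normalize_pairs(D[seq_len(p_rows), , drop = FALSE],
                            1 / sqrt(p_rows))
      Dc <- normalize_columns(D[(p_rows + 1L):Y, , drop = FALSE]) / sqrt(2)
      rbind(Dp, Dc)
    },
    pM = {
      if (is.null(p_rows)) stop("pM code requires p_rows")
      pure_P <- as.integer(pure_P); pure_C <- as.integer(pure_C)
      if (pure_P + pure_C > N) stop("pure_P + pure_C exceeds N")
      pi_ <- seq_len(p_rows)
      ci_ <- setdiff(seq_len(Y), pi_)
      if (pure_P > 0L) D[ci_, seq_len(pure_P)] <- 0
      if (pure_C > 0L) D[pi_, pure_P + seq_len(pure_C)] <- 0
      normalize_columns(D)
    }
  )
  new_network_model(D, code = code, p_rows = p_rows,
                    pure_P = pure_P, pure_C = pure_C)
}

#' Optimal firing thresholds
#'
#' The spike-coding network's optimal thresholds are
#' \eqn{T = \frac{1}{2} diag(D' D)}, i.e. half the squared column norms;
#' with unit-norm tuning vectors every threshold is 1/2.
#'
#' @param D Y x N decoder matrix.
#' @return N-vector of thresholds.
#' @export
default_thresholds <- function(D) {
  0.5 * colSums(D^2)
}

#' Threshold (excitability) modulation for null-space remapping
#'
#' Participation in the map is controlled by raising thresholds of a random
#' subset of neurons to `T_suppr`, which effectively silences them without
#' touching the decoder. `spar` is the fraction of neurons left at their
#' normal (excitable) threshold: `round(N * (1 - spar))` neurons are
#' suppressed. The reference "default" map uses `spar = 0.5`; `spar > 0.5`
#' releases suppression (cell birth), `spar < 0.5` deepens it (cell death).
#'
#' @param T N-vector of baseline thresholds.
#' @param spar Active fraction in \eqn{[0, 1]}.
#' @param seed Integer seed selecting the suppressed subset.
#' @param T_suppr Elevated threshold (default 10, about 10x the unit-column
#'   baseline of 1/2... large enough to prevent firing at unit input norms).
#' @return List with `T` (modulated thresholds), `suppressed` (indices),
#'   `spar`, `T_suppr`.
#' @export
modulate_thresholds <- function(T, spar, seed = 1L, T_suppr = 10) {
  if (spar < 0 || spar > 1) stop("spar must lie in [0, 1]")
  N <- length(T)
  n_suppr <- round(N * (1 - spar))
  rng <- local_seed(seed)
  on.exit(rng())
  suppressed <- if (n_suppr > 0L) sort(sample.int(N, n_suppr)) else integer(0)
  T[suppressed] <- T_suppr
  list(T = T, suppressed = suppressed, spar = spar, T_suppr = T_suppr)
}

#' Steady-state firing rates for one input
#'
#' Solves the nonnegative quadratic program
#' \deqn{r^* = argmin_{r \ge 0} \|y - D r\|^2 + 2 T' r,}
#' the steady state of the competitive spike-coding network: a decoding-error
#' term plus an l1 activity cost whose weights are the thresholds. Solved by
#' an active-set method; the returned solution carries a KKT certificate
#' (checkable with [kkt_residual()]).
#'
#' @param y Embedding input vector (length Y).
#' @param D Y x N decoder.
#' @param T N-vector of positive thresholds.
#' @return Nonnegative rate vector of length N.
#' @seealso [batch_solve()] for whole rate maps.
#' @export
solve_rates <- function(y, D, T) {
  if (any(T <= 0)) stop("thresholds must be positive")
  if (length(y) != nrow(D)) stop("input/decoder dimension mismatch")
  drop(.nnqp_batch(D, as.matrix(y), T))
}

#' KKT residual of a candidate rate vector
#'
#' For \eqn{g = D'(D r - y) + T}, optimality requires \eqn{g_i \ge 0}
#' everywhere and \eqn{r_i g_i = 0}. Returns the largest violation
#' (`max(-g)` and `max(r * |g|)` combined), which should be below ~1e-6 for a
#' converged solution.
#'
#' @param y Input vector.
#' @param D Decoder.
#' @param T Thresholds.
#' @param r Candidate rates.
#' @return Scalar residual (0 = exact KKT point).
#' @export
kkt_residual <- function(y, D, T, r) {
  g <- drop(crossprod(D, D %*% r - y)) + T
  max(c(0, -g, abs(r * g)))
}

#' Solve steady-state rates over a whole grid
#'
#' Applies [solve_rates()] to every column of an embedding trajectory and
#' packages the result as a rate-map set: rates, their linear decode
#' \eqn{D r}, and the null-space component \eqn{r - E D r} (the part of the
#' population activity invisible to the decoder).
#'
#' @param Ymat Y x G matrix of embedding inputs (columns = grid points).
#' @param D Y x N decoder.
#' @param T N-vector of thresholds.
#' @param E Optional N x Y encoder (right pseudo-inverse of D); computed if
#'   missing.
#' @param environment_id Optional label.
#' @return A `ratemap_set` object: list with `rates` (N x G), `decoded`
#'   (Y x G), `null_component` (N x G), `environment_id`.
#' @export
batch_solve <- function(Ymat, D, T, E = NULL, environment_id = NULL) {
  Ymat <- as.matrix(Ymat)
  if (any(T <= 0)) stop("thresholds must be positive")
  if (nrow(Ymat) != nrow(D)) stop("input/decoder dimension mismatch")
  rates <- .nnqp_batch(D, Ymat, T)
  if (is.null(E)) E <- pseudo_inverse_encoder(D)
  decoded <- D %*% rates
  structure(list(rates = rates,
                 decoded = decoded,
                 null_component = rates - E %*% decoded,
                 environment_id = environment_id),
            class = "ratemap_set")
}

#' @export
print.ratemap_set <- function(x, ...) {
  cat(sprintf("<ratemap_set%s: %d neurons x %d positions, %.1f%% nonzero>\n",
              if (is.null(x$environment_id)) "" else
                paste0(" env ", x$environment_id),
              nrow(x$rates), ncol(x$rates), 100 * mean(x$rates > 0)))
  invisible(x)
}

#' Right pseudo-inverse encoder
#'
#' The most general encoder consistent with the linear decoder D is
#' \eqn{r = E z + \nu(z)} with \eqn{E = D'(D D')^{-1}} the right
#' pseudo-inverse (so \eqn{D E = Id}) and \eqn{\nu} any function in the null
#' space of D.
#'
#' @param D Y x N decoder with full row rank.
#' @return N x Y encoder matrix.
#' @export
pseudo_inverse_encoder <- function(D) {
  Gm <- tcrossprod(D)
  E <- tryCatch(t(solve(Gm, D)), error = function(e) NULL)
  if (is.null(E)) {
    E <- MASS::ginv(D)
    if (max(abs(D %*% E - diag(nrow(D)))) > 1e-6) {
      stop("decoder is rank deficient; right pseudo-inverse does not exist")
    }
  }
  E
}

#' Decode latent estimates from rates
#'
#' The network output decode: \eqn{\hat y = D r}, then back through the
#' embedding map, \eqn{\hat z = R' \hat y} (identity map: \eqn{\hat z = \hat
#' y}).
#'
#' @param rates N-vector or N x G matrix of rates.
#' @param D Y x N decoder.
#' @param map Optional `embedding_map`; when supplied the estimate is pulled
#'   back to latent coordinates.
#' @return List with `y_hat` and `z_hat`.
#' @export
decode_latents <- function(rates, D, map = NULL) {
  rates <- as.matrix(rates)
  y_hat <- D %*% rates
  z_hat <- if (is.null(map)) y_hat else crossprod(map$R, y_hat)
  list(y_hat = y_hat, z_hat = z_hat)
}

new_network_model <- function(D, code, p_rows = NULL, pure_P = 0L,
                              pure_C = 0L) {
  E <- pseudo_inverse_encoder(D)
  structure(list(D = D, E = E, T = default_thresholds(D), code = code,
                 p_rows = p_rows, pure_P = pure_P, pure_C = pure_C),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model: %d neurons, Y = %d, %s code>\n",
              ncol(x$D), nrow(x$D), x$code))
  invisible(x)
}

normalize_columns <- function(M, target = 1) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2L, nrm / target, "/")
}

normalize_pairs <- function(M, target) {
  stopifnot(nrow(M) %% 2L == 0L)
  for (j in seq_len(nrow(M) %/% 2L)) {
    rows <- (j - 1L) * 2L + 1L:2L
    nrm <- sqrt(colSums(M[rows, , drop = FALSE]^2))
    nrm[nrm == 0] <- 1
    M[rows, ] <- sweep(M[rows, , drop = FALSE], 2L, nrm / target, "/")
  }
  M
}
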