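#' Sample per-environment cognitive variables over a position grid
#'
#' Cognitive variables are modeled as a constant per-environment offset plus a
#' smooth position-dependent fluctuation: \eqn{c^A(p) = wrap(k^A + g^A(p))}.
#' The offset is drawn \eqn{k^A \sim N(0, \sigma)} per component when
#' \eqn{\sigma < 1} and uniformly on \eqn{[-1, 1]} when \eqn{\sigma = 1}; the
#' fluctuation is a Gaussian process with squared-exponential kernel
#' \eqn{K(x, x') = \sigma^2 \exp(-\|x - x'\|^2 / (2 v^2))}, sampled i.i.d.
#' across the C components. The wrap \eqn{c \mapsto ((c + 1) \bmod 2) - 1}
#' keeps values on the circle \eqn{[-1, 1)}, consistent with the angular code.
#'
#' A single variance parameter `sigma` drives both the offset and the GP
#' amplitude, so `sigma = 0` yields identically zero cognitive variables.
#'
#' @param grid P x G position grid (columns are points); kernel distance is
#'   Euclidean over the P position coordinates.
#' @param C Number of cognitive variables.
#' @param sigma Variance parameter in \eqn{[0, 1]}.
#' @param v Kernel length scale in normalized position units (default 0.3).
#' @param seed Integer seed.
#' @param amplitude Optional override for the GP marginal standard deviation
#'   (defaults to `sigma`).
#' @return C x G matrix of cognitive values in \eqn{[-1, 1)}.
#' @export
sample_cognitive_trajectory <- function(grid, C, sigma, v = 0.3, seed = 1L,
                                        amplitude = NULL) {
  grid <- as.matrix(grid)
  G <- ncol(grid)
  if (G < 1L) stop("position grid is empty")
  if (sigma < 0 || sigma > 1) stop("sigma must lie in [0, 1]")
  if (v <= 0) stop("length scale v must be positive")
  if (C < 1L) return(matrix(0, 0L, G))
  amp <- if (is.null(amplitude)) sigma else amplitude
  rng <- local_seed(seed)
  on.exit(rng())
  k <- if (sigma == 0) {
    rep(0, C)
  } else if (sigma < 1) {
    stats::rnorm(C, 0, sigma)
  } else {
    stats::runif(C, -1, 1)
  }
  g <- matrix(0, C, G)
  if (amp > 0) {
    d2 <- as.matrix(stats::dist(t(grid)))^2
    K <- amp^2 * exp(-d2 / (2 * v^2)) + diag(1e-8, G)
    L <- t(chol(K))
    g <- t(L %*% matrix(stats::rnorm(G * C), G, C))
  }
  wrap_circle(sweep(g, 1L, k, "+"))
}

#' Gaussian reward profile as a cognitive variable
#'
#' A single cognitive variable reflecting reward at location `mu`:
#' \eqn{c(p) = \exp(-(p - \mu)^2 / (2 \sigma_r^2)) - 1}, peaking at 0 at the
#' reward location and decaying to -1 far from it.
#'
#' @param grid 1 x G position grid.
#' @param mu Reward location in \eqn{[-1, 1]}.
#' @param sigma_r Positive reward spread.
#' @return 1 x G matrix of values in \eqn{(-1, 0]}.
#' @export
reward_profile <- function(grid, mu, sigma_r) {
  grid <- as.matrix(grid)
  if (ncol(grid) < 1L) stop("position grid is empty")
  if (nrow(grid) != 1L) stop("reward profile is defined for 1-d position")
  if (sigma_r <= 0) stop("sigma_r must be positive")
  if (mu < -1 || mu > 1) stop("mu must lie in [-1, 1]")
  matrix(exp(-(grid[1L, ] - mu)^2 / (2 * sigma_r^2)) - 1, 1L)
}

#' Sample a random orthonormal (multi-chart) embedding map
#'
#' Draws a Y x Z matrix with orthonormal columns uniformly (Haar measure) by
#' QR-orthogonalizing a standard-Gaussian matrix and correcting column signs
#' with the signs of the R-factor diagonal. Each environment gets its own map,
#' rotating the shared latent trajectory into a random Z-dimensional subspace
#' of the common embedding space.
#'
#' @param Y Embedding dimensionality (rows).
#' @param Z Latent dimensionality (columns), Z <= Y.
#' @param seed Integer seed.
#' @param environment_id Optional label.
#' @return An `embedding_map` object (list with `R`, `kind`, `environment_id`).
#' @export
sample_multichart_map <- function(Y, Z, seed = 1L, environment_id = NULL) {
  if (Z > Y) stop("latent dimensionality Z must not exceed embedding Y")
  rng <- local_seed(seed)
  on.exit(rng())
  A <- matrix(stats::rnorm(Y * Z), Y, Z)
  qr_A <- qr(A)
  Q <- qr.Q(qr_A)
  d <- sign(diag(qr.R(qr_A)))
  d[d == 0] <- 1
  R <- sweep(Q, 2L, d, "*")
  new_embedding_map(R, "multi_chart", environment_id)
}

#' Sample a grid-realignment (module phase-shift) embedding map
#'
#' Builds a block-diagonal map of m*P independent 2 x 2 rotation matrices with
#' angles drawn uniformly on \eqn{[0, 2\pi)}. Acting on a multi-module angular
#' code, each block advances the phase of one (position dimension, module)
#' pair, emulating the coherent phase realignment of grid modules across
#' environments.
#'
#' @param m Number of grid modules.
#' @param P Number of position dimensions.
#' @param seed Integer seed.
#' @param environment_id Optional label.
#' @return An `embedding_map` object with a 2mP x 2mP orthogonal matrix; the
#'   drawn angles are attached as attribute `delta_alpha` (length m*P, in the
#'   row-block order of [encode_grid()]).
#' @export
sample_gridshift_map <- function(m, P, seed = 1L, environment_id = NULL) {
  m <- as.integer(m); P <- as.integer(P)
  stopifnot(m >= 1L, P >= 1L)
  rng <- local_seed(seed)
  on.exit(rng())
  nb <- m * P
  da <- stats::runif(nb, 0, 2 * pi)
  R <- matrix(0, 2L * nb, 2L * nb)
  for (b in seq_len(nb)) {
    i <- (b - 1L) * 2L
    R[i + 1L:2L, i + 1L:2L] <- rotation2(da[b])
  }
  out <- new_embedding_map(R, "grid_shift", environment_id)
  attr(out, "delta_alpha") <- da
  out
}

#' Identity embedding map
#'
#' Used for mixed-selective remapping, where the latent-to-embedding map is
#' fixed across environments and remapping comes from the cognitive
#' trajectories instead.
#'
#' @param Z Latent (= embedding) dimensionality.
#' @param environment_id Optional label.
#' @return An `embedding_map` object with R = Id.
#' @export
identity_map <- function(Z, environment_id = NULL) {
  new_embedding_map(diag(Z), "identity", environment_id)
}

#' Apply an embedding map to latent vectors
#'
#' Computes \eqn{y = R z}. All embedding maps have orthonormal columns, so the
#' map is an isometry: \eqn{\|y\| = \|z\|}.
#'
#' @param z Numeric vector (length Z) or Z x G matrix.
#' @param map An `embedding_map`.
#' @return Vector of length Y or Y x G matrix.
#' @export
build_embedding <- function(z, map) {
  stopifnot(inherits(map, "embedding_map"))
  vec <- is.null(dim(z))
  z <- as.matrix(z)
  if (nrow(z) != ncol(map$R)) {
    stop(sprintf("latent dimension %d does not match map columns %d",
                 nrow(z), ncol(map$R)))
  }
  y <- map$R %*% z
  if (vec) drop(y) else y
}

new_embedding_map <- function(R, kind, environment_id = NULL) {
  err <- max(abs(crossprod(R) - diag(ncol(R))))
  if (err > 1e-8) stop("embedding map columns are not orthonormal")
  structure(list(R = R, kind = kind, environment_id = environment_id),
            class = "embedding_map")
}

#' @export
print.embedding_map <- function(x, ...) {
  cat(sprintf("<embedding_map: %s, %d x %d%s>\n", x$kind,
              nrow(x$R), ncol(x$R),
              if (is.null(x$environment_id)) "" else
                paste0(", env ", x$environment_id)))
  invisible(x)
}

rotation2 <- function(a) {
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

wrap_circle <- function(x) {
  ((x + 1) %% 2) - 1
}

# Temporarily set the RNG seed; returns a restorer for on.exit().
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Counter-based sub-seed derivation: adding later consumers never perturbs
# earlier ones. Kept below 2^31.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + 100003 * as.numeric(counter)) %%
               2147483647) + 1L
}
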