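#' Angular encoding of environmental variables
#'
#' Maps each environmental variable \eqn{p_i \in [-1, 1]} to an angle
#' \eqn{\alpha_i = \pi (p_i + 1) \in [0, 2\pi]} and then onto the unit circle,
#' \eqn{(z_{2i-1}, z_{2i}) = (\cos\alpha_i, \sin\alpha_i)}. The resulting
#' latent vector lives on a product of circles (a torus), the geometry that
#' yields localized, place-field-like tuning with energy-constrained codes.
#'
#' @param p Numeric vector (length P) or P x G matrix of variables in
#'   \eqn{[-1, 1]}; columns of a matrix are separate points.
#' @return Numeric vector of length 2P (or 2P x G matrix) stacking
#'   (cos, sin) pairs per variable.
#' @seealso [decode_angles()], [encode_grid()]
#' @examples
#' encode_angles(0)      # (-1, 0)
#' encode_angles(-1)     # ( 1, 0)
#' @export
encode_angles <- function(p) {
  p <- check_range(p, "p")
  vec <- is.null(dim(p))
  p <- as.matrix(p)
  alpha <- pi * (p + 1)
  z <- interleave_rows(cos(alpha), sin(alpha))
  if (vec) drop(z) else z
}

#' Angular decoding back to environmental variables
#'
#' Inverse of [encode_angles()]: each consecutive (cos, sin) pair is
#' normalized, its angle recovered with `atan2(sin, cos)` mapped into
#' \eqn{[0, 2\pi)}, and converted back to \eqn{p = \alpha/\pi - 1 \in [-1, 1)}.
#' The branch is chosen so the encode/decode round trip is the identity on
#' \eqn{[-1, 1)}; the periodic seam \eqn{p = +1} canonicalizes to \eqn{-1}.
#'
#' @param z Numeric vector of length 2P (or 2P x G matrix) of (cos, sin) pairs.
#' @return Numeric vector of length P (or P x G matrix) of variables in
#'   \eqn{[-1, 1)}.
#' @export
decode_angles <- function(z) {
  vec <- is.null(dim(z))
  z <- as.matrix(z)
  if (nrow(z) %% 2L != 0L) {
    stop("latent block must have an even number of rows (cos, sin pairs)")
  }
  cz <- z[seq(1L, nrow(z), by = 2L), , drop = FALSE]
  sz <- z[seq(2L, nrow(z), by = 2L), , drop = FALSE]
  nrm <- sqrt(cz^2 + sz^2)
  if (any(nrm <= 1e-12)) {
    stop("degenerate latent input: a (cos, sin) pair has zero norm")
  }
  alpha <- atan2(sz / nrm, cz / nrm)
  alpha <- ifelse(alpha < 0, alpha + 2 * pi, alpha)
  p <- alpha / pi - 1
  # canonicalize the seam: alpha numerically equal to 2*pi wraps to p = -1
  p <- ifelse(p >= 1, p - 2, p)
  if (vec) drop(p) else p
}

#' Multi-module (grid) angular encoding
#'
#' Encodes each position variable with `m` angular modules whose spatial
#' frequencies are scaled by powers of 3/2: module j uses
#' \eqn{\alpha_{i,j} = (3/2)^{f_j} \pi (p_i + 1)}. The first module must have
#' \eqn{f_1 = 0} so that it forms a bijection with position and can be used
#' alone for decoding; modules with \eqn{f_j \neq 0} wrap the circle a
#' non-integer number of times, mimicking grid-cell modules of different scale.
#'
#' Row layout of the result: for each position variable i, the m modules'
#' (cos, sin) pairs are stacked in module order, so the block for variable i
#' occupies rows (i-1)*2m + 1 ... i*2m.
#'
#' @param p Numeric vector (length P) or P x G matrix in \eqn{[-1, 1]}.
#' @param f Integer vector of module frequency exponents; `f[1]` must be 0.
#' @return Numeric vector of length 2mP (or 2mP x G matrix).
#' @seealso [decode_grid()], [default_frequencies()]
#' @export
encode_grid <- function(p, f = 0L) {
  f <- as.numeric(f)
  if (length(f) < 1L || f[1] != 0) {
    stop("frequency exponents must start with f[1] = 0 (bijective first module)")
  }
  p <- check_range(p, "p")
  vec <- is.null(dim(p))
  p <- as.matrix(p)
  P <- nrow(p); G <- ncol(p); m <- length(f)
  scale <- (3 / 2)^f
  z <- matrix(0, 2L * m * P, G)
  for (i in seq_len(P)) {
    for (j in seq_len(m)) {
      alpha <- scale[j] * pi * (p[i, ] + 1)
      r0 <- (i - 1L) * 2L * m + (j - 1L) * 2L
      z[r0 + 1L, ] <- cos(alpha)
      z[r0 + 2L, ] <- sin(alpha)
    }
  }
  if (vec) drop(z) else z
}

#' Decode position from a multi-module latent block
#'
#' Position is recovered from the first module only (its frequency exponent is
#' pinned to 0, making it a bijection with position); the remaining modules are
#' ignored by the decoder and act like additional mixed-selective variables.
#'
#' @param z Numeric vector of length 2mP (or 2mP x G matrix) laid out as in
#'   [encode_grid()].
#' @param m Number of modules used at encoding time.
#' @return Numeric vector of length P (or P x G matrix) in \eqn{[-1, 1)}.
#' @export
decode_grid <- function(z, m) {
  m <- as.integer(m)
  vec <- is.null(dim(z))
  z <- as.matrix(z)
  if (nrow(z) %% (2L * m) != 0L) {
    stop("latent block rows are not a multiple of 2*m")
  }
  P <- nrow(z) %/% (2L * m)
  keep <- as.vector(vapply(seq_len(P), function(i) {
    (i - 1L) * 2L * m + c(1L, 2L)
  }, integer(2)))
  p <- decode_angles(z[keep, , drop = FALSE])
  if (vec) drop(as.matrix(p)) else as.matrix(p)
}

#' Default grid-module frequency exponents
#'
#' @param m Number of modules.
#' @return Integer vector of length `m`: `0` for m = 1, `c(0, 1)` for m = 2,
#'   `c(0, 1, -1)` for m = 3, and `0, 1, -1, 2, -2, ...` beyond.
#' @export
default_frequencies <- function(m) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  base <- c(0L, as.vector(rbind(seq_len(m), -seq_len(m))))
  base[seq_len(m)]
}

#' Block normalization of a latent vector
#'
#' Normalizes the positional and cognitive blocks of a latent vector so the
#' network receives inputs of controlled magnitude: with both blocks present,
#' each is scaled to norm \eqn{1/\sqrt{2}} (total norm 1); with a single block,
#' to norm 1. When the embedding dimensionality Y is large (above
#' `rescale_cutoff`), the whole vector is additionally rescaled as
#' \eqn{y \gets Y y}, which keeps the input amplitude well above the fixed
#' firing thresholds so the network autoencodes accurately as Y grows.
#'
#' @param z Numeric vector (length Z) or Z x G matrix.
#' @param p_rows Number of leading rows that form the positional block
#'   (2mP); the rest is the cognitive block. Use 0 or Z for single-block input.
#' @param rescale_dim Optional embedding dimensionality Y triggering the
#'   linear rescale by Y.
#' @param rescale_cutoff Y values above this get the rescale (default 4).
#' @return Normalized vector/matrix of the same shape.
#' @export
normalize_blocks <- function(z, p_rows = NULL, rescale_dim = NULL,
                             rescale_cutoff = 4) {
  vec <- is.null(dim(z))
  z <- as.matrix(z)
  Z <- nrow(z)
  if (is.null(p_rows)) p_rows <- Z
  p_rows <- as.integer(p_rows)
  stopifnot(p_rows >= 0L, p_rows <= Z)
  blocks <- list()
  if (p_rows > 0L) blocks$p <- seq_len(p_rows)
  if (p_rows < Z) blocks$c <- seq(p_rows + 1L, Z)
  target <- if (length(blocks) == 2L) 1 / sqrt(2) else 1
  out <- z
  for (idx in blocks) {
    nrm <- sqrt(colSums(z[idx, , drop = FALSE]^2))
    if (any(nrm <= 1e-12)) {
      stop("degenerate latent input: a block has zero norm")
    }
    out[idx, ] <- sweep(z[idx, , drop = FALSE], 2L, nrm / target, "/")
  }
  if (!is.null(rescale_dim) && rescale_dim > rescale_cutoff) {
    out <- out * rescale_dim
  }
  if (vec) drop(out) else out
}

#' Equally spaced half-open position grid on \eqn{[-1, 1)^P}
#'
#' The value +1 is excluded: it encodes identically to -1 under the angular
#' code, so a half-open grid avoids duplicated latent states.
#'
#' @param n Points per dimension.
#' @param P Number of position dimensions.
#' @return P x n^P matrix; columns are grid points.
#' @export
position_grid <- function(n, P = 1L) {
  P <- as.integer(P)
  stopifnot(n >= 1L, P >= 1L)
  g <- seq(-1, 1, length.out = n + 1L)[seq_len(n)]
  if (P == 1L) {
    matrix(g, 1L)
  } else {
    t(as.matrix(do.call(expand.grid, rep(list(g), P))))
  }
}

# interleave two equally-shaped matrices row-wise: a1, b1, a2, b2, ...
interleave_rows <- function(a, b) {
  out <- matrix(0, 2L * nrow(a), ncol(a))
  out[seq(1L, 2L * nrow(a), by = 2L), ] <- a
  out[seq(2L, 2L * nrow(a), by = 2L), ] <- b
  out
}

check_range <- function(p, name) {
  bad <- which(p < -1 | p > 1)
  if (length(bad) > 0L) {
    stop(sprintf("%s[%d] = %g outside [-1, 1]", name, bad[1], p[bad[1]]))
  }
  p
}
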