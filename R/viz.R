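#' Feedforward excitation approximation
#'
#' The feedforward input to each neuron, \eqn{\tilde r = D' y}, used as a
#' cheap stand-in for the full rate solve when painting tuning mosaics. It is
#' a cartooning device only and is never used in analysis statistics.
#'
#' @param y Embedding vector (length Y) or Y x G matrix.
#' @param D Y x N decoder.
#' @return Length-N vector or N x G matrix of approximate excitations (can be
#'   negative).
#' @export
feedforward_excitation <- function(y, D) {
  vec <- is.null(dim(y))
  out <- crossprod(D, as.matrix(y))
  if (vec) drop(out) else out
}

#' Winner-take-all tuning mosaic over the variable square
#'
#' Colors the square \eqn{[-1, 1]^2} of two environmental variables by the
#' most excited neuron at each mesh point: each point is angular-encoded,
#' pushed through the embedding map, and the per-neuron excitation computed
#' (feedforward approximation by default, or the full rate solve). Suppressed
#' neurons are zeroed before the argmax. Points where no neuron has positive
#' excitation have no winner (NA). Ties break to the lowest index.
#'
#' @param network A `network_model` (or list with `D`, `T`).
#' @param map Optional `embedding_map` (default identity).
#' @param mesh_n Mesh points per axis (default 200).
#' @param f Frequency exponents for the first variable's angular code
#'   (default single module).
#' @param suppressed Optional neuron indices zeroed before the argmax.
#' @param p_rows Latent rows of the first variable's block; remaining latent
#'   rows encode the second variable. Defaults to the multi-module code of the
#'   first variable.
#' @param method `"feedforward"` (default) or `"solve"` (full rate solve).
#' @param rescale_dim,rescale_cutoff Passed to [normalize_blocks()].
#' @return A `tuning_mosaic`: list with `winner` (mesh_n x mesh_n integer
#'   matrix, NA = background), `mesh` (axis values), `colors` (stable
#'   neuron-index palette).
#' @export
argmax_mosaic <- function(network, map = NULL, mesh_n = 200L, f = 0L,
                          suppressed = NULL,
                          method = c("feedforward", "solve"),
                          rescale_dim = NULL, rescale_cutoff = 4) {
  method <- match.arg(method)
  D <- network$D
  axis <- seq(-1, 1, length.out = mesh_n + 1L)[seq_len(mesh_n)]
  pts <- rbind(rep(axis, times = mesh_n), rep(axis, each = mesh_n))
  z1 <- encode_grid(pts[1L, , drop = FALSE], f = f)
  z2 <- encode_angles(pts[2L, , drop = FALSE])
  z <- rbind(as.matrix(z1), as.matrix(z2))
  z <- normalize_blocks(z, p_rows = nrow(as.matrix(z1)),
                        rescale_dim = rescale_dim,
                        rescale_cutoff = rescale_cutoff)
  y <- if (is.null(map)) z else build_embedding(z, map)
  excit <- if (method == "feedforward") {
    feedforward_excitation(y, D)
  } else {
    batch_solve(y, D, network$T)$rates
  }
  if (!is.null(suppressed)) excit[suppressed, ] <- 0
  winner <- apply(excit, 2L, function(e) {
    if (max(e) <= 0) NA_integer_ else which.max(e)
  })
  structure(list(
    winner = matrix(winner, mesh_n, mesh_n),
    mesh = axis,
    colors = neuron_colors(ncol(D))
  ), class = "tuning_mosaic")
}

#' Stable neuron color assignment
#'
#' Deterministic palette keyed on the neuron index (golden-ratio hue steps),
#' so mosaics are directly comparable across environments and runs.
#'
#' @param N Number of neurons.
#' @return Character vector of N colors.
#' @export
neuron_colors <- function(N) {
  h <- (0.61803398875 * seq_len(N)) %% 1
  grDevices::hsv(h, s = 0.65, v = 0.92)
}

#' Plot a tuning mosaic
#'
#' @param x A `tuning_mosaic`.
#' @param xlab,ylab Axis labels.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.tuning_mosaic <- function(x, xlab = "variable 1", ylab = "variable 2",
                               ...) {
  w <- x$winner
  ids <- sort(unique(as.vector(w)))
  lut <- match(w, ids)
  graphics::image(x$mesh, x$mesh, matrix(lut, nrow(w), ncol(w)),
                  col = x$colors[ids], xlab = xlab, ylab = ylab,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Gnomonic projection onto the unit sphere
#'
#' Maps a point of the plane to the lower unit hemisphere,
#' \eqn{(2x, 2y, x^2 + y^2 - 1) / (x^2 + y^2 + 1)}; the output is always unit
#' norm. Used to visualize multi-chart latent trajectories on a sphere instead
#' of a torus.
#'
#' @param x,y Numeric vectors (recycled to common length).
#' @return 3 x n matrix of unit vectors.
#' @export
gnomonic_embed <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  s <- x^2 + y^2
  rbind(2 * x, 2 * y, s - 1) / rep(s + 1, each = 3L)
}

#' Export a mosaic winner grid as CSV
#'
#' Allows testing and downstream use without a graphics device.
#'
#' @param mosaic A `tuning_mosaic`.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_mosaic_csv <- function(mosaic, path) {
  utils::write.csv(mosaic$winner, path, row.names = FALSE)
  invisible(path)
}
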