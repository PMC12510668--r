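#' Threshold rate maps and compute environment means
#'
#' Preprocessing before any remapping statistic: rates below `threshold`
#' (default 1e-3) are set to zero, and the per-environment mean population
#' vector is the average over grid positions.
#'
#' @param rates N x G nonnegative rate matrix.
#' @param threshold Zeroing threshold.
#' @return List with `rates` (thresholded) and `mean` (length-N vector).
#' @export
preprocess_ratemaps <- function(rates, threshold = 1e-3) {
  rates <- as.matrix(rates)
  if (any(rates < 0)) stop("rates must be nonnegative")
  rates[rates < threshold] <- 0
  list(rates = rates, mean = rowMeans(rates))
}

#' Population-vector overlap between two environments
#'
#' Cosine similarity of the environment-mean population rate vectors,
#' \eqn{\omega(A, B) = \bar r^A \cdot \bar r^B / (\|\bar r^A\| \|\bar r^B\|)}.
#' With nonnegative rates the overlap lies in \eqn{[0, 1]}; 1 means the same
#' set of neurons participates with the same relative mean rates.
#'
#' @param meanA,meanB Length-N mean rate vectors.
#' @return Scalar overlap.
#' @export
overlap <- function(meanA, meanB) {
  cosine_sim(meanA, meanB)
}

#' Shuffle-null overlap
#'
#' The chance level of [overlap()] under random reassignment of neuron
#' identities: both mean vectors are independently permuted and the cosine
#' similarity is averaged over `n_shuffle` realizations.
#'
#' @param meanA,meanB Length-N mean rate vectors.
#' @param n_shuffle Number of shuffle realizations (default 20).
#' @param seed Integer seed for the shuffle stream.
#' @return Scalar mean shuffled overlap.
#' @export
overlap_shuffle <- function(meanA, meanB, n_shuffle = 20L, seed = 1L) {
  N <- length(meanA)
  rng <- local_seed(seed)
  on.exit(rng())
  mean(vapply(seq_len(n_shuffle), function(s) {
    cosine_sim(meanA[sample.int(N)], meanB[sample.int(N)])
  }, numeric(1)))
}

#' Per-neuron spatial correlation between two environments
#'
#' For every neuron active in both environments (any post-threshold rate > 0),
#' the cosine similarity between its two rate maps (vectors over positions) is
#' computed; the statistic is the mean over those co-active neurons. High
#' values mean neurons keep their firing locations across environments.
#'
#' @param ratesA,ratesB N x G thresholded rate matrices on the same grid.
#' @return Scalar mean spatial correlation.
#' @export
spatial_correlation <- function(ratesA, ratesB) {
  act <- coactive_neurons(ratesA, ratesB)
  mean(vapply(act, function(i) cosine_sim(ratesA[i, ], ratesB[i, ]),
              numeric(1)))
}

#' Shuffle-null spatial correlation
#'
#' Chance level of [spatial_correlation()]: the same average but across
#' randomly chosen pairs of distinct co-active neurons i != j (neuron i's map
#' in A against neuron j's map in B), averaged over `n_shuffle` resamples.
#'
#' @param ratesA,ratesB N x G thresholded rate matrices.
#' @param n_shuffle Number of resamples (default 20).
#' @param seed Integer seed.
#' @return Scalar mean shuffled spatial correlation.
#' @export
spatial_correlation_shuffle <- function(ratesA, ratesB, n_shuffle = 20L,
                                        seed = 1L) {
  act <- coactive_neurons(ratesA, ratesB)
  n <- length(act)
  if (n < 2L) stop("need at least two co-active neurons for the shuffle null")
  rng <- local_seed(seed)
  on.exit(rng())
  mean(vapply(seq_len(n_shuffle), function(s) {
    # random partner j != i for every co-active neuron
    j <- vapply(seq_len(n), function(k) {
      pool <- act[-k]
      pool[sample.int(length(pool), 1L)]
    }, numeric(1))
    mean(vapply(seq_len(n), function(k) {
      cosine_sim(ratesA[act[k], ], ratesB[j[k], ])
    }, numeric(1)))
  }, numeric(1)))
}

#' Significance of pairwise statistics against the shuffle mean
#'
#' Two-sided one-sample t-test of the per-pair statistics against the overall
#' shuffle mean, with a Bonferroni-corrected threshold
#' \eqn{p_{thresh} = 0.05 / n_{tests}} (`n_tests` = number of parameter
#' settings in a sweep; 1 for a single run).
#'
#' @param pair_stats Numeric vector of per-environment-pair statistics.
#' @param shuffle_mean Overall mean of the corresponding shuffle statistic.
#' @param n_tests Bonferroni divisor.
#' @param alpha Family-wise level (default 0.05).
#' @return List with `p_value`, `t`, `p_thresh`, `significant`, `direction`
#'   (sign of mean difference).
#' @export
significance <- function(pair_stats, shuffle_mean, n_tests = 1L,
                         alpha = 0.05) {
  pair_stats <- pair_stats[!is.na(pair_stats)]
  if (length(pair_stats) < 2L) {
    stop("need at least two environment pairs for the t-test")
  }
  p_thresh <- alpha / n_tests
  if (stats::sd(pair_stats) == 0) {
    # degenerate: all pair statistics identical
    p <- if (pair_stats[1] == shuffle_mean) 1 else 0
    tval <- if (pair_stats[1] == shuffle_mean) 0 else Inf
  } else {
    ht <- stats::t.test(pair_stats, mu = shuffle_mean)
    p <- ht$p.value
    tval <- unname(ht$statistic)
  }
  list(p_value = p, t = tval, p_thresh = p_thresh,
       significant = p < p_thresh,
       direction = sign(mean(pair_stats) - shuffle_mean))
}

#' Decompose the remapping vector into spatial, cognitive and null parts
#'
#' For a pair of environments the remapping vector at each position is
#' \eqn{\Delta r(p) = r^A(p) - r^B(p)}. Its norm (root-mean-square over
#' positions by default) is split into the component visible to the positional
#' decoder rows, the component visible to the cognitive rows, and the
#' null-space component \eqn{\Delta r - E D \Delta r} invisible to the decoder
#' altogether. With orthonormal encoder columns the squared total equals the
#' squared decoded part plus the squared null part (Pythagoras).
#'
#' @param ratesA,ratesB N x G rate matrices.
#' @param D Y x N decoder.
#' @param E N x Y encoder (right pseudo-inverse of D).
#' @param p_rows Number of leading decoder rows that read out positional
#'   latents; the remaining rows are cognitive. `NULL` means all rows are
#'   spatial (C = 0 scenarios), so the cognitive norm is 0.
#' @param aggregate `"rms"` (default) or `"sum"` over grid positions.
#' @return List with nonnegative scalars `total`, `spatial`, `cognitive`,
#'   `null_space`.
#' @export
remap_norms <- function(ratesA, ratesB, D, E, p_rows = NULL,
                        aggregate = c("rms", "sum")) {
  aggregate <- match.arg(aggregate)
  dr <- as.matrix(ratesA) - as.matrix(ratesB)
  Y <- nrow(D)
  if (is.null(p_rows)) p_rows <- Y
  dz <- D %*% dr
  dnull <- dr - E %*% dz
  agg <- function(M) {
    v <- sqrt(colSums(M^2))
    if (aggregate == "rms") sqrt(mean(v^2)) else sum(v)
  }
  list(
    total = agg(dr),
    spatial = if (p_rows > 0L) agg(dz[seq_len(p_rows), , drop = FALSE]) else 0,
    cognitive = if (p_rows < Y) agg(dz[(p_rows + 1L):Y, , drop = FALSE]) else 0,
    null_space = agg(dnull)
  )
}

#' Place-field statistics for one environment
#'
#' `pct_active` is the percentage of neurons with any post-threshold rate > 0.
#' A neuron's field size is the percentage of grid positions where its rate
#' exceeds `field_fraction` (default 0.1) of its own peak; fields need not be
#' contiguous, so multi-field neurons are measured as the union of their
#' fields. `mean_field_size_pct` averages over active neurons.
#'
#' @param rates N x G thresholded rate matrix.
#' @param field_fraction Fraction of the peak defining the field (default 0.1).
#' @return List with `pct_active`, `mean_field_size_pct` (NA when no neuron is
#'   active), and `field_size_pct` per active neuron (named by neuron index).
#' @export
place_field_stats <- function(rates, field_fraction = 0.1) {
  rates <- as.matrix(rates)
  G <- ncol(rates)
  active <- which(apply(rates > 0, 1L, any))
  pct_active <- 100 * length(active) / nrow(rates)
  if (length(active) == 0L) {
    return(list(pct_active = 0, mean_field_size_pct = NA_real_,
                field_size_pct = numeric(0)))
  }
  sizes <- vapply(active, function(i) {
    peak <- max(rates[i, ])
    100 * sum(rates[i, ] > field_fraction * peak) / G
  }, numeric(1))
  names(sizes) <- active
  list(pct_active = pct_active,
       mean_field_size_pct = mean(sizes),
       field_size_pct = sizes)
}

#' Full pairwise remapping analysis over a set of environments
#'
#' Computes, for every environment pair, the overlap, the spatial correlation,
#' their shuffle nulls, and the remapping-norm decomposition; then the means
#' over pairs and the t-test significance of each statistic against its
#' overall shuffle mean. Pairs in which an environment is silent (all rates
#' zero after thresholding, so cosine similarity is undefined) are reported as
#' `NA` and excluded from the means and tests.
#'
#' @param ratemaps List of `ratemap_set` objects (or plain rate matrices) on a
#'   common grid.
#' @param D,E Decoder and encoder of the shared network.
#' @param p_rows Positional decoder rows (see [remap_norms()]).
#' @param pairs `"all"` for all unordered pairs, `"vs_first"` to compare every
#'   environment against the first only (used for null-space sweeps against
#'   the default map).
#' @param n_shuffle Shuffle realizations per pair (default 20).
#' @param n_tests Bonferroni divisor for the significance threshold.
#' @param seed Master seed for the shuffle streams (one independent stream per
#'   pair).
#' @param threshold Rate-zeroing threshold (default 1e-3).
#' @param field_fraction Field-size definition (see [place_field_stats()]).
#' @return A `remapping_stats` object: list with `pairs` (data.frame),
#'   `summary` (means + tests), `fields` (per-environment place-field stats).
#' @export
analyze_ratemaps <- function(ratemaps, D, E, p_rows = NULL,
                             pairs = c("all", "vs_first"), n_shuffle = 20L,
                             n_tests = 1L, seed = 1L, threshold = 1e-3,
                             field_fraction = 0.1) {
  pairs <- match.arg(pairs)
  mats <- lapply(ratemaps, function(x) {
    if (inherits(x, "ratemap_set")) x$rates else as.matrix(x)
  })
  K <- length(mats)
  if (K < 2L) stop("need at least two environments")
  prep <- lapply(mats, preprocess_ratemaps, threshold = threshold)
  idx <- if (pairs == "all") {
    utils::combn(K, 2L)
  } else {
    rbind(1L, 2:K)
  }
  n_pairs <- ncol(idx)
  rows <- vector("list", n_pairs)
  for (q in seq_len(n_pairs)) {
    a <- idx[1L, q]; b <- idx[2L, q]
    sseed <- derive_seed(seed, 1000L + q)
    silent <- !any(prep[[a]]$rates > 0) || !any(prep[[b]]$rates > 0)
    coact <- if (silent) integer(0) else
      coactive_indices(prep[[a]]$rates, prep[[b]]$rates)
    if (silent || length(coact) < 2L) {
      om <- om_sh <- rho <- rho_sh <- NA_real_
      note <- if (silent) "silent environment" else "too few co-active neurons"
    } else {
      om <- overlap(prep[[a]]$mean, prep[[b]]$mean)
      om_sh <- overlap_shuffle(prep[[a]]$mean, prep[[b]]$mean,
                               n_shuffle = n_shuffle, seed = sseed)
      rho <- spatial_correlation(prep[[a]]$rates, prep[[b]]$rates)
      rho_sh <- spatial_correlation_shuffle(prep[[a]]$rates, prep[[b]]$rates,
                                            n_shuffle = n_shuffle,
                                            seed = sseed + 1L)
      note <- ""
    }
    nm <- remap_norms(prep[[a]]$rates, prep[[b]]$rates, D, E, p_rows = p_rows)
    rows[[q]] <- data.frame(
      env_a = a, env_b = b, overlap = om, overlap_shuffle = om_sh,
      spatial_corr = rho, spatial_corr_shuffle = rho_sh,
      norm_total = nm$total, norm_spatial = nm$spatial,
      norm_cognitive = nm$cognitive, norm_null = nm$null_space,
      note = note, stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$overlap)
  if (!any(ok)) stop("no valid environment pairs (all silent or degenerate)")
  if (sum(ok) >= 2L) {
    om_test <- significance(tab$overlap[ok], mean(tab$overlap_shuffle[ok]),
                            n_tests = n_tests)
    rho_test <- significance(tab$spatial_corr[ok],
                             mean(tab$spatial_corr_shuffle[ok]),
                             n_tests = n_tests)
  } else {
    # a single pair cannot support a t-test over pair means
    om_test <- rho_test <- NULL
  }
  fields <- lapply(prep, function(p) {
    place_field_stats(p$rates, field_fraction = field_fraction)
  })
  structure(list(
    pairs = tab,
    summary = list(
      overlap_mean = mean(tab$overlap[ok]),
      overlap_shuffle_mean = mean(tab$overlap_shuffle[ok]),
      spatial_corr_mean = mean(tab$spatial_corr[ok]),
      spatial_corr_shuffle_mean = mean(tab$spatial_corr_shuffle[ok]),
      overlap_test = om_test,
      spatial_corr_test = rho_test,
      n_pairs = n_pairs,
      n_pairs_used = sum(ok),
      n_tests = n_tests
    ),
    fields = fields
  ), class = "remapping_stats")
}

#' @export
print.remapping_stats <- function(x, ...) {
  s <- x$summary
  star <- function(t) {
    if (is.null(t)) return("(single pair, no test)")
    pt <- sprintf("p = %.3g", t$p_value)
    if (t$significant) {
      paste(pt, if (t$direction > 0) "* (above shuffle)" else "* (below shuffle)")
    } else {
      paste(pt, "n.s.")
    }
  }
  cat(sprintf("Remapping statistics over %d pairs (%d used):\n",
              s$n_pairs, s$n_pairs_used))
  cat(sprintf("  overlap        %.4f  vs shuffle %.4f  %s\n",
              s$overlap_mean, s$overlap_shuffle_mean, star(s$overlap_test)))
  cat(sprintf("  spatial corr   %.4f  vs shuffle %.4f  %s\n",
              s$spatial_corr_mean, s$spatial_corr_shuffle_mean,
              star(s$spatial_corr_test)))
  invisible(x)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector")
  }
  sum(a * b) / (na * nb)
}

coactive_indices <- function(ratesA, ratesB) {
  which(apply(ratesA > 0, 1L, any) & apply(ratesB > 0, 1L, any))
}

coactive_neurons <- function(ratesA, ratesB) {
  act <- coactive_indices(ratesA, ratesB)
  if (length(act) == 0L) {
    stop("no neurons are active in both environments")
  }
  act
}
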