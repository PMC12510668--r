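#' Run a full remapping scenario end to end
#'
#' Builds the position grid, per-environment cognitive trajectories and
#' embedding maps, samples the network, solves the steady-state rate maps for
#' every environment, and runs the full pairwise remapping analysis. All
#' randomness derives from the config's master seed via counter-based
#' sub-seeds, so identical configs reproduce bit-identical results and adding
#' environments does not perturb earlier ones.
#'
#' @param config A `scenario_config` (see [scenario_config()]).
#' @param out_dir Optional output directory; when given, results are persisted
#'   with [persist_record()].
#' @param verbose Log progress to stderr.
#' @return A `run_record`: list with `config`, `grid`, `latents` (Z x G per
#'   environment), `embeddings` (Y x G per environment), `maps`, `network`,
#'   `thresholds` (per environment), `ratemaps`, `stats`
#'   (a `remapping_stats`), `quality` (autoencoding error summary), and for
#'   null-space runs `ns` (decoded-vs-rate change ratios against the default
#'   map).
#' @export
run_scenario <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  say <- function(...) if (verbose) message(sprintf(...))
  grid <- position_grid(cf$grid_n, max(cf$P, 1L))
  G <- ncol(grid)
  p_lat <- 2L * cf$m * cf$P   # positional latent rows

  # shared positional latents
  z_p <- if (cf$P > 0L) encode_grid(grid, f = cf$f) else NULL

  # per-environment cognitive trajectories
  cvals <- vector("list", cf$K)
  if (cf$C > 0L) {
    for (k in seq_len(cf$K)) {
      cvals[[k]] <- if (cf$kind == "reward") {
        reward_profile(grid, cf$reward_mu[k], cf$reward_sigma)
      } else {
        sample_cognitive_trajectory(grid, cf$C, cf$sigma, v = cf$v,
                                    seed = derive_seed(cf$seed, 10L + k))
      }
    }
  }

  # per-environment latents, block-normalized and rescaled
  latents <- vector("list", cf$K)
  for (k in seq_len(cf$K)) {
    z <- if (cf$C > 0L) {
      zc <- encode_angles(cvals[[k]])
      if (is.null(z_p)) as.matrix(zc) else rbind(as.matrix(z_p), as.matrix(zc))
    } else {
      as.matrix(z_p)
    }
    latents[[k]] <- normalize_blocks(z,
                                     p_rows = if (cf$C > 0L) p_lat else nrow(z),
                                     rescale_dim = cf$Y,
                                     rescale_cutoff = cf$rescale_cutoff)
  }

  # embedding maps
  maps <- vector("list", cf$K)
  for (k in seq_len(cf$K)) {
    mseed <- derive_seed(cf$seed, 100L + k)
    maps[[k]] <- switch(cf$kind,
      multi_chart = sample_multichart_map(cf$Y, cf$Z, seed = mseed,
                                          environment_id = k),
      grid_realign = sample_gridshift_map(cf$m, cf$P, seed = mseed,
                                          environment_id = k),
      null_space = sample_multichart_map(cf$Y, cf$Z,
                                         seed = derive_seed(cf$seed, 101L),
                                         environment_id = k),
      identity_map(cf$Z, environment_id = k)
    )
  }
  embeddings <- lapply(seq_len(cf$K), function(k) {
    build_embedding(latents[[k]], maps[[k]])
  })

  # shared network
  network <- sample_decoder(cf$Y, cf$N, code = cf$code,
                            seed = derive_seed(cf$seed, 1L),
                            p_rows = if (p_lat > 0L) p_lat else NULL,
                            pure_P = cf$pure_P, pure_C = cf$pure_C,
                            identity = cf$full_D)

  # per-environment thresholds (modulated for null-space runs)
  thresholds <- vector("list", cf$K)
  suppressed <- vector("list", cf$K)
  spar_of_env <- NULL
  if (cf$kind == "null_space") {
    spar_of_env <- c(cf$spar_default,
                     rep(cf$spar_sweep, each = cf$ns_repeats))
  }
  for (k in seq_len(cf$K)) {
    if (cf$kind == "null_space") {
      mod <- modulate_thresholds(network$T, spar_of_env[k],
                                 seed = derive_seed(cf$seed, 200L + k),
                                 T_suppr = cf$T_suppr)
      thresholds[[k]] <- mod$T
      suppressed[[k]] <- mod$suppressed
    } else {
      thresholds[[k]] <- network$T
      suppressed[[k]] <- integer(0)
    }
  }

  say("solving %d x %d rate maps for %d environments", cf$N, G, cf$K)
  ratemaps <- lapply(seq_len(cf$K), function(k) {
    batch_solve(embeddings[[k]], network$D, thresholds[[k]], E = network$E,
                environment_id = k)
  })

  # autoencoding quality: relative embedding reconstruction error per point
  rel_err <- lapply(seq_len(cf$K), function(k) {
    num <- sqrt(colSums((ratemaps[[k]]$decoded - embeddings[[k]])^2))
    den <- sqrt(colSums(embeddings[[k]]^2))
    num / den
  })
  quality <- list(median_rel_error = stats::median(unlist(rel_err)),
                  per_env_median = vapply(rel_err, stats::median, numeric(1)))

  # decoder rows carrying cognitive latents (mixed-selective kinds only)
  p_rows_dec <- if (cf$kind %in% c("space_feature", "implicit_space", "reward")) {
    p_lat
  } else {
    NULL
  }
  say("analyzing %d environment pairs", choose(cf$K, 2L))
  stats_out <- analyze_ratemaps(
    ratemaps, network$D, network$E, p_rows = p_rows_dec,
    pairs = if (cf$kind == "null_space") "vs_first" else "all",
    n_shuffle = cf$n_shuffle, n_tests = cf$n_tests,
    seed = derive_seed(cf$seed, 2L)
  )

  ns <- NULL
  if (cf$kind == "null_space") {
    ns <- ns_change_ratios(ratemaps, network$D)
    ns$spar <- spar_of_env[-1L]
  }

  record <- structure(list(
    config = cf, grid = grid, latents = latents, embeddings = embeddings,
    maps = maps, network = network, thresholds = thresholds,
    suppressed = suppressed, spar_of_env = spar_of_env,
    ratemaps = ratemaps, stats = stats_out,
    quality = quality, ns = ns,
    version = as.character(utils::packageVersion("remapgeom"))
  ), class = "run_record")
  if (!is.null(out_dir)) persist_record(record, out_dir)
  record
}

# For each modulated map, how much of the activity change relative to the
# default map is visible to the decoder (should be tiny for pure null-space
# remapping) and how much the decoded estimate moves relative to the rates.
ns_change_ratios <- function(ratemaps, D) {
  K <- length(ratemaps)
  ref <- ratemaps[[1L]]
  out <- data.frame(env = 2:K, decoded_ratio = NA_real_,
                    decoded_shift_ratio = NA_real_)
  for (k in 2:K) {
    dr <- ratemaps[[k]]$rates - ref$rates
    dz <- D %*% dr
    nr <- sqrt(colSums(dr^2))
    nz <- sqrt(colSums(dz^2))
    keep <- nr > 1e-9
    out$decoded_ratio[k - 1L] <- if (any(keep)) {
      stats::median(nz[keep] / nr[keep])
    } else {
      0
    }
    out$decoded_shift_ratio[k - 1L] <-
      stats::median(sqrt(colSums((ratemaps[[k]]$decoded - ref$decoded)^2))) /
      max(stats::median(nr), 1e-12)
  }
  out
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record: %s scenario, %d environments, N = %d>\n",
              x$config$kind, x$config$K, x$config$N))
  cat(sprintf("  median autoencoding rel. error: %.4f\n",
              x$quality$median_rel_error))
  print(x$stats)
  invisible(x)
}
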