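#' Compare coding schemes in the reward-location case
#'
#' For a `"reward"` scenario run, characterizes how the code scheme shapes the
#' representation around the reward. Winners are computed from the feedforward
#' excitation \eqn{D'y} along each environment's latent trajectory, the regime
#' in which pure-selective neurons are not yet out-competed by the recurrent
#' winner-take-all dynamics.
#'
#' Two zones are used. The *density zone* (default half-width
#' `2 * reward_sigma`) covers the region where the reward signal varies
#' appreciably; the count of distinct winning neurons per unit position is
#' compared inside versus outside it ("denser firing near rewards"). The
#' *location zone* (default half-width `reward_sigma`) brackets the reward
#' location proper and is used for winner-set identity comparisons: which
#' pure-cognitive ("reward") neurons respond at both environments' reward
#' locations, and whether the conjunctive winner sets at the two locations are
#' disjoint once spatially-driven winners (those that also win somewhere
#' outside the zones) are discounted.
#'
#' @param record A `run_record` from a `"reward"` scenario.
#' @param density_halfwidth Half-width of the density zone in position units
#'   (default `2 * reward_sigma`).
#' @param location_halfwidth Half-width of the location zone (default
#'   `reward_sigma`).
#' @return List with per-environment vectors `winner_density_in`,
#'   `winner_density_out` (distinct winners per unit position, density zone);
#'   `zone_winners` and `outside_winners` (location zone; lists of neuron
#'   index vectors); `pure_C_ids`; `pure_shared_active` (pure-cognitive
#'   neurons with above-threshold feedforward excitation inside the location
#'   zone of every environment); and `zone_overlap_nonspatial` (winners shared
#'   between the two location zones that never win outside any zone).
#' @export
reward_code_comparison <- function(record, density_halfwidth = NULL,
                                   location_halfwidth = NULL) {
  stopifnot(inherits(record, "run_record"))
  cf <- record$config
  if (cf$kind != "reward") stop("record is not from a reward scenario")
  if (is.null(density_halfwidth)) density_halfwidth <- 2 * cf$reward_sigma
  if (is.null(location_halfwidth)) location_halfwidth <- cf$reward_sigma
  D <- record$network$D
  Tvec <- record$network$T
  p <- record$grid[1L, ]
  step <- p[2L] - p[1L]
  K <- cf$K
  dens_in <- dens_out <- numeric(K)
  zone_winners <- outside_winners <- active_pure <- vector("list", K)
  pure_ids <- if (cf$code == "pM" && cf$pure_C > 0L) {
    cf$pure_P + seq_len(cf$pure_C)
  } else {
    integer(0)
  }
  for (k in seq_len(K)) {
    excit <- feedforward_excitation(record$embeddings[[k]], D)
    win <- apply(excit, 2L, function(e) {
      if (max(e) <= 0) NA_integer_ else which.max(e)
    })
    in_dens <- abs(p - cf$reward_mu[k]) <= density_halfwidth
    dens_in[k] <- length(unique(stats::na.omit(win[in_dens]))) /
      (sum(in_dens) * step)
    dens_out[k] <- length(unique(stats::na.omit(win[!in_dens]))) /
      (sum(!in_dens) * step)
    in_loc <- abs(p - cf$reward_mu[k]) <= location_halfwidth
    zone_winners[[k]] <- sort(unique(stats::na.omit(win[in_loc])))
    outside_winners[[k]] <- sort(unique(stats::na.omit(win[!in_loc])))
    active_pure[[k]] <- if (length(pure_ids) > 0L) {
      pure_ids[vapply(pure_ids, function(i) {
        any(excit[i, in_loc] > Tvec[i])
      }, logical(1))]
    } else {
      integer(0)
    }
  }
  shared_zone <- Reduce(intersect, zone_winners)
  any_outside <- sort(unique(unlist(outside_winners)))
  list(
    winner_density_in = dens_in,
    winner_density_out = dens_out,
    zone_winners = zone_winners,
    outside_winners = outside_winners,
    pure_C_ids = pure_ids,
    pure_shared_active = Reduce(intersect, active_pure),
    zone_overlap_nonspatial = setdiff(shared_zone, any_outside)
  )
}
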