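#' Build and validate a scenario configuration
#'
#' A scenario fixes the remapping generator and all simulation parameters.
#' Kinds:
#'
#' * `"multi_chart"`: encoder-decoder remapping by random orthonormal
#'   embedding maps (one per environment); no cognitive variables. With
#'   `full_D = TRUE` the decoder is the identity (Y = N), the maximally
#'   random ("full-D") case.
#' * `"grid_realign"`: encoder-decoder remapping by per-module phase shifts of
#'   a multi-module (grid) code; Y = Z = 2mP.
#' * `"space_feature"`: mixed-selective remapping; shared spatial latents plus
#'   environment-specific Gaussian-process cognitive trajectories; identity
#'   embedding map.
#' * `"implicit_space"`: mixed-selective remapping with no explicit position
#'   code (P = 0); place fields arise from position-dependent cognitive
#'   variables alone.
#' * `"null_space"`: a single multi-chart environment whose maps differ only
#'   by threshold (excitability) modulation; environment 1 is the default map
#'   (`spar_default`), the rest follow `spar_sweep`.
#' * `"reward"`: space-feature coding with a Gaussian reward profile as the
#'   single cognitive variable; one environment per reward location in
#'   `reward_mu`.
#'
#' Unspecified parameters take the scenario's reference defaults (desk-scale
#' versions of the published sweeps).
#'
#' @param kind Scenario kind (see above).
#' @param K Number of environments.
#' @param P,C Numbers of position / cognitive variables.
#' @param m Number of grid modules; `f` their frequency exponents
#'   (default [default_frequencies()]).
#' @param Y Embedding dimensionality; `N` network size.
#' @param code Decoder code scheme (see [sample_decoder()]).
#' @param sigma,v Cognitive-process variance parameter and GP length scale.
#' @param grid_n Grid points per position dimension.
#' @param spar_default,spar_sweep,T_suppr Null-space modulation parameters.
#' @param ns_repeats Independent random suppression draws per `spar_sweep`
#'   value (null-space runs); K = 1 + ns_repeats * length(spar_sweep).
#' @param reward_mu,reward_sigma Reward locations (length K) and spread.
#' @param pure_P,pure_C Pure-neuron counts for the `"pM"` code.
#' @param n_shuffle Shuffle realizations per pair.
#' @param n_tests Bonferroni divisor for significance.
#' @param field_fraction Place-field size definition.
#' @param rescale_cutoff Embedding dimensionalities above this trigger the
#'   linear input rescale by Y.
#' @param seed Master seed; all sub-seeds derive from it.
#' @param full_D Identity-decoder special case (multi_chart only).
#' @param f Frequency exponents (first must be 0).
#' @return A validated `scenario_config` (list).
#' @export
scenario_config <- function(kind, K = NULL, P = NULL, C = NULL, m = NULL,
                            Y = NULL, N = NULL, code = NULL, sigma = NULL,
                            v = 0.3, grid_n = NULL, spar_default = 0.5,
                            spar_sweep = NULL, T_suppr = 10,
                            ns_repeats = 5L,
                            reward_mu = NULL, reward_sigma = 0.2,
                            pure_P = 0L, pure_C = 0L, n_shuffle = 20L,
                            n_tests = 1L, field_fraction = 0.1,
                            rescale_cutoff = 4, seed = 1L, full_D = FALSE,
                            f = NULL) {
  kinds <- c("multi_chart", "grid_realign", "space_feature", "implicit_space",
             "null_space", "reward")
  if (missing(kind) || !kind %in% kinds) {
    stop("scenario kind is required; one of: ", paste(kinds, collapse = ", "))
  }
  def <- switch(kind,
    multi_chart = list(K = 10L, P = 2L, C = 0L, m = 1L,
                       Y = if (full_D) 64L else 16L,
                       N = if (full_D) 64L else 256L, code = "M",
                       sigma = 0, grid_n = 32L),
    grid_realign = list(K = 10L, P = 2L, C = 0L, m = 3L, Y = 12L, N = 96L,
                        code = "C", sigma = 0, grid_n = 32L),
    space_feature = list(K = 10L, P = 2L, C = 6L, m = 1L, Y = 16L, N = 256L,
                         code = "CM", sigma = 0.3, grid_n = 32L),
    implicit_space = list(K = 10L, P = 0L, C = 6L, m = 1L, Y = 12L, N = 256L,
                          code = "M", sigma = 0.3, grid_n = 100L),
    null_space = list(K = NULL, P = 1L, C = 0L, m = 1L, Y = 16L, N = 256L,
                      code = "M", sigma = 0, grid_n = 100L),
    reward = list(K = 2L, P = 1L, C = 1L, m = 1L, Y = 4L, N = 32L,
                  code = "C", sigma = 0, grid_n = 100L)
  )
  pick <- function(x, d) if (is.null(x)) d else x
  ns_repeats <- as.integer(ns_repeats)
  K <- as.integer(pick(K, def$K)); P <- as.integer(pick(P, def$P))
  C <- as.integer(pick(C, def$C)); m <- as.integer(pick(m, def$m))
  Y <- as.integer(pick(Y, def$Y)); N <- as.integer(pick(N, def$N))
  code <- pick(code, def$code); sigma <- pick(sigma, def$sigma)
  grid_n <- as.integer(pick(grid_n, def$grid_n))
  if (is.null(f)) f <- default_frequencies(max(m, 1L))
  if (kind == "null_space") {
    if (is.null(spar_sweep)) spar_sweep <- c(0, 0.25, 0.5, 0.75, 1)
    if (length(K) == 0L) K <- 1L + ns_repeats * length(spar_sweep)
  }
  if (kind == "reward" && is.null(reward_mu)) reward_mu <- c(-0.5, 0.5)
  if (code == "pM" && pure_P == 0L && pure_C == 0L) {
    # a quarter pure-positional, a quarter pure-cognitive, half mixed
    pure_P <- max(1L, as.integer(round(N / 4)))
    pure_C <- max(1L, as.integer(round(N / 4)))
  }

  Z <- 2L * m * P + 2L * C
  fail <- function(field, msg) stop(sprintf("config field '%s': %s", field, msg))
  if (K < 2L) fail("K", "need at least 2 environments")
  if (sigma < 0 || sigma > 1) fail("sigma", "must lie in [0, 1]")
  if (v <= 0) fail("v", "must be positive")
  if (grid_n < 2L) fail("grid_n", "need at least 2 grid points per dimension")
  if (length(f) != m || f[1] != 0) fail("f", "length m with f[1] = 0")
  if (kind %in% c("multi_chart", "null_space")) {
    if (C != 0L) fail("C", "encoder-decoder scenarios use C = 0")
    if (m != 1L) fail("m", "multi-chart scenarios use a single module")
    if (full_D && Y != N) fail("Y", "full-D case requires Y = N")
    if (Z > Y || Y > N) fail("Y", "need Z <= Y <= N")
  }
  if (kind == "grid_realign") {
    if (C != 0L) fail("C", "grid realignment uses C = 0")
    if (m < 2L) fail("m", "grid realignment needs m >= 2 modules")
    if (Y != Z) fail("Y", sprintf("grid realignment forces Y = Z = %d", Z))
  }
  if (kind == "space_feature") {
    if (P < 1L || C < 1L) fail("P", "space-feature coding needs P >= 1, C >= 1")
    if (Y != Z) fail("Y", sprintf("mixed-selective scenarios force Y = Z = %d", Z))
  }
  if (kind == "implicit_space") {
    if (P != 0L) fail("P", "implicit-space coding forces P = 0")
    if (C < 1L) fail("C", "implicit-space coding needs C >= 1")
    if (Y != Z) fail("Y", sprintf("mixed-selective scenarios force Y = Z = %d", Z))
  }
  if (kind == "null_space") {
    if (any(spar_sweep < 0 | spar_sweep > 1)) fail("spar_sweep", "values in [0, 1]")
    if (spar_default < 0 || spar_default > 1) fail("spar_default", "in [0, 1]")
    if (ns_repeats < 1L) fail("ns_repeats", "need at least one draw per spar")
    if (K != ns_repeats * length(spar_sweep) + 1L) {
      fail("K", "must equal ns_repeats * length(spar_sweep) + 1 (default map first)")
    }
  }
  if (kind == "reward") {
    if (P != 1L || C != 1L) fail("P", "reward scenario uses P = 1, C = 1")
    if (Y != Z) fail("Y", sprintf("reward scenario forces Y = Z = %d", Z))
    if (length(reward_mu) != K) fail("reward_mu", "one reward location per environment")
    if (any(reward_mu < -1 | reward_mu > 1)) fail("reward_mu", "locations in [-1, 1]")
    if (reward_sigma <= 0) fail("reward_sigma", "must be positive")
    if (!code %in% c("C", "pM", "CM", "M")) fail("code", "unknown code scheme")
  }
  if (!code %in% c("M", "C", "CM", "pM")) fail("code", "unknown code scheme")
  if (N < Y && !full_D) fail("N", "need N >= Y")
  if (pure_P + pure_C > N) fail("pure_P", "pure_P + pure_C exceeds N")

  structure(list(kind = kind, K = K, P = P, C = C, m = m, f = f, Y = Y, N = N,
                 Z = Z, code = code, sigma = sigma, v = v, grid_n = grid_n,
                 spar_default = spar_default, spar_sweep = spar_sweep,
                 ns_repeats = ns_repeats,
                 T_suppr = T_suppr, reward_mu = reward_mu,
                 reward_sigma = reward_sigma, pure_P = as.integer(pure_P),
                 pure_C = as.integer(pure_C), n_shuffle = as.integer(n_shuffle),
                 n_tests = as.integer(n_tests),
                 field_fraction = field_fraction,
                 rescale_cutoff = rescale_cutoff, seed = as.integer(seed),
                 full_D = isTRUE(full_D)),
            class = "scenario_config")
}

#' Read a scenario configuration from YAML or JSON
#'
#' Unknown keys raise a warning and are ignored; invalid values fail with the
#' offending key named. The `kind` key is required; all other keys default as
#' in [scenario_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `scenario_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  # YAML 1.1 reads the bare keys Y and N as booleans; map them back
  names(raw)[names(raw) == "TRUE"] <- "Y"
  names(raw)[names(raw) == "FALSE"] <- "N"
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
    raw <- raw[intersect(names(raw), known)]
  }
  if (is.null(raw$kind)) stop("config field 'kind': scenario kind is required")
  do.call(scenario_config, raw)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config: %s, K = %d, N = %d, Y = %d, Z = %d, seed = %d>\n",
              x$kind, x$K, x$N, x$Y, x$Z, x$seed))
  invisible(x)
}
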