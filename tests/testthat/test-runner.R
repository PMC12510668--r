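# a small multi-chart configuration used throughout this file
toy_config <- function(seed = 1L, ...) {
  scenario_config("multi_chart", K = 3L, P = 1L, Y = 3L, N = 24L,
                  grid_n = 40L, seed = seed, ...)
}

test_that("scenario constraints are enforced with the offending field named", {
  expect_error(scenario_config("implicit_space", P = 1L), "'P'")
  expect_error(scenario_config("multi_chart", sigma = 1.5), "'sigma'")
  expect_error(scenario_config("multi_chart", C = 2L), "'C'")
  expect_error(scenario_config("grid_realign", m = 1L), "'m'")
  expect_error(scenario_config("grid_realign", Y = 10L), "'Y'")
  expect_error(scenario_config("multi_chart", Y = 300L), "'Y'")
  expect_error(scenario_config("reward", reward_mu = c(0, 0, 0)), "'reward_mu'")
  expect_error(scenario_config("null_space", spar_sweep = c(0.5, 2)),
               "'spar_sweep'")
  expect_error(scenario_config(), "kind is required")
  # defaults: three modules get the standard frequency exponents
  cf <- scenario_config("grid_realign")
  expect_identical(cf$f, c(0L, 1L, -1L))
  expect_equal(cf$Z, 12L)
})

test_that("configs parse from YAML and JSON with unknown keys warned", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("kind: multi_chart", "K: 3", "P: 1", "Y: 3", "N: 24",
               "grid_n: 40", "seed: 7", "bogus_key: 1"), yml)
  expect_warning(cf <- parse_config(yml), "bogus_key")
  expect_equal(cf$K, 3L)
  expect_equal(cf$seed, 7L)
  # bare Y/N keys survive YAML 1.1 boolean coercion
  expect_equal(cf$Y, 3L)
  expect_equal(cf$N, 24L)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(list(kind = "reward", reward_sigma = 0.3), jsn,
                       auto_unbox = TRUE)
  cfj <- parse_config(jsn)
  expect_equal(cfj$kind, "reward")
  expect_equal(cfj$reward_sigma, 0.3)
  # kind is required
  empty <- tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_error(parse_config(empty), "kind")
  unlink(c(yml, jsn, empty))
})

test_that("a toy multi-chart run produces coherent rate maps and stats", {
  rec <- run_scenario(toy_config())
  expect_s3_class(rec, "run_record")
  expect_length(rec$ratemaps, 3)
  expect_equal(dim(rec$ratemaps[[1]]$rates), c(24L, 40L))
  expect_true(all(rec$ratemaps[[1]]$rates >= 0))
  expect_equal(nrow(rec$stats$pairs), 3)
  expect_true(all(rec$stats$pairs$overlap >= 0 & rec$stats$pairs$overlap <= 1))
  # KKT certificate holds across sampled grid points of each environment
  for (k in 1:3) {
    res <- vapply(seq(1, 40, by = 7), function(g) {
      kkt_residual(rec$embeddings[[k]][, g], rec$network$D,
                   rec$thresholds[[k]], rec$ratemaps[[k]]$rates[, g])
    }, numeric(1))
    expect_lt(max(res), 1e-6)
  }
})

test_that("identical configs reproduce byte-identical persisted statistics", {
  d1 <- file.path(tempdir(), "run_a")
  d2 <- file.path(tempdir(), "run_b")
  run_scenario(toy_config(seed = 5L), out_dir = d1)
  run_scenario(toy_config(seed = 5L), out_dir = d2)
  f1 <- file.path(d1, "stats_pairs.csv")
  f2 <- file.path(d2, "stats_pairs.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(unname(tools::md5sum(file.path(d1, "ratemap_env01.csv"))),
                   unname(tools::md5sum(file.path(d2, "ratemap_env01.csv"))))
  # a different seed changes the maps
  d3 <- file.path(tempdir(), "run_c")
  run_scenario(toy_config(seed = 6L), out_dir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "ratemap_env01.csv"))),
    unname(tools::md5sum(file.path(d3, "ratemap_env01.csv")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("persisted runs reload and re-analyze to the in-process statistics", {
  dir <- file.path(tempdir(), "run_persist")
  rec <- run_scenario(toy_config(seed = 9L), out_dir = dir)
  # manifest lists every written file with a checksum
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  listed <- vapply(man$files, function(f) f$path, character(1))
  expect_true(all(c("config.json", "stats_pairs.csv", "summary.json") %in% listed))
  for (f in man$files) {
    expect_identical(unname(tools::md5sum(file.path(dir, f$path))), f$md5)
  }
  # re-analysis from disk reproduces the in-process analysis exactly
  res <- load_and_analyze(dir)
  expect_equal(res$stats$pairs$overlap, rec$stats$pairs$overlap,
               tolerance = 1e-15)
  expect_equal(res$stats$summary$overlap_test$p_value,
               rec$stats$summary$overlap_test$p_value, tolerance = 1e-15)
  # manifest from another version warns but proceeds
  man$version <- "0.0.0.9999"
  jsonlite::write_json(man, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_warning(load_and_analyze(dir), "version")
  unlink(dir, recursive = TRUE)
})

test_that("null-space runs attach spar labels and change ratios", {
  cf <- scenario_config("null_space", N = 32L, Y = 4L, grid_n = 30L,
                        spar_sweep = c(0.5, 1), ns_repeats = 2L, seed = 2)
  rec <- run_scenario(cf)
  expect_equal(rec$spar_of_env, c(0.5, 0.5, 0.5, 1, 1))
  expect_equal(nrow(rec$ns), 4)
  expect_true(all(rec$ns$decoded_ratio >= 0))
  # suppressed sets differ between repeats of the same spar
  expect_false(identical(rec$suppressed[[2]], rec$suppressed[[3]]))
})
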