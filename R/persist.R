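#' Persist a run record to disk
#'
#' Writes the config (JSON), one full-precision rate-map CSV per environment,
#' the pairwise statistics table (CSV), a JSON summary (means, tests,
#' autoencoding quality, config echo), and a manifest JSON listing every file
#' with its md5 checksum. Numbers are written with 17 significant digits so
#' doubles round-trip exactly; re-running with the same config and seed
#' produces byte-identical stats files.
#'
#' @param record A `run_record` from [run_scenario()].
#' @param dir Output directory (created if missing).
#' @param figures Also render tuning-mosaic PNGs (one per environment).
#' @return Invisibly, the manifest as a list.
#' @export
persist_record <- function(record, dir, figures = FALSE) {
  stopifnot(inherits(record, "run_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cf <- record$config
  files <- character(0)

  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cf), cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, cfg_path)

  for (k in seq_along(record$ratemaps)) {
    p <- file.path(dir, sprintf("ratemap_env%02d.csv", k))
    write_matrix_csv(record$ratemaps[[k]]$rates, p)
    files <- c(files, p)
  }

  stats_path <- file.path(dir, "stats_pairs.csv")
  tab <- record$stats$pairs
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.csv(tab, stats_path, row.names = FALSE)
  files <- c(files, stats_path)

  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(summary = record$stats$summary,
         quality = record$quality,
         ns = record$ns,
         fields = lapply(record$stats$fields, function(f) {
           f[c("pct_active", "mean_field_size_pct")]
         }),
         config = unclass(cf),
         version = record$version),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE,
    force = TRUE)
  files <- c(files, summary_path)

  if (figures) {
    for (k in seq_along(record$ratemaps)) {
      p <- file.path(dir, sprintf("mosaic_env%02d.png", k))
      grDevices::png(p, width = 600, height = 600)
      mos <- argmax_mosaic(record$network, map = record$maps[[k]],
                           mesh_n = 200L, f = cf$f,
                           suppressed = record$suppressed[[k]],
                           rescale_dim = cf$Y,
                           rescale_cutoff = cf$rescale_cutoff)
      plot(mos, main = sprintf("environment %d", k))
      grDevices::dev.off()
      files <- c(files, p)
    }
  }

  manifest <- list(
    package = "remapgeom",
    version = record$version,
    created = format(Sys.time(), tz = "UTC"),
    files = lapply(files, function(fp) {
      list(path = basename(fp), md5 = unname(tools::md5sum(fp)))
    })
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Load persisted rate maps and re-run the analysis
#'
#' Reads the rate maps and config written by [persist_record()] and reproduces
#' the in-process analysis exactly (the CSVs round-trip doubles at full
#' precision). A manifest written by a different package version triggers a
#' warning but loading proceeds.
#'
#' @param dir Directory written by [persist_record()].
#' @return List with `config`, `ratemaps` (plain matrices), `stats`.
#' @export
load_and_analyze <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path)
    cur <- as.character(utils::packageVersion("remapgeom"))
    if (!identical(man$version, cur)) {
      warning(sprintf("manifest written by version %s, loading with %s",
                      man$version, cur))
    }
  }
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  keep <- intersect(names(cfg_raw), names(formals(scenario_config)))
  cf <- do.call(scenario_config, cfg_raw[keep])
  rate_files <- sort(list.files(dir, pattern = "^ratemap_env[0-9]+\\.csv$",
                                full.names = TRUE))
  if (length(rate_files) < 2L) stop("no persisted rate maps found in ", dir)
  ratemaps <- lapply(rate_files, read_matrix_csv)
  # the analysis needs the shared network, reproducible from the config seed
  p_lat <- 2L * cf$m * cf$P
  network <- sample_decoder(cf$Y, cf$N, code = cf$code,
                            seed = derive_seed(cf$seed, 1L),
                            p_rows = if (p_lat > 0L) p_lat else NULL,
                            pure_P = cf$pure_P, pure_C = cf$pure_C,
                            identity = cf$full_D)
  p_rows_dec <- if (cf$kind %in% c("space_feature", "implicit_space",
                                   "reward")) p_lat else NULL
  stats_out <- analyze_ratemaps(
    ratemaps, network$D, network$E, p_rows = p_rows_dec,
    pairs = if (cf$kind == "null_space") "vs_first" else "all",
    n_shuffle = cf$n_shuffle, n_tests = cf$n_tests,
    seed = derive_seed(cf$seed, 2L))
  list(config = cf, ratemaps = ratemaps, stats = stats_out)
}

write_matrix_csv <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", nrow(M), " x ", ncol(M)), con)
  for (i in seq_len(nrow(M))) {
    writeLines(paste(sprintf("%.17g", M[i, ]), collapse = ","), con)
  }
  invisible(path)
}

read_matrix_csv <- function(path) {
  lines <- readLines(path)
  stopifnot(startsWith(lines[1], "# "))
  vals <- strsplit(lines[-1], ",", fixed = TRUE)
  do.call(rbind, lapply(vals, as.numeric))
}
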