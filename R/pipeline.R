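# Shared helpers for the stage runners: each stage writes its artifacts
# into `outdir` together with a manifest recording the configuration,
# the seed and a config hash, so identical configs yield identical
# artifacts and runs are auditable.

default_run_config <- function() {
  list(
    input = NULL,
    conf_level = 0.95,
    ci_method = "wilson",
    tol_deg = 1e-3,
    lag_width = 60,
    cutoff = 2000,
    weight_mode = "npairs_over_h2",
    bbox = c(34, 71, -11, 61),
    resolution = 0.5,
    clamp = TRUE,
    neighborhood = NULL,
    k_inv = 0L,
    n_inv = 40L,
    alpha = 0.05,
    seed = 1L,
    outdir = "."
  )
}

#' Load a run configuration
#'
#' Reads a YAML configuration file and merges it over the documented
#' defaults; entries in `overrides` (e.g. command-line flags) take
#' precedence over the file, which takes precedence over defaults.
#'
#' @param path Optional path to a YAML file.
#' @param overrides Named list of values overriding the file.
#' @return A named list with the full run configuration.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path), class = "wolb_io_error")
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  cfg
}

write_manifest <- function(cfg, stage, outdir) {
  manifest <- list(
    stage = stage,
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    config_hash = rlang::hash(cfg[order(names(cfg))])
  )
  jsonlite::write_json(
    manifest, file.path(outdir, paste0(stage, "_manifest.json")),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the frequency-estimation stage
#'
#' Reads a population table, estimates per-population infection
#' frequencies with binomial confidence intervals, and writes
#' `frequencies.csv` plus a manifest to `outdir`.
#'
#' @param config A run configuration list (see [load_run_config()]);
#'   `config$input` must name the population CSV.
#' @return The estimates tibble, invisibly.
#' @export
run_freqs <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  tbl <- read_population_table(cfg$input)
  stage_log("freqs", "read %d populations from %s", nrow(tbl), cfg$input)
  est <- estimate_frequencies(tbl, conf_level = cfg$conf_level, method = cfg$ci_method)
  if (nrow(est) == 0) warn("input table is empty; writing empty estimates")
  readr::write_csv(est, file.path(cfg$outdir, "frequencies.csv"), progress = FALSE)
  write_manifest(cfg, "freqs", cfg$outdir)
  invisible(est)
}

#' Run the variogram stage
#'
#' Reads a population table, removes duplicate locations, computes the
#' empirical semivariogram of the observed infection frequencies and
#' fits the exponential model. Writes `empirical_variogram.csv` and
#' `variogram_model.json`.
#'
#' @param config A run configuration list; uses `input`, `tol_deg`,
#'   `lag_width`, `cutoff`, `weight_mode`, `seed`.
#' @return The `wolb_variogram_fit`, invisibly.
#' @export
run_variogram <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  tbl <- read_population_table(cfg$input)
  n_raw <- nrow(tbl)
  tbl <- filter_duplicate_locations(tbl, seed = cfg$seed, tol_deg = cfg$tol_deg)
  stage_log(
    "variogram", "%d populations (%d duplicate locations dropped)",
    nrow(tbl), n_raw - nrow(tbl)
  )
  emp <- empirical_variogram(tbl, tbl$k / tbl$n,
    lag_width = cfg$lag_width, cutoff = cfg$cutoff
  )
  fit <- fit_exponential(emp, weight_mode = cfg$weight_mode)
  readr::write_csv(
    as_tibble(emp), file.path(cfg$outdir, "empirical_variogram.csv"),
    progress = FALSE
  )
  jsonlite::write_json(
    list(
      C0 = fit$C0, C1 = fit$C1, b = fit$b, sse = fit$sse,
      weight_mode = fit$weight_mode, converged = fit$converged,
      range_identifiable = fit$range_identifiable,
      seed = cfg$seed, config_hash = rlang::hash(cfg[order(names(cfg))])
    ),
    file.path(cfg$outdir, "variogram_model.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_manifest(cfg, "variogram", cfg$outdir)
  invisible(fit)
}

read_variogram_model <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("variogram model file not found: ", path), class = "wolb_io_error")
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the kriging stage
#'
#' Reads a population table and a fitted variogram model, kriges the
#' infection frequency over the configured grid, cross-validates by
#' leave-one-out, and writes `surface.csv`, `surface.geojson`,
#' `loocv.csv` and `loocv_summary.json`.
#'
#' @param config A run configuration list; uses `input`, `model_file`
#'   (defaults to `variogram_model.json` in `outdir`), `bbox`,
#'   `resolution`, `clamp`, `neighborhood`, `tol_deg`, `seed`.
#' @return The `wolb_surface`, invisibly.
#' @export
run_krige <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  model_file <- cfg$model_file %||% file.path(cfg$outdir, "variogram_model.json")
  model <- read_variogram_model(model_file)
  tbl <- read_population_table(cfg$input)
  tbl <- filter_duplicate_locations(tbl, seed = cfg$seed, tol_deg = cfg$tol_deg)
  grid <- make_grid(cfg$bbox, cfg$resolution)
  stage_log(
    "krige", "kriging %d grid points from %d sites (model b = %.0f km)",
    nrow(grid), nrow(tbl), model$b
  )
  z <- tbl$k / tbl$n
  surface <- predict_grid(model, tbl, z, grid,
    neighborhood = cfg$neighborhood, clamp = cfg$clamp
  )
  cv <- loocv(model, tbl, z)
  readr::write_csv(as_tibble(surface), file.path(cfg$outdir, "surface.csv"), progress = FALSE)
  write_geojson_points(as_tibble(surface), file.path(cfg$outdir, "surface.geojson"))
  readr::write_csv(as_tibble(cv), file.path(cfg$outdir, "loocv.csv"), progress = FALSE)
  jsonlite::write_json(
    c(as.list(glance(cv)), list(seed = cfg$seed)),
    file.path(cfg$outdir, "loocv_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_manifest(cfg, "krige", cfg$outdir)
  invisible(surface)
}

#' Run the origin-inference stage
#'
#' Reads a kriged surface and scores every grid cell for compatibility
#' with the invasive-range sample; writes `candidates.csv` and a JSON
#' run summary.
#'
#' @param config A run configuration list; uses `surface_file` (defaults
#'   to `surface.csv` in `outdir`), `k_inv`, `n_inv`, `alpha`.
#' @return The assessment tibble, invisibly.
#' @export
run_origin <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  surface_file <- cfg$surface_file %||% file.path(cfg$outdir, "surface.csv")
  if (!file.exists(surface_file)) {
    abort(paste0("surface file not found: ", surface_file), class = "wolb_io_error")
  }
  surface <- readr::read_csv(surface_file, show_col_types = FALSE, progress = FALSE)
  out <- invasion_compatibility(surface, cfg$k_inv, cfg$n_inv, alpha = cfg$alpha)
  stage_log(
    "origin", "%d of %d grid cells are candidate origins (alpha = %g)",
    sum(out$candidate), nrow(out), cfg$alpha
  )
  readr::write_csv(out, file.path(cfg$outdir, "candidates.csv"), progress = FALSE)
  jsonlite::write_json(
    list(
      k_inv = cfg$k_inv, n_inv = cfg$n_inv, alpha = cfg$alpha,
      n_cells = nrow(out), n_candidates = sum(out$candidate),
      seed = cfg$seed, config_hash = rlang::hash(cfg[order(names(cfg))])
    ),
    file.path(cfg$outdir, "origin_summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_manifest(cfg, "origin", cfg$outdir)
  invisible(out)
}

#' Run the simulation stage
#'
#' Generates a synthetic population table with the configured spatial
#' structure and writes it (plus the generating truth) to `outdir`.
#'
#' @param config A run configuration list; recognised simulator fields
#'   are passed to [sim_config()] (`n_sites`, `bbox`, `C0`, `C1`, `b`,
#'   `mean_p`, `link`, `site_mode`, `seed`).
#' @return The generated table, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- utils::modifyList(default_run_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sc <- sim_config(
    n_sites = cfg$n_sites %||% 238L,
    bbox = cfg$bbox,
    C0 = cfg$C0 %||% 0.05, C1 = cfg$C1 %||% 0.20, b = cfg$b %||% 600,
    mean_p = cfg$mean_p %||% 0.5,
    link = cfg$link %||% "truncate",
    site_mode = cfg$site_mode %||% "uniform",
    seed = cfg$seed
  )
  sim <- generate_dataset(sc)
  write_population_table(sim$table, file.path(cfg$outdir, "synthetic_populations.csv"))
  jsonlite::write_json(
    list(
      latent_p = sim$truth$latent_p,
      model = attr(sim$truth, "model"),
      mean_p = attr(sim$truth, "mean_p"),
      seed = sc$seed,
      config_hash = rlang::hash(cfg[order(names(cfg))])
    ),
    file.path(cfg$outdir, "synthetic_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_manifest(cfg, "simulate", cfg$outdir)
  stage_log("simulate", "wrote %d synthetic populations", nrow(sim$table))
  invisible(sim$table)
}
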