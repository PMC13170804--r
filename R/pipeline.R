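# Pipeline orchestration: validated configuration, staged execution with
# per-stage logging and fail-fast errors, deterministic outputs, and a run
# manifest carrying seeds and content hashes.

#' Classify a river as human-impacted
#'
#' A site is human-impacted when its landscape class is urban or cropland,
#' or its population density is strictly greater than 20 people km-2.
#'
#' @param landscape_class character; one of urban, cropland, dense,
#'   pristine, forest, grassland, wetland.
#' @param population_density people km-2.
#' @return logical vector.
#' @export
classify_human_impacted <- function(landscape_class, population_density) {
  bad <- !landscape_class %in% LANDSCAPE_CLASSES
  if (any(bad))
    stop("unknown landscape class: ", unique(landscape_class[bad])[1])
  landscape_class %in% c("urban", "cropland") | population_density > 20
}

#' Assemble the per-cell-month predictor table
#'
#' Derives nutrient concentrations as load/runoff, takes the monthly water
#' temperature, and carries the cell's terrestrial predictors and labels,
#' producing one row per (cell, month) with the 21 modeling predictors.
#'
#' @param cells grid-cell table.
#' @param basin_col cell column used as the basin label for the pristine
#'   scenario (default `"continent"`, the desk-scale basin stand-in).
#' @return `data.frame` with cell_id, month, predictors, region labels and
#'   `basin_id`.
#' @export
build_cell_predictors <- function(cells, basin_col = "continent") {
  ter <- intersect(terrestrial_predictors(), names(cells))
  rows <- lapply(1:12, function(m) {
    runoff <- cells[[sprintf("runoff_m%02d", m)]]
    d <- data.frame(cell_id = cells$cell_id, month = m,
                    stringsAsFactors = FALSE)
    for (s in NUTRIENT_FIELDS)
      d[[s]] <- cell_nutrient_concentration(
        cells[[sprintf("load_%s_m%02d", s, m)]], runoff, cells$cell_id)
    d$water_temp <- cells[[sprintf("water_temp_m%02d", m)]]
    for (p in ter) d[[p]] <- cells[[p]]
    for (lab in c("climate_zone", "continent", "income_group", "country_id",
                  "landscape_class"))
      d[[lab]] <- cells[[lab]]
    d$basin_id <- cells[[basin_col]]
    d
  })
  do.call(rbind, rows)
}

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. In
#' synthetic mode the three input tables are generated from `params`;
#' otherwise `observations_path`, `reaches_path` and `cells_path` must
#' exist at validation time.
#'
#' @param out_dir output directory (created if absent).
#' @param synthetic generate inputs from `params` instead of reading files.
#' @param params a [truth_params()] object (synthetic mode).
#' @param n_sites,n_cells,reaches_per_cell synthetic world size.
#' @param observations_path,reaches_path,cells_path input CSVs (file mode).
#' @param seed master seed for model fitting and splits.
#' @param responses responses to model (`"ln_flux"` is required for
#'   upscaling; `"ln_conc"` optional).
#' @param months calendar months to model (default all 12).
#' @param min_n minimum windowed observations per monthly model.
#' @param train_frac training fraction.
#' @param tune tune hyperparameters per month (slower).
#' @param grid_scale `"test"` or `"full"` hyperparameter grids.
#' @param cor_threshold correlation filter threshold for predictor
#'   selection reporting.
#' @param subgroup_min_n minimum n for a reported subgroup coefficient.
#' @param loess_span span for the density-gradient smoother.
#' @param impacted_only train on, and upscale, human-impacted rivers only.
#' @param scenarios character subset of `c("half", "sustainable",
#'   "pristine")`.
#' @param country_reduction_ratio named country-to-fraction map for the
#'   sustainable scenario (single unnamed number = same ratio everywhere).
#' @param smearing apply the smearing back-transform correction.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = TRUE,
                            params = truth_params(),
                            n_sites = 300, n_cells = 12,
                            reaches_per_cell = 4,
                            observations_path = NULL, reaches_path = NULL,
                            cells_path = NULL,
                            seed = 1L,
                            responses = c("ln_flux"),
                            months = 1:12, min_n = 10, train_frac = 0.7,
                            tune = FALSE, grid_scale = "test",
                            cor_threshold = 0.1, subgroup_min_n = 10,
                            loess_span = 0.75,
                            impacted_only = TRUE,
                            scenarios = c("half", "pristine"),
                            country_reduction_ratio = 0.3,
                            smearing = FALSE) {
  cfg <- list(out_dir = out_dir, synthetic = synthetic, params = params,
              n_sites = n_sites, n_cells = n_cells,
              reaches_per_cell = reaches_per_cell,
              observations_path = observations_path,
              reaches_path = reaches_path, cells_path = cells_path,
              seed = as.integer(seed), responses = responses,
              months = months, min_n = min_n, train_frac = train_frac,
              tune = tune, grid_scale = grid_scale,
              cor_threshold = cor_threshold,
              subgroup_min_n = subgroup_min_n, loess_span = loess_span,
              impacted_only = impacted_only, scenarios = scenarios,
              country_reduction_ratio = country_reduction_ratio,
              smearing = smearing)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` object.
#' @export
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.numeric(config$seed) || is.na(config$seed))
    stop("seed must be an integer")
  if (!config$synthetic) {
    for (f in c("observations_path", "reaches_path", "cells_path")) {
      p <- config[[f]]
      if (is.null(p) || !file.exists(p))
        stop("input path missing or nonexistent: ", f,
             if (!is.null(p)) paste0(" (", p, ")"))
    }
  } else {
    validate_truth_params(config$params)
  }
  if (!"ln_flux" %in% config$responses)
    stop("responses must include ln_flux (needed for upscaling)")
  bad <- setdiff(config$scenarios, c("half", "sustainable", "pristine"))
  if (length(bad)) stop("unknown scenario kind: ", bad[1])
  config
}

# content hash of a config: canonical JSON -> md5 (no file timestamps);
# out_dir is excluded so the hash identifies the scientific configuration,
# not where its outputs land
config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  x$params <- unclass(x$params)
  j <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15, force = TRUE,
                        null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(j, tf)
  unname(tools::md5sum(tf))
}

write_output <- function(x, dir, name) {
  path <- file.path(dir, name)
  write.csv(x, path, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Stages, in dependency order: input generation/loading, driver
#' screening, monthly ensemble training, per-cell-month prediction,
#' upscaling (areas, ebullition, aggregation), scenarios with mitigation
#' accounting, and the run manifest. Outputs are deterministic under a
#' fixed configuration: rerunning writes byte-identical files.
#'
#' Files written to `config$out_dir`: `coefficients.csv`,
#' `predictions.csv`, `emissions.csv`, `regional_summary.csv`,
#' `mitigation.csv`, `manifest.json` (plus `inputs/` in synthetic mode).
#'
#' @param config a validated [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the in-memory stage results and output
#'   paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_pipeline_config(config)
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- run_stage("inputs", {
    if (config$synthetic) {
      obs <- simulate_observations(config$n_sites, config$params)
      net <- generate_network(config$n_cells, config$reaches_per_cell,
                              config$params)
      idir <- file.path(config$out_dir, "inputs")
      dir.create(idir, showWarnings = FALSE)
      write_observations(obs, file.path(idir, "observations.csv"))
      write_reaches(net$reaches, file.path(idir, "reaches.csv"))
      write_cells(net$cells, file.path(idir, "cells.csv"))
      write_truth_params(config$params, file.path(idir, "truth_params.yml"))
      list(observations = obs, reaches = net$reaches, cells = net$cells)
    } else {
      list(observations = read_observations(config$observations_path),
           reaches = read_reaches(config$reaches_path),
           cells = read_cells(config$cells_path))
    }
  })
  say("inputs: ", nrow(inputs$observations), " observations, ",
      nrow(inputs$reaches), " reaches, ", nrow(inputs$cells), " cells")

  coefs <- run_stage("screening", {
    rbind(
      subgroup_coefficients(inputs$observations, "global",
                            min_n = config$subgroup_min_n),
      subgroup_coefficients(inputs$observations, "impacted_vs_pristine",
                            min_n = config$subgroup_min_n))
  })
  say("screening: ", nrow(coefs), " coefficient records")

  obs_model <- inputs$observations
  if (config$impacted_only)
    obs_model <- obs_model[classify_human_impacted(
      obs_model$landscape_class, obs_model$population_density), ,
      drop = FALSE]

  ensembles <- run_stage("train", {
    out <- list()
    for (resp in config$responses) {
      out[[resp]] <- lapply(config$months, function(m)
        fit_monthly_ensemble(obs_model, m, resp,
                             grids = default_grids(config$grid_scale),
                             tune = config$tune,
                             train_frac = config$train_frac,
                             min_n = config$min_n,
                             seed = config$seed + m))
      names(out[[resp]]) <- as.character(config$months)
    }
    out
  })
  say("train: ", length(config$months), " monthly models x ",
      length(config$responses), " responses")

  cells_scope <- inputs$cells
  if (config$impacted_only)
    cells_scope <- cells_scope[classify_human_impacted(
      cells_scope$landscape_class, cells_scope$population_density), ,
      drop = FALSE]
  if (!nrow(cells_scope)) stop("no cells in scope after impacted filter")

  cellpred <- run_stage("predict", build_cell_predictors(cells_scope))

  predict_flux <- function(ptab) {
    out <- list()
    for (m in config$months) {
      pm <- ptab[ptab$month == m, , drop = FALSE]
      pr <- ensemble_predict(ensembles$ln_flux[[as.character(m)]], pm,
                             type = "natural", smearing = config$smearing,
                             members = TRUE)
      d <- data.frame(cell_id = pm$cell_id, month = m, flux = pr$mean,
                      flux_rf = pr$members[, "rf"],
                      flux_gbt = pr$members[, "gbt"],
                      flux_svr = pr$members[, "svr"],
                      stringsAsFactors = FALSE)
      if ("ln_conc" %in% names(ensembles))
        d$conc <- ensemble_predict(ensembles$ln_conc[[as.character(m)]], pm,
                                   type = "natural",
                                   smearing = config$smearing)
      out[[length(out) + 1L]] <- d
    }
    do.call(rbind, out)
  }
  predictions <- run_stage("predict", predict_flux(cellpred))
  say("predict: ", nrow(predictions), " cell-month predictions")

  upscale <- run_stage("upscale", {
    areas <- cell_monthly_areas(inputs$reaches, cells_scope)
    em <- emission_table(predictions, areas, cells_scope,
                         config$params$ebullition_breaks,
                         config$params$ebullition_ratios)
    list(areas = areas, emissions = em,
         annual = annual_aggregate(em, cells_scope))
  })
  say("upscale: total ", signif(upscale$annual$total_Tg, 4), " Tg CH4 yr-1")

  scen_out <- run_stage("scenario", {
    mits <- list()
    for (kind in config$scenarios) {
      spec <- switch(kind,
        half = scenario_spec("half"),
        sustainable = {
          ratio <- config$country_reduction_ratio
          if (is.null(names(ratio))) {
            ids <- unique(cellpred$country_id)
            ratio <- setNames(rep(ratio[1], length(ids)), ids)
          }
          scenario_spec("sustainable", country_reduction_ratio = ratio)
        },
        pristine = pristine_spec_from_observations(inputs$observations))
      ptab <- apply_scenario(cellpred, spec)
      pred_s <- predict_flux(ptab)
      em_s <- emission_table(pred_s, upscale$areas, cells_scope,
                             config$params$ebullition_breaks,
                             config$params$ebullition_ratios)
      mit <- mitigation(upscale$annual, annual_aggregate(em_s, cells_scope))
      reg <- mit$regional
      reg <- rbind(reg, data.frame(
        region_type = "global", region = "global",
        current_Tg = upscale$annual$total_Tg,
        scenario_Tg = upscale$annual$total_Tg - mit$total[["reduction_Tg"]],
        reduction_Tg = mit$total[["reduction_Tg"]],
        reduction_pct = mit$total[["reduction_pct"]],
        stringsAsFactors = FALSE))
      reg <- cbind(scenario = kind, reg, stringsAsFactors = FALSE)
      mits[[kind]] <- reg
    }
    do.call(rbind, c(mits, list(make.row.names = FALSE)))
  })
  say("scenario: ", length(config$scenarios), " scenarios evaluated")

  paths <- c(
    coefficients = write_output(coefs, config$out_dir, "coefficients.csv"),
    predictions = write_output(predictions, config$out_dir,
                               "predictions.csv"),
    emissions = write_output(upscale$emissions, config$out_dir,
                             "emissions.csv"),
    regional_summary = write_output(upscale$annual$regional, config$out_dir,
                                    "regional_summary.csv"),
    mitigation = write_output(scen_out, config$out_dir, "mitigation.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("riverch4")),
    config_hash = config_hash(config),
    seed = config$seed,
    rows = list(observations = nrow(inputs$observations),
                reaches = nrow(inputs$reaches),
                cells = nrow(inputs$cells),
                coefficients = nrow(coefs),
                predictions = nrow(predictions),
                emissions = nrow(upscale$emissions),
                mitigation = nrow(scen_out)),
    total_Tg = upscale$annual$total_Tg,
    output_md5 = as.list(tools::md5sum(unname(paths))))
  names(manifest$output_md5) <- basename(unname(paths))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("manifest: ", manifest$config_hash)

  invisible(list(inputs = inputs, coefficients = coefs,
                 ensembles = ensembles, predictions = predictions,
                 upscale = upscale, mitigation = scen_out,
                 manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}
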