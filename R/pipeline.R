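#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' temperature thresholds 35 / -4 degC, 250 km station radius, up to 10
#' stations, 30 weather years, 10 snow years, 3 cfs perennial-flow cutoff,
#' 13 km^2 and 2.5% polygon aggregation criteria, 9 km^2 heterogeneity
#' window, background multiplier 2, collinearity cutoffs 0.7 / 10, 4
#' cross-validation folds and 100 iterations. Unknown keys are rejected; the
#' resolved configuration is written alongside every run's outputs.
#'
#' @param ... overrides of the defaults listed above (see the source for key
#'   names). `landscape` takes a [landscape_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    hot_c = 35, cold_c = -4, radius_km = 250, max_stations = 10,
    lapse_c_per_km = 6.49, min_flow_cfs = 3, min_area_km2 = 13,
    min_prop = 0.025, home_range_km2 = 9, background_multiplier = 2,
    r_cut = 0.7, vif_cut = 10, k_folds = 4, cv_iterations = 100,
    n_bins = 10, binning = c("quantile", "equal_interval"),
    form = "exponential", marginality = TRUE,
    standardization_sample = "estimation",  # or "all"
    dispersal_km = NULL,  # NULL = estimate from first-occupancy distances
    include_woody_wetlands = TRUE,
    seed = 1L, landscape = landscape_config())
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$standardization_sample %in% c("estimation", "all"))
    stop("`standardization_sample` must be \"estimation\" or \"all\"",
         call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

# Write `obj` with `writer` unless resuming and the file already exists.
emit <- function(path, writer, resume) {
  if (resume && file.exists(path)) return(invisible(path))
  writer(path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, covariates, ingest, fit, validate, and predict in
#' order over a synthetic landscape, writing every artifact (rasters,
#' stations, watersheds, occurrence polygons, covariate table, occurrence
#' series, samples, subset ledger, averaged-model table, validation report,
#' predictions, resolved config, run log) under `out_dir`. All randomness
#' derives from `config$seed`, so two runs with the same configuration
#' produce byte-identical CSV outputs. With `resume = TRUE`, stages are
#' recomputed deterministically but only missing artifact files are written.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param resume only write artifacts that are missing.
#' @param validate run the cross-validation stage (the slowest stage)?
#' @return invisibly, a list with the in-memory stage products and the
#'   output directory.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         resume = FALSE, validate = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log <- c(sprintf("swinescape %s | R %s.%s", "0.1.0", R.version$major,
                   R.version$minor),
           sprintf("seed: %d", config$seed))
  tick <- function(stage) {
    log <<- c(log, sprintf("%s: done at +%.1fs", stage,
                           as.numeric(Sys.time() - t0, units = "secs")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  lc <- config$landscape
  lc$seed <- config$seed
  lc <- do.call(landscape_config, lc[setdiff(names(lc), character(0))])

  # -- simulate -------------------------------------------------------------
  land <- stage("simulate", generate_landscape(lc))
  ws <- watershed_table(land)
  raw <- stage("covariates", compute_covariates(
    land, ws, radius_km = config$radius_km,
    max_stations = config$max_stations, hot_c = config$hot_c,
    cold_c = config$cold_c, lapse_c_per_km = config$lapse_c_per_km,
    min_flow_cfs = config$min_flow_cfs,
    home_range_km2 = config$home_range_km2,
    forest = forest_classes(config$include_woody_wetlands)))
  cov_all <- standardize_covariates(raw)  # all-watersheds scale for truth
  sim <- stage("simulate", simulate_occurrence(land, lc, cov_all))
  emit(file.path(out_dir, "elevation.csv"),
       function(p) write_grid_csv(land$elevation, p, land$cell_km), resume)
  emit(file.path(out_dir, "flow.csv"),
       function(p) write_grid_csv(land$flow, p, land$cell_km), resume)
  emit(file.path(out_dir, "landcover.csv"),
       function(p) write_grid_csv(land$landcover, p, land$cell_km), resume)
  emit(file.path(out_dir, "partition.csv"),
       function(p) write_grid_csv(land$partition, p, land$cell_km), resume)
  emit(file.path(out_dir, "stations.csv"),
       function(p) write_stations_csv(land, p), resume)
  emit(file.path(out_dir, "watersheds.geojson"),
       function(p) write_watersheds_geojson(ws, p), resume)
  emit(file.path(out_dir, "occurrence_polygons.geojson"),
       function(p) write_polygons_geojson(sim$polygons, nrow(land$partition),
                                          land$cell_km, p), resume)
  tick("simulate")

  # -- ingest ---------------------------------------------------------------
  adj <- watershed_adjacency(land$partition)
  series <- stage("ingest", assign_presence(
    sim$polygons, land$partition, ws, config$min_area_km2, config$min_prop,
    land$cell_km))
  thr <- config$dispersal_km
  if (is.null(thr))
    thr <- stage("ingest", estimate_dispersal_threshold(series, ws))
  series <- stage("ingest", flag_introductions(series, ws, thr, adj))
  samples <- stage("ingest", build_samples(
    series, ws, config$background_multiplier, config$seed))
  emit(file.path(out_dir, "occurrence_series.csv"),
       function(p) utils::write.csv(series, p, row.names = FALSE), resume)
  emit(file.path(out_dir, "samples.csv"), function(p) utils::write.csv(
    data.frame(role = rep(c("presence", "background"),
                          c(length(samples$presence),
                            length(samples$background))),
               watershed_id = c(samples$presence, samples$background)),
    p, row.names = FALSE), resume)
  tick("ingest")

  # -- covariates (fitting scale) -------------------------------------------
  cov_fit <- if (config$standardization_sample == "all") cov_all else
    stage("covariates", standardize_covariates(
      raw, c(samples$presence, samples$background)))
  emit(file.path(out_dir, "covariates.csv"),
       function(p) write_covariates_csv(cov_fit, p), resume)
  tick("covariates")

  # -- fit ------------------------------------------------------------------
  dat <- stage("fit", estimation_data(cov_fit, samples))
  spec <- global_model_spec(marginality = config$marginality,
                            r_cut = config$r_cut, vif_cut = config$vif_cut)
  screen <- stage("fit", collinearity_screen(
    build_design(dat, covariate_terms()), config$r_cut, config$vif_cut))
  if (length(screen$flagged))
    log <- c(log, paste("collinearity screen flagged:",
                        paste(screen$flagged, collapse = ", ")))
  ledger <- stage("fit", fit_all_subsets(dat, spec))
  avg <- stage("fit", model_average(ledger,
                                    attr(cov_fit, "standardization")))
  emit(file.path(out_dir, "subset_ledger.csv"), function(p)
    utils::write.csv(ledger$table, p, row.names = FALSE), resume)
  emit(file.path(out_dir, "averaged_model.csv"), function(p)
    utils::write.csv(avg$table, p, row.names = FALSE), resume)
  tick("fit")

  # -- validate -------------------------------------------------------------
  report <- NULL
  if (validate) {
    report <- stage("validate", cross_validate(
      dat, spec, k = config$k_folds, iterations = config$cv_iterations,
      n_bins = config$n_bins, seed = config$seed,
      methods = config$binning, form = "logistic"))
    emit(file.path(out_dir, "validation.csv"), function(p)
      utils::write.csv(report$results, p, row.names = FALSE), resume)
    emit(file.path(out_dir, "validation_summary.csv"), function(p)
      utils::write.csv(report$summary, p, row.names = FALSE), resume)
    tick("validate")
  }

  # -- predict --------------------------------------------------------------
  pred_exp <- stage("predict",
                    predict_relative_occurrence(avg, cov_fit, "exponential"))
  pred_log <- stage("predict",
                    predict_relative_occurrence(avg, cov_fit, "logistic"))
  preds <- data.frame(watershed_id = pred_exp$watershed_id,
                      eta = pred_exp$eta,
                      score_exponential = pred_exp$score,
                      score_logistic = pred_log$score)
  emit(file.path(out_dir, "predictions.csv"), function(p)
    utils::write.csv(preds, p, row.names = FALSE), resume)
  tick("predict")

  resolved <- unclass(config)
  resolved$landscape <- unclass(lc)
  resolved$dispersal_km <- thr
  emit(file.path(out_dir, "config_resolved.txt"),
       function(p) write_config_txt(resolved, p), resume)
  writeLines(log, file.path(out_dir, "run_log.txt"))

  invisible(list(out_dir = out_dir, landscape = land, watersheds = ws,
                 covariates = cov_fit, sim = sim, series = series,
                 samples = samples, screen = screen, ledger = ledger,
                 averaged = avg, validation = report, predictions = preds,
                 dispersal_km = thr))
}
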