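# Shared configuration and deterministic state builders for the numbered
# analysis scripts. Every script re-derives the upstream state it needs from
# the same seeded configuration (a few seconds of compute), so the scripts
# can be run independently and always agree.

library(swinescape)

# A 160,000-cell landscape with 400 watersheds: large enough for a
# well-populated presence sample (a few hundred units) while keeping the
# full all-subsets cross-validation to a few minutes on one CPU.
cfg <- pipeline_config(seed = 1L,
                       landscape = landscape_config(nrow = 400L, ncol = 400L,
                                                    n_watersheds = 400L,
                                                    n_stations = 25L))
out_dir <- "results/national_run"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

.state <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.state[[name]])) .state[[name]] <- force(expr)
  .state[[name]]
}

get_landscape_config <- function() memo("lc", {
  lc <- cfg$landscape
  lc$seed <- cfg$seed
  lc
})

get_landscape <- function() memo("land", generate_landscape(get_landscape_config()))

get_watersheds <- function() memo("ws", watershed_table(get_landscape()))

get_raw_covariates <- function() memo("raw", compute_covariates(
  get_landscape(), get_watersheds(), radius_km = cfg$radius_km,
  max_stations = cfg$max_stations, hot_c = cfg$hot_c, cold_c = cfg$cold_c,
  lapse_c_per_km = cfg$lapse_c_per_km, min_flow_cfs = cfg$min_flow_cfs,
  home_range_km2 = cfg$home_range_km2,
  forest = forest_classes(cfg$include_woody_wetlands)))

# all-watersheds standardization: the scale on which the simulator's true
# coefficients are defined
get_cov_all <- function() memo("cov_all",
                               standardize_covariates(get_raw_covariates()))

get_sim <- function() memo("sim", simulate_occurrence(
  get_landscape(), get_landscape_config(), get_cov_all()))

get_series <- function() memo("series", {
  land <- get_landscape()
  ws <- get_watersheds()
  series <- assign_presence(get_sim()$polygons, land$partition, ws,
                            cfg$min_area_km2, cfg$min_prop, land$cell_km)
  thr <- cfg$dispersal_km
  if (is.null(thr)) thr <- estimate_dispersal_threshold(series, ws)
  .state$dispersal_km <- thr
  flag_introductions(series, ws, thr, watershed_adjacency(land$partition))
})

get_samples <- function() memo("samples", build_samples(
  get_series(), get_watersheds(), cfg$background_multiplier, cfg$seed))

# covariates on the fitting scale (standardized over the estimation sample)
get_cov_fit <- function() memo("cov_fit", {
  if (cfg$standardization_sample == "all") get_cov_all()
  else standardize_covariates(get_raw_covariates(),
                              c(get_samples()$presence,
                                get_samples()$background))
})

get_estimation_data <- function() memo("dat",
                                       estimation_data(get_cov_fit(),
                                                       get_samples()))

get_model_spec <- function() memo("spec", global_model_spec(
  marginality = cfg$marginality, r_cut = cfg$r_cut, vif_cut = cfg$vif_cut))

get_ledger <- function() memo("ledger",
                              fit_all_subsets(get_estimation_data(),
                                              get_model_spec()))

get_averaged <- function() memo("avg", model_average(
  get_ledger(), attr(get_cov_fit(), "standardization")))
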