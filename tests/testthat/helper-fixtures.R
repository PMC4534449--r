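# Shared fixtures, built once per test run. The "small" landscape trades the
# default study conditions for speed: coarser cells and fewer watersheds,
# stations and years, which exercises every code path at a fraction of the
# cost.

small_config <- function(seed = 42, ...) {
  landscape_config(nrow = 60, ncol = 60, cell_km = 2, n_watersheds = 60,
                   n_stations = 8, n_years = 15, n_weather_years = 8,
                   n_snow_years = 4, seed = seed, ...)
}

.fixtures <- new.env(parent = emptyenv())

small_landscape <- function() {
  if (is.null(.fixtures$land)) .fixtures$land <-
      generate_landscape(small_config())
  .fixtures$land
}

small_watersheds <- function() {
  if (is.null(.fixtures$ws)) .fixtures$ws <-
      watershed_table(small_landscape())
  .fixtures$ws
}

small_covariates <- function() {
  if (is.null(.fixtures$cov)) .fixtures$cov <-
      compute_covariates(small_landscape())
  .fixtures$cov
}

small_covariates_std <- function() {
  if (is.null(.fixtures$cz)) .fixtures$cz <-
      standardize_covariates(small_covariates())
  .fixtures$cz
}

# Watershed table for a hand-built partition (flat terrain).
toy_watershed_table <- function(partition, cell_km) {
  nr <- nrow(partition)
  cell <- seq_along(partition)
  i <- (cell - 1L) %% nr + 1L
  j <- (cell - 1L) %/% nr + 1L
  x <- (j - 0.5) * cell_km
  y <- (i - 0.5) * cell_km
  ids <- sort(unique(as.vector(partition)))
  n_cells <- as.vector(table(factor(partition, levels = ids)))
  data.frame(watershed_id = ids, n_cells = n_cells,
             area_km2 = n_cells * cell_km^2,
             centroid_x_km = as.numeric(tapply(x, partition, mean)),
             centroid_y_km = as.numeric(tapply(y, partition, mean)),
             centroid_elev_m = 0, row.names = NULL)
}

# One toy weather station with given daily matrices (365 x years).
toy_station <- function(id, x_km, y_km, elev_m, tmax, tmin = tmax - 10) {
  list(stations = data.frame(station_id = id, x_km = x_km, y_km = y_km,
                             elev_m = elev_m, stringsAsFactors = FALSE),
       series = stats::setNames(
         list(list(station_id = id, years = seq_len(ncol(tmax)),
                   tmax = tmax, tmin = tmin)), id))
}

# A standardized covariate table filled with explicit z values (recycled),
# for predict-level tests that need a known scale.
toy_std_table <- function(n = 5, z = 0, center = 14, scale = 22) {
  terms <- covariate_terms()
  tab <- data.frame(watershed_id = seq_len(n))
  for (tm in terms) tab[[tm]] <- rep_len(z, n)
  class(tab) <- c("covariate_table", "data.frame")
  attr(tab, "standardization") <- list(
    center = stats::setNames(rep(center, length(terms)), terms),
    scale = stats::setNames(rep(scale, length(terms)), terms),
    sample_ids = seq_len(n))
  tab
}

# Minimal averaged model built from explicit per-term estimates.
toy_averaged_model <- function(estimates, se = 0 * estimates) {
  tab <- data.frame(term = names(estimates), estimate = unname(estimates),
                    se = unname(se), stringsAsFactors = FALSE)
  tab$ci_low <- tab$estimate - 1.959964 * tab$se
  tab$ci_high <- tab$estimate + 1.959964 * tab$se
  tab$importance <- 1
  structure(list(table = tab, z = 1.959964, n = NA_integer_,
                 standardization = NULL),
            class = "averaged_model")
}
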