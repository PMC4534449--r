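#' Covariate term names
#'
#' The seven watershed-level habitat covariates used by the occurrence model,
#' optionally with the quadratic hot-days term appended after its linear
#' component.
#'
#' @param quadratic include `days_above_35_sq`?
#' @return character vector of term names.
#' @export
covariate_terms <- function(quadratic = FALSE) {
  base <- c("days_above_35", "days_below_minus4", "snow_depth", "dist_water",
            "forest_pct", "forage_pct", "heterogeneity")
  if (quadratic) append(base, "days_above_35_sq", after = 1L) else base
}

# Land-cover classes the synthetic generator can emit.
landcover_classes <- function() {
  c("deciduous", "evergreen", "mixed", "woody_wetland", "crop", "mast",
    "grass", "open_water")
}

#' Forest and forage land-cover class presets
#'
#' Two forest presets are shipped because national land-cover practice is
#' ambiguous about woody wetlands: one preset is the strict
#' deciduous/evergreen/mixed forest set, the other additionally counts woody
#' wetlands as forest cover. Forage is crop plus hard-mast-producing cover.
#'
#' @param include_woody_wetlands count woody wetlands as forest?
#' @return character vector of class labels.
#' @export
forest_classes <- function(include_woody_wetlands = TRUE) {
  cl <- c("deciduous", "evergreen", "mixed")
  if (include_woody_wetlands) c(cl, "woody_wetland") else cl
}

#' @rdname forest_classes
#' @export
forage_classes <- function() c("crop", "mast")

#' Adiabatic lapse-rate temperature correction
#'
#' Transfers a station temperature to a watershed centroid using the mean
#' adiabatic lapse rate of 6.49 degC per 1000 m: a centroid above the station
#' is colder, below it warmer.
#'
#' @param temp_c observed temperature at the station (degC).
#' @param station_elev_m station elevation (m).
#' @param centroid_elev_m watershed centroid elevation (m).
#' @param lapse_c_per_km lapse rate (degC per 1000 m).
#' @return adjusted temperature (degC).
#' @export
adjust_temperature <- function(temp_c, station_elev_m, centroid_elev_m,
                               lapse_c_per_km = 6.49) {
  temp_c - lapse_c_per_km * (centroid_elev_m - station_elev_m) / 1000
}

#' Temperature day-count covariates
#'
#' For each watershed, selects the weather stations within `radius_km` of the
#' centroid (up to `max_stations` closest; distance ties broken by station
#' id), lapse-adjusts every daily record to the centroid elevation, counts
#' days per year with adjusted maximum above `hot_c` and adjusted minimum
#' below `cold_c`, and averages those yearly counts over available years and
#' then across stations. Years with partial records contribute counts over
#' the days they have; stations and daily records are de-duplicated so that
#' repeating a station's record cannot change the result.
#'
#' @param stations data frame with `station_id`, `x_km`, `y_km`, `elev_m`.
#' @param series named list (by station id) with elements `tmax`, `tmin`
#'   (365 x years matrices, NA = missing).
#' @param watersheds watershed table ([watershed_table()]).
#' @param radius_km search radius around each centroid.
#' @param max_stations maximum number of stations per watershed.
#' @param hot_c,cold_c thresholds (degC) for the two day counts.
#' @param lapse_c_per_km lapse rate passed to [adjust_temperature()].
#' @return data frame `watershed_id`, `days_above_35`, `days_below_minus4`.
#' @export
temperature_day_covariates <- function(stations, series, watersheds,
                                       radius_km = 250, max_stations = 10,
                                       hot_c = 35, cold_c = -4,
                                       lapse_c_per_km = 6.49) {
  keep <- !duplicated(stations$station_id)
  stations <- stations[keep, , drop = FALSE]
  out <- data.frame(watershed_id = watersheds$watershed_id,
                    days_above_35 = NA_real_, days_below_minus4 = NA_real_)
  for (w in seq_len(nrow(watersheds))) {
    d <- sqrt((stations$x_km - watersheds$centroid_x_km[w])^2 +
                (stations$y_km - watersheds$centroid_y_km[w])^2)
    ord <- order(d, stations$station_id)
    ord <- ord[d[ord] <= radius_km]
    if (!length(ord))
      stop(sprintf("no weather station within %g km of watershed %s",
                   radius_km, watersheds$watershed_id[w]), call. = FALSE)
    ord <- ord[seq_len(min(max_stations, length(ord)))]
    hot <- cold <- numeric(length(ord))
    for (s in seq_along(ord)) {
      st <- stations[ord[s], ]
      rec <- series[[st$station_id]]
      tmax <- adjust_temperature(rec$tmax, st$elev_m,
                                 watersheds$centroid_elev_m[w],
                                 lapse_c_per_km)
      tmin <- adjust_temperature(rec$tmin, st$elev_m,
                                 watersheds$centroid_elev_m[w],
                                 lapse_c_per_km)
      avail_hot <- colSums(!is.na(tmax)) > 0
      avail_cold <- colSums(!is.na(tmin)) > 0
      hot[s] <- mean(colSums(tmax > hot_c, na.rm = TRUE)[avail_hot])
      cold[s] <- mean(colSums(tmin < cold_c, na.rm = TRUE)[avail_cold])
    }
    out$days_above_35[w] <- mean(hot)
    out$days_below_minus4[w] <- mean(cold)
  }
  out
}

#' Mean April-1 snow depth per watershed
#'
#' Averages the per-year April-1 snow-depth grids cell-wise over years, then
#' averages the multi-year mean within each watershed.
#'
#' @param snow list of snow-depth matrices (m), one per year.
#' @param partition integer watershed-id matrix.
#' @return data frame `watershed_id`, `snow_depth` (m).
#' @export
mean_snow_depth <- function(snow, partition) {
  if (!length(snow)) stop("need at least one year of snow grids",
                          call. = FALSE)
  dims <- vapply(snow, function(m) paste(dim(m), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1L ||
      !identical(dim(snow[[1]]), dim(partition)))
    stop("snow grids and partition must share the same shape", call. = FALSE)
  mgrid <- Reduce(`+`, snow) / length(snow)
  agg <- tapply(as.vector(mgrid), as.vector(partition), mean)
  data.frame(watershed_id = as.integer(names(agg)),
             snow_depth = as.numeric(agg), row.names = NULL)
}

#' Mean distance to perennial water per watershed
#'
#' Streams with average annual flow below `min_flow_cfs` are removed as
#' ephemeral; the Euclidean distance (cell centre to cell centre) from every
#' cell to the nearest retained water cell is computed with an exact distance
#' transform and averaged within each watershed. Retained water cells have
#' distance 0.
#'
#' @param flow matrix of average annual flow (cubic feet per second;
#'   0 = no water).
#' @param partition integer watershed-id matrix.
#' @param cell_km cell size (km).
#' @param min_flow_cfs minimum flow for a water cell to be retained.
#' @return data frame `watershed_id`, `dist_water` (km).
#' @export
mean_distance_to_water <- function(flow, partition, cell_km,
                                   min_flow_cfs = 3) {
  if (!identical(dim(flow), dim(partition)))
    stop("flow raster and partition must share the same shape", call. = FALSE)
  retained <- flow >= min_flow_cfs
  if (!any(retained))
    stop(sprintf(
      "no retained water: no cell has flow >= %g cubic feet per second",
      min_flow_cfs), call. = FALSE)
  m <- matrix(1, nrow(flow), ncol(flow))
  m[retained] <- 0
  d <- matrix(as.numeric(EBImage::distmap(m, metric = "euclidean")),
              nrow(flow), ncol(flow)) * cell_km
  agg <- tapply(as.vector(d), as.vector(partition), mean)
  data.frame(watershed_id = as.integer(names(agg)),
             dist_water = as.numeric(agg), row.names = NULL)
}

#' Percent cover of a land-cover class set per watershed
#'
#' @param landcover character matrix of land-cover classes.
#' @param partition integer watershed-id matrix.
#' @param classes class labels to count (must be known classes).
#' @return data frame `watershed_id`, `percent` (0-100).
#' @export
percent_cover <- function(landcover, partition, classes) {
  if (!length(classes)) stop("class set must be non-empty", call. = FALSE)
  unknown <- setdiff(classes, landcover_classes())
  if (length(unknown))
    stop("unknown land-cover class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!identical(dim(landcover), dim(partition)))
    stop("landcover raster and partition must share the same shape",
         call. = FALSE)
  agg <- tapply(as.vector(landcover %in% classes), as.vector(partition),
                mean)
  data.frame(watershed_id = as.integer(names(agg)),
             percent = 100 * as.numeric(agg), row.names = NULL)
}

# Offsets (di, dj) of the disk window of radius sqrt(home_range_km2/pi) km,
# in cell units; ties at the boundary are included.
disk_offsets <- function(home_range_km2, cell_km) {
  radius_km <- sqrt(home_range_km2 / pi)
  r_cells <- radius_km / cell_km
  rng <- -floor(r_cells):floor(r_cells)
  off <- expand.grid(di = rng, dj = rng)
  off[sqrt(off$di^2 + off$dj^2) <= r_cells + 1e-9, , drop = FALSE]
}

# TRUE wherever `mask` has any TRUE cell within the disk window (window
# truncated at grid edges).
dilate_disk <- function(mask, offsets) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (k in seq_len(nrow(offsets))) {
    di <- offsets$di[k]; dj <- offsets$dj[k]
    ti <- max(1, 1 - di):min(nr, nr - di)
    tj <- max(1, 1 - dj):min(nc, nc - dj)
    out[ti, tj] <- out[ti, tj] | mask[ti + di, tj + dj]
  }
  out
}

#' Habitat-heterogeneity index per watershed
#'
#' For each focal cell, counts how many of the three key resources (water,
#' cover, forage) have at least one positive cell within a circular window
#' whose area equals the average sounder home range (`home_range_km2`, radius
#' `sqrt(home_range_km2/pi)` km); the per-cell counts (0-3) are averaged
#' within each watershed to give a continuous 0-3 index.
#'
#' @param water,cover,forage logical resource masks on the common grid.
#' @param partition integer watershed-id matrix.
#' @param cell_km cell size (km).
#' @param home_range_km2 home-range window area (km^2).
#' @return data frame `watershed_id`, `heterogeneity` (0-3).
#' @export
heterogeneity_index <- function(water, cover, forage, partition, cell_km,
                                home_range_km2 = 9) {
  if (home_range_km2 <= 0)
    stop("`home_range_km2` must be positive", call. = FALSE)
  dims <- list(dim(water), dim(cover), dim(forage), dim(partition))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("resource masks and partition must share the same shape",
         call. = FALSE)
  off <- disk_offsets(home_range_km2, cell_km)
  counts <- dilate_disk(water, off) + dilate_disk(cover, off) +
    dilate_disk(forage, off)
  agg <- tapply(as.vector(counts), as.vector(partition), mean)
  data.frame(watershed_id = as.integer(names(agg)),
             heterogeneity = as.numeric(agg), row.names = NULL)
}

#' Derive the full covariate table for a landscape
#'
#' Runs every covariate operation over a synthetic landscape and assembles
#' the seven-covariate table (unstandardized), one row per watershed.
#'
#' @param landscape a [generate_landscape()] result.
#' @param watersheds optional precomputed [watershed_table()].
#' @param radius_km,max_stations,hot_c,cold_c,lapse_c_per_km temperature
#'   day-count settings (see [temperature_day_covariates()]).
#' @param min_flow_cfs perennial-stream flow cutoff (cubic feet per second).
#' @param home_range_km2 heterogeneity window area (km^2).
#' @param forest,forage land-cover class sets (see [forest_classes()]).
#' @return data frame of class `covariate_table`: `watershed_id` plus the
#'   seven covariates of [covariate_terms()].
#' @export
compute_covariates <- function(landscape, watersheds = NULL,
                               radius_km = 250, max_stations = 10,
                               hot_c = 35, cold_c = -4,
                               lapse_c_per_km = 6.49, min_flow_cfs = 3,
                               home_range_km2 = 9,
                               forest = forest_classes(),
                               forage = forage_classes()) {
  stopifnot(inherits(landscape, "landscape"))
  if (is.null(watersheds)) watersheds <- watershed_table(landscape)
  temps <- temperature_day_covariates(landscape$stations, landscape$series,
                                      watersheds, radius_km, max_stations,
                                      hot_c, cold_c, lapse_c_per_km)
  snowd <- mean_snow_depth(landscape$snow, landscape$partition)
  dwat <- mean_distance_to_water(landscape$flow, landscape$partition,
                                 landscape$cell_km, min_flow_cfs)
  fpct <- percent_cover(landscape$landcover, landscape$partition, forest)
  gpct <- percent_cover(landscape$landcover, landscape$partition, forage)
  het <- heterogeneity_index(landscape$flow >= min_flow_cfs,
                             matrix(landscape$landcover %in% forest,
                                    nrow(landscape$landcover)),
                             matrix(landscape$landcover %in% forage,
                                    nrow(landscape$landcover)),
                             landscape$partition, landscape$cell_km,
                             home_range_km2)
  tab <- data.frame(watershed_id = watersheds$watershed_id,
                    days_above_35 = temps$days_above_35,
                    days_below_minus4 = temps$days_below_minus4,
                    snow_depth = snowd$snow_depth,
                    dist_water = dwat$dist_water,
                    forest_pct = fpct$percent,
                    forage_pct = gpct$percent,
                    heterogeneity = het$heterogeneity)
  class(tab) <- c("covariate_table", "data.frame")
  tab
}

#' Standardize covariates on a stated sample
#'
#' Centres and scales every covariate column using the mean and sample SD
#' (n - 1) computed over the rows named by `sample_ids` (a multiset: repeated
#' ids contribute repeatedly, so the scale can match an estimation sample in
#' which a watershed appears as both presence and background). The
#' standardization metadata (per-column mean and SD plus the sample) is
#' attached for back-transformation.
#'
#' @param table a [compute_covariates()] table (unstandardized).
#' @param sample_ids watershed ids defining the standardization sample;
#'   default all rows.
#' @return the standardized `covariate_table`, with attribute
#'   `standardization` = list(center, scale, sample_ids).
#' @export
standardize_covariates <- function(table, sample_ids = table$watershed_id) {
  if (!is.null(attr(table, "standardization")))
    stop("table is already standardized", call. = FALSE)
  if (!length(sample_ids))
    stop("standardization sample must be non-empty", call. = FALSE)
  rows <- match(sample_ids, table$watershed_id)
  if (anyNA(rows))
    stop("sample ids not present in covariate table", call. = FALSE)
  cols <- covariate_terms()
  center <- scale <- stats::setNames(numeric(length(cols)), cols)
  for (cn in cols) {
    xs <- table[[cn]][rows]
    center[cn] <- mean(xs)
    scale[cn] <- stats::sd(xs)
    if (!is.finite(scale[cn]) || scale[cn] == 0)
      stop(sprintf("covariate `%s` is constant on the standardization sample",
                   cn), call. = FALSE)
    table[[cn]] <- (table[[cn]] - center[cn]) / scale[cn]
  }
  attr(table, "standardization") <- list(center = center, scale = scale,
                                         sample_ids = sample_ids)
  table
}

#' Back-transform standardized covariate values to the natural scale
#'
#' @param z standardized values.
#' @param table a standardized `covariate_table`.
#' @param term covariate name.
#' @return values on the natural scale of `term`.
#' @export
unstandardize <- function(z, table, term) {
  meta <- attr(table, "standardization")
  if (is.null(meta)) stop("table carries no standardization metadata",
                          call. = FALSE)
  meta$center[[term]] + meta$scale[[term]] * z
}
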