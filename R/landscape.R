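#' Configuration for a synthetic landscape
#'
#' Bundles and validates all tunables of the synthetic-landscape generator.
#' The generator emulates the structure of the national wild-pig analysis
#' inputs: spatially autocorrelated habitat rasters, a contiguous watershed
#' partition, weather stations with multi-decade daily temperature records,
#' and a multi-year occupancy process with rare long-distance human
#' introductions. Defaults give watersheds of a few hundred km^2 (the HUC10
#' scale of the real analysis) on a grid small enough to iterate on quickly.
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param cell_km cell edge length in km.
#' @param n_watersheds number of contiguous watershed units to grow.
#' @param n_stations number of weather stations.
#' @param n_years number of occupancy years to simulate.
#' @param n_weather_years length of the daily temperature record (years).
#' @param n_snow_years number of April-1 snow-depth grids.
#' @param corr_length_km spatial correlation length (km) of the Gaussian
#'   random fields behind every covariate raster. Scalar, or a named vector
#'   with any of `climate`, `elevation`, `water`, `landcover`, `snow`.
#' @param beta_true named true coefficient vector on the standardized
#'   covariate scale; names must be covariate terms
#'   (`days_above_35`, `days_above_35_sq`, `days_below_minus4`, `snow_depth`,
#'   `dist_water`, `forest_pct`, `forage_pct`, `heterogeneity`).
#' @param intercept_true true intercept of the annual colonization
#'   probability (logit scale).
#' @param intro_rate expected number of human-introduction events per year
#'   (Poisson).
#' @param dispersal_km natural-dispersal threshold: introductions are placed
#'   farther than this from any occupied watershed.
#' @param seed_quantile fraction of watersheds (highest true linear
#'   predictor) occupied in year 1.
#' @param polygon_fraction fraction of an occupied watershed's cells covered
#'   by its emitted occurrence polygon.
#' @param seed integer root random seed; all draws are derived from it via
#'   [derive_seed()].
#' @return a validated list of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 200L, ncol = 200L, cell_km = 1,
                             n_watersheds = 100L, n_stations = 15L,
                             n_years = 31L, n_weather_years = 30L,
                             n_snow_years = 10L, corr_length_km = 30,
                             beta_true = c(days_above_35 = 0.8,
                                           days_above_35_sq = -0.3,
                                           days_below_minus4 = -1.2,
                                           snow_depth = 0,
                                           dist_water = -0.6,
                                           forest_pct = 0,
                                           forage_pct = 0,
                                           heterogeneity = 0.5),
                             intercept_true = -4, intro_rate = 0.3,
                             dispersal_km = 60, seed_quantile = 0.01,
                             polygon_fraction = 0.6, seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    as.integer(x)
  }
  nrow <- chk_count(nrow, "nrow"); ncol <- chk_count(ncol, "ncol")
  n_watersheds <- chk_count(n_watersheds, "n_watersheds")
  n_stations <- chk_count(n_stations, "n_stations")
  n_years <- chk_count(n_years, "n_years")
  n_weather_years <- chk_count(n_weather_years, "n_weather_years")
  n_snow_years <- chk_count(n_snow_years, "n_snow_years")
  if (cell_km <= 0) stop("`cell_km` must be positive", call. = FALSE)
  if (any(corr_length_km <= 0))
    stop("`corr_length_km` must be positive", call. = FALSE)
  if (n_watersheds > nrow * ncol)
    stop("more watersheds than grid cells", call. = FALSE)
  if (n_stations > nrow * ncol)
    stop("more stations than grid cells", call. = FALSE)
  terms <- covariate_terms(quadratic = TRUE)
  if (is.null(names(beta_true)) || !all(names(beta_true) %in% terms))
    stop("`beta_true` must be named with covariate terms", call. = FALSE)
  beta <- stats::setNames(numeric(length(terms)), terms)
  beta[names(beta_true)] <- beta_true
  if (seed_quantile <= 0 || seed_quantile > 1)
    stop("`seed_quantile` must be in (0, 1]", call. = FALSE)
  if (polygon_fraction <= 0 || polygon_fraction > 1)
    stop("`polygon_fraction` must be in (0, 1]", call. = FALSE)
  if (intro_rate < 0) stop("`intro_rate` must be >= 0", call. = FALSE)
  if (dispersal_km <= 0) stop("`dispersal_km` must be positive", call. = FALSE)
  cfg <- list(nrow = nrow, ncol = ncol, cell_km = cell_km,
              n_watersheds = n_watersheds, n_stations = n_stations,
              n_years = n_years, n_weather_years = n_weather_years,
              n_snow_years = n_snow_years, corr_length_km = corr_length_km,
              beta_true = beta, intercept_true = intercept_true,
              intro_rate = intro_rate, dispersal_km = dispersal_km,
              seed_quantile = seed_quantile,
              polygon_fraction = polygon_fraction, seed = as.integer(seed))
  class(cfg) <- "landscape_config"
  cfg
}

# Correlation length for one field family, honouring scalar or named config.
corr_length_for <- function(config, field) {
  cl <- config$corr_length_km
  if (!is.null(names(cl)) && field %in% names(cl)) return(unname(cl[[field]]))
  unname(cl[[1L]])
}

#' Simulate a spatially autocorrelated Gaussian random field
#'
#' White noise smoothed with an isotropic Gaussian kernel by circular (FFT)
#' convolution, then restandardized to mean 0, SD 1. The kernel SD equals the
#' correlation length, so neighbouring-cell correlation decays to 0 as
#' `corr_length_km` approaches 0 (the field degenerates to white noise).
#'
#' @param nrow,ncol grid dimensions.
#' @param corr_length_km correlation length in km.
#' @param cell_km cell size in km.
#' @return a `nrow x ncol` numeric matrix. Uses the current RNG state.
#' @export
gaussian_field <- function(nrow, ncol, corr_length_km, cell_km = 1) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  s <- corr_length_km / cell_km  # kernel SD in cells
  if (s < 0.3) return(z)
  # torus distances so the circular convolution is stationary
  di <- pmin(0:(nrow - 1), nrow - 0:(nrow - 1))
  dj <- pmin(0:(ncol - 1), ncol - 0:(ncol - 1))
  k <- exp(-outer(di^2, dj^2, "+") / (2 * s^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
    (nrow * ncol)
  (f - mean(f)) / stats::sd(f)
}

# Grow `n` contiguous watersheds from random seed cells by synchronous
# randomized frontier expansion (rook neighbourhood). Every cell ends up with
# exactly one label in 1..n and every label is non-empty.
grow_watersheds <- function(nrow, ncol, n) {
  lab <- matrix(0L, nrow, ncol)
  seeds <- sample.int(nrow * ncol, n)
  lab[seeds] <- seq_len(n)
  shift <- function(m, di, dj) {
    out <- matrix(0L, nrow, ncol)
    src_i <- seq_len(nrow) - di; src_j <- seq_len(ncol) - dj
    ok_i <- src_i >= 1 & src_i <= nrow; ok_j <- src_j >= 1 & src_j <= ncol
    out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
    out
  }
  while (any(lab == 0L)) {
    nb <- list(shift(lab, 1, 0), shift(lab, -1, 0),
               shift(lab, 0, 1), shift(lab, 0, -1))
    cand <- which(lab == 0L &
                    (nb[[1]] > 0 | nb[[2]] > 0 | nb[[3]] > 0 | nb[[4]] > 0))
    if (!length(cand)) stop("watershed growth stalled")  # unreachable
    opts <- cbind(nb[[1]][cand], nb[[2]][cand], nb[[3]][cand], nb[[4]][cand])
    pick <- apply(opts, 1L, function(v) {
      v <- v[v > 0L]
      if (length(v) == 1L) v else v[sample.int(length(v), 1L)]
    })
    lab[cand] <- pick
  }
  lab
}

#' Generate a synthetic landscape
#'
#' Produces every raw input the covariate engine consumes: an elevation
#' raster, a stream/water raster with annual-flow attributes, a land-cover
#' raster, per-year April-1 snow-depth rasters, daily min/max temperature
#' records at weather stations, and a contiguous watershed partition. All
#' continuous fields are spatially autocorrelated Gaussian random fields with
#' the configured correlation length; station temperature climatology is tied
#' to the elevation raster through the adiabatic lapse rate so that
#' lapse-rate correction in the covariate engine is exercised for real.
#'
#' @param config a [landscape_config()].
#' @return a list of class `landscape` with elements `config`, `cell_km`,
#'   `elevation` (m), `flow` (cubic feet/s; 0 = dry cell), `landcover`
#'   (character matrix of classes), `snow` (list of April-1 depth matrices,
#'   m), `partition` (integer watershed-id matrix), `stations` (data frame),
#'   and `series` (per-station list with `years`, `tmax`, `tmin` matrices of
#'   dimension 365 x years; NA = missing record).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(derive_seed(config$seed, "landscape"), {
    nr <- config$nrow; nc <- config$ncol; ck <- config$cell_km
    # elevation: broad field, positive, mountainous in patches
    elev_f <- gaussian_field(nr, nc, corr_length_for(config, "elevation"), ck)
    elevation <- pmax(500 + 400 * elev_f, 0)

    # water: stream network from a thresholded field; lognormal annual flow
    wf <- gaussian_field(nr, nc, corr_length_for(config, "water"), ck)
    flow <- matrix(0, nr, nc)
    wet <- wf > stats::quantile(wf, 0.85)
    flow[wet] <- stats::rlnorm(sum(wet), meanlog = 1.6, sdlog = 1.1)

    # land cover: competing autocorrelated propensity fields
    clc <- corr_length_for(config, "landcover")
    f_forest <- gaussian_field(nr, nc, clc, ck)
    f_crop   <- gaussian_field(nr, nc, clc, ck)
    f_mast   <- gaussian_field(nr, nc, clc, ck)
    landcover <- matrix("grass", nr, nc)
    landcover[f_forest > 0.4] <-
      sample(c("deciduous", "evergreen", "mixed"), sum(f_forest > 0.4),
             replace = TRUE, prob = c(0.5, 0.3, 0.2))
    crop <- f_crop > 0.8 & landcover == "grass"
    landcover[crop] <- "crop"
    mast <- f_mast > 1.0 & landcover == "grass"
    landcover[mast] <- "mast"
    landcover[flow > 0 & f_forest > 0.2] <- "woody_wetland"
    landcover[flow > 0 & f_forest <= 0.2] <- "open_water"

    # climate: south (high row index) warm, north cold; lapse with elevation.
    # summer-heat and winter-cold climatologies use separate fields so the
    # two day-count covariates are correlated but not collinear
    lat <- matrix(rep(seq_len(nr) / nr, nc), nr, nc)
    clim_warm <- gaussian_field(nr, nc, corr_length_for(config, "climate"), ck)
    clim_cold <- gaussian_field(nr, nc, corr_length_for(config, "climate"), ck)
    warm_site <- 25 + 5 * lat + 5 * clim_warm - 6.49 * elevation / 1000
    cold_site <- 1 + 8 * lat + 6 * clim_cold - 6.49 * elevation / 1000

    # April-1 snow depth (m): cold, high sites hold snow; yearly variation
    snow_f <- gaussian_field(nr, nc, corr_length_for(config, "snow"), ck)
    snow_base <- pmax(0.08 * (2 - cold_site) + 0.12 * snow_f, 0)
    snow <- lapply(seq_len(config$n_snow_years), function(y) {
      yr_f <- gaussian_field(nr, nc, corr_length_for(config, "snow"), ck)
      pmax(snow_base * stats::rlnorm(1, 0, 0.2) + 0.05 * yr_f, 0)
    })

    partition <- grow_watersheds(nr, nc, config$n_watersheds)

    # weather stations: distinct cells; elevation taken from the raster
    st_cells <- sample.int(nr * nc, config$n_stations)
    st_i <- (st_cells - 1L) %% nr + 1L
    st_j <- (st_cells - 1L) %/% nr + 1L
    stations <- data.frame(
      station_id = sprintf("st%03d", seq_len(config$n_stations)),
      x_km = (st_j - 0.5) * ck, y_km = (st_i - 0.5) * ck,
      elev_m = elevation[st_cells], stringsAsFactors = FALSE)

    # daily records: site climatology + seasonal cycle + weather noise;
    # some stations report fewer years and a few percent of days are missing
    nyw <- config$n_weather_years
    day <- seq_len(365)
    season <- -cos(2 * pi * day / 365)  # -1 on Jan 1, +1 at midsummer
    series <- lapply(seq_len(config$n_stations), function(k) {
      warm_k <- warm_site[st_cells[k]]
      cold_k <- cold_site[st_cells[k]]
      n_avail <- if (stats::runif(1) < 0.2)
        sample(10:(nyw - 1), 1L) else nyw
      yrs <- seq.int(nyw - n_avail + 1L, nyw)
      tmax <- matrix(warm_k + 11 * season +
                       stats::rnorm(365 * n_avail, 0, 3), 365, n_avail)
      tmin <- matrix(cold_k + 11 * season +
                       stats::rnorm(365 * n_avail, 0, 3), 365, n_avail)
      tmin <- pmin(tmin, tmax - 1)
      miss <- stats::runif(365 * n_avail) < 0.03
      tmax[miss] <- NA_real_; tmin[miss] <- NA_real_
      list(station_id = stations$station_id[k], years = yrs,
           tmax = tmax, tmin = tmin)
    })
    names(series) <- stations$station_id

    structure(list(config = config, cell_km = ck, elevation = elevation,
                   flow = flow, landcover = landcover, snow = snow,
                   partition = partition, stations = stations,
                   series = series),
              class = "landscape")
  })
}

#' Watershed attribute table
#'
#' Summarizes the watershed partition of a landscape into one row per unit:
#' cell count, area, centroid coordinates, and centroid elevation (elevation
#' raster value at the cell nearest the centroid).
#'
#' @param landscape a [generate_landscape()] result.
#' @return data frame with columns `watershed_id`, `n_cells`, `area_km2`,
#'   `centroid_x_km`, `centroid_y_km`, `centroid_elev_m`.
#' @export
watershed_table <- function(landscape) {
  p <- landscape$partition; ck <- landscape$cell_km
  nr <- nrow(p)
  cell <- seq_along(p)
  i <- (cell - 1L) %% nr + 1L
  j <- (cell - 1L) %/% nr + 1L
  x <- (j - 0.5) * ck; y <- (i - 0.5) * ck
  ids <- sort(unique(as.vector(p)))
  n_cells <- as.vector(table(factor(p, levels = ids)))
  cx <- tapply(x, p, mean); cy <- tapply(y, p, mean)
  # elevation at the cell of the watershed nearest its centroid
  celev <- vapply(seq_along(ids), function(k) {
    sel <- which(as.vector(p) == ids[k])
    d2 <- (x[sel] - cx[k])^2 + (y[sel] - cy[k])^2
    landscape$elevation[sel[which.min(d2)]]
  }, numeric(1))
  data.frame(watershed_id = ids, n_cells = n_cells,
             area_km2 = n_cells * ck^2,
             centroid_x_km = as.numeric(cx), centroid_y_km = as.numeric(cy),
             centroid_elev_m = celev, row.names = NULL)
}

#' Watershed adjacency (shared boundary edge)
#'
#' Two watersheds are adjacent when some cell of one shares an edge (rook
#' neighbourhood) with a cell of the other.
#'
#' @param partition integer watershed-id matrix.
#' @return data frame of unordered adjacent pairs (`a` < `b`).
#' @export
watershed_adjacency <- function(partition) {
  p <- partition
  pairs <- rbind(
    cbind(as.vector(p[-nrow(p), ]), as.vector(p[-1, ])),
    cbind(as.vector(p[, -ncol(p)]), as.vector(p[, -1])))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  pairs <- unique(pairs)
  data.frame(a = pairs[, 1], b = pairs[, 2])
}
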