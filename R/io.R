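#' Write a gridded raster as CSV with a sidecar JSON header
#'
#' Plain-text raster export: cell values in row-major CSV (no header row)
#' plus `<path>.json` recording dimensions and cell size.
#'
#' @param m matrix.
#' @param path output CSV path.
#' @param cell_km cell size recorded in the sidecar.
#' @export
write_grid_csv <- function(m, path, cell_km = NA_real_) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = is.character(m[1]))
  jsonlite::write_json(list(nrow = nrow(m), ncol = ncol(m),
                            cell_km = cell_km),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_csv
#' @param character read cells as character (land-cover grids)?
#' @export
read_grid_csv <- function(path, character = FALSE) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  m <- as.matrix(utils::read.table(path, sep = ",",
                                   colClasses = if (character) "character"
                                   else "numeric"))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == meta$nrow, ncol(m) == meta$ncol)
  attr(m, "cell_km") <- meta$cell_km
  m
}

#' Write weather stations and their daily records as CSV
#'
#' Long format: one row per station-day with year, day-of-year, and min/max
#' temperature (NA = missing record).
#'
#' @param landscape a [generate_landscape()] result.
#' @param path output CSV path.
#' @export
write_stations_csv <- function(landscape, path) {
  rows <- lapply(landscape$series, function(rec) {
    st <- landscape$stations[landscape$stations$station_id ==
                               rec$station_id, ]
    ny <- length(rec$years)
    data.frame(station_id = rec$station_id, x_km = st$x_km, y_km = st$y_km,
               elev_m = st$elev_m,
               year = rep(rec$years, each = 365),
               day = rep(seq_len(365), ny),
               tmin_c = as.vector(rec$tmin), tmax_c = as.vector(rec$tmax))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the watershed table as GeoJSON centroid points
#'
#' @param watersheds watershed table ([watershed_table()]).
#' @param path output path.
#' @export
write_watersheds_geojson <- function(watersheds, path) {
  feats <- lapply(seq_len(nrow(watersheds)), function(i) {
    w <- watersheds[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(w$centroid_x_km, w$centroid_y_km)),
         properties = list(id = w$watershed_id,
                           centroid_elev_m = w$centroid_elev_m,
                           area_km2 = w$area_km2, n_cells = w$n_cells))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_watersheds_geojson
#' @export
read_watersheds_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  rows <- lapply(g$features, function(f)
    data.frame(watershed_id = f$properties$id,
               n_cells = f$properties$n_cells,
               area_km2 = f$properties$area_km2,
               centroid_x_km = f$geometry$coordinates[[1]],
               centroid_y_km = f$geometry$coordinates[[2]],
               centroid_elev_m = f$properties$centroid_elev_m))
  do.call(rbind, rows)
}

# Compress a cell set into maximal vertical runs; returns a data frame of
# rectangles (i0, i1, j) in cell units.
cell_runs <- function(cells, nrow_grid) {
  i <- (cells - 1L) %% nrow_grid + 1L
  j <- (cells - 1L) %/% nrow_grid + 1L
  ord <- order(j, i)
  i <- i[ord]; j <- j[ord]
  brk <- c(TRUE, diff(i) != 1L | diff(j) != 0L)
  run <- cumsum(brk)
  data.frame(i0 = tapply(i, run, min), i1 = tapply(i, run, max),
             j = tapply(j, run, min))
}

#' Write occurrence polygons as GeoJSON
#'
#' Each population-year polygon (a union of covered grid cells) is emitted as
#' a MultiPolygon of axis-aligned rectangles (maximal vertical cell runs) in
#' km coordinates — an exact cover of the same cells, not a dissolved
#' boundary.
#'
#' @param polygons polygon table from [simulate_occurrence()].
#' @param nrow_grid number of grid rows (to decode cell indices).
#' @param cell_km cell size (km).
#' @param path output path.
#' @export
write_polygons_geojson <- function(polygons, nrow_grid, cell_km, path) {
  feats <- lapply(seq_len(nrow(polygons)), function(p) {
    runs <- cell_runs(polygons$cells[[p]], nrow_grid)
    rects <- lapply(seq_len(nrow(runs)), function(r) {
      x0 <- (runs$j[r] - 1) * cell_km; x1 <- runs$j[r] * cell_km
      y0 <- (runs$i0[r] - 1) * cell_km; y1 <- runs$i1[r] * cell_km
      list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
    })
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = rects),
         properties = list(population_id = polygons$population_id[p],
                           year = polygons$year[p],
                           area_km2 = polygons$area_km2[p]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path, nrow_grid, cell_km) {
  g <- jsonlite::read_json(path)
  rows <- lapply(g$features, function(f) {
    cells <- unlist(lapply(f$geometry$coordinates, function(rect) {
      ring <- rect[[1]]
      xs <- vapply(ring, function(pt) pt[[1]], numeric(1))
      ys <- vapply(ring, function(pt) pt[[2]], numeric(1))
      j <- round(min(xs) / cell_km) + 1L
      i0 <- round(min(ys) / cell_km) + 1L
      i1 <- round(max(ys) / cell_km)
      (j - 1L) * nrow_grid + i0:i1
    }))
    out <- data.frame(population_id = f$properties$population_id,
                      year = f$properties$year,
                      area_km2 = f$properties$area_km2,
                      stringsAsFactors = FALSE)
    out$cells <- list(sort(as.integer(cells)))
    out
  })
  do.call(rbind, rows)
}

#' Write a covariate table as CSV with a standardization sidecar
#'
#' @param table covariate table.
#' @param path output CSV path; standardization metadata (if present) goes to
#'   `<path>.json`.
#' @export
write_covariates_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  meta <- attr(table, "standardization")
  if (!is.null(meta))
    jsonlite::write_json(list(center = as.list(meta$center),
                              scale = as.list(meta$scale),
                              sample_ids = meta$sample_ids),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_covariates_csv
#' @export
read_covariates_csv <- function(path) {
  tab <- utils::read.csv(path)
  class(tab) <- c("covariate_table", "data.frame")
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(tab, "standardization") <- list(center = unlist(meta$center),
                                         scale = unlist(meta$scale),
                                         sample_ids = meta$sample_ids)
  }
  tab
}

#' Write a resolved configuration as key = value text
#'
#' @param config named list (nested lists are flattened with `.` separators).
#' @param path output path.
#' @export
write_config_txt <- function(config, path) {
  flat <- list()
  walk <- function(x, prefix) {
    for (nm in names(x)) {
      key <- if (nzchar(prefix)) paste(prefix, nm, sep = ".") else nm
      v <- x[[nm]]
      if (is.list(v)) walk(v, key)
      else flat[[key]] <<- paste(format(v, digits = 15), collapse = ",")
    }
  }
  walk(config, "")
  writeLines(paste0(names(flat), " = ", unlist(flat)), path)
  invisible(path)
}
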