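#' Assign population polygons to watershed presences
#'
#' Aggregates occurrence polygons to watershed-year presence records using
#' the two size criteria of the national analysis: a population polygon
#' counts toward a watershed only if (a) its total area exceeds
#' `min_area_km2` (three times the mean U.S. wild pig home range, 13 km^2)
#' and (b) the polygon covers more than `min_prop` (2.5%) of the watershed's
#' area.
#'
#' @param polygons data frame with `population_id`, `year`, `area_km2`, and a
#'   `cells` list-column of covered grid-cell indices (the raster analogue of
#'   the drawn population polygons).
#' @param partition integer watershed-id matrix.
#' @param watersheds watershed table ([watershed_table()]).
#' @param min_area_km2 minimum total polygon area (km^2).
#' @param min_prop minimum covered proportion of the watershed (0-1).
#' @param cell_km cell size (km).
#' @return occurrence series: data frame `watershed_id`, `year`, `present`,
#'   `introduction` (initialized FALSE; see [flag_introductions()]),
#'   `population_id`, sorted by year then watershed.
#' @export
assign_presence <- function(polygons, partition, watersheds,
                            min_area_km2 = 13, min_prop = 0.025, cell_km) {
  n_cell <- length(partition)
  max_id <- max(watersheds$watershed_id)
  area_of <- stats::setNames(watersheds$area_km2, watersheds$watershed_id)
  rows <- list()
  for (p in seq_len(nrow(polygons))) {
    cells <- polygons$cells[[p]]
    if (!length(cells) || anyNA(cells) || any(cells < 1 | cells > n_cell))
      stop(sprintf("invalid geometry for polygon `%s`",
                   polygons$population_id[p]), call. = FALSE)
    if (polygons$area_km2[p] <= min_area_km2) next
    hit <- tabulate(partition[cells], nbins = max_id)
    ids <- which(hit > 0)
    prop <- hit[ids] * cell_km^2 / area_of[as.character(ids)]
    ids <- ids[prop > min_prop]
    if (length(ids))
      rows[[length(rows) + 1L]] <- data.frame(
        watershed_id = ids, year = polygons$year[p], present = TRUE,
        introduction = FALSE, population_id = polygons$population_id[p],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(watershed_id = integer(), year = integer(),
                      present = logical(), introduction = logical(),
                      population_id = character()))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("watershed_id", "year")]), ]
  out[order(out$year, out$watershed_id), , drop = FALSE]
}

#' Flag likely human introductions in an occurrence series
#'
#' A watershed's first-occupancy record is flagged as a likely human
#' introduction when its centroid is farther than `dispersal_threshold_km`
#' from every watershed occupied in the previous year (year-1 founding
#' records are never flagged). A flagged watershed's records are excluded
#' from the presence data until the first later year in which it is again
#' reported occupied or an adjacent watershed becomes occupied; from that
#' year on its records are re-included.
#'
#' @param series occurrence series ([assign_presence()]).
#' @param watersheds watershed table.
#' @param dispersal_threshold_km distance beyond which first occupancies are
#'   deemed introductions; see [estimate_dispersal_threshold()] for a
#'   data-driven default.
#' @param adjacency optional [watershed_adjacency()] table enabling the
#'   adjacent-occupancy re-inclusion rule.
#' @return the series with `introduction` set on flagged first-occupancy
#'   records and a logical `excluded` column marking records dropped from the
#'   presence data.
#' @export
flag_introductions <- function(series, watersheds, dispersal_threshold_km,
                               adjacency = NULL) {
  if (dispersal_threshold_km <= 0)
    stop("`dispersal_threshold_km` must be positive", call. = FALSE)
  if (!nrow(series)) {
    series$excluded <- logical()
    return(series)
  }
  series <- series[order(series$year, series$watershed_id), , drop = FALSE]
  first_year <- tapply(series$year, series$watershed_id, min)
  fy <- stats::setNames(as.integer(first_year),
                        names(first_year))
  idx <- match(watersheds$watershed_id, as.integer(names(fy)))
  fy_all <- as.integer(fy[idx])  # NA = never occupied
  xy <- cbind(watersheds$centroid_x_km, watersheds$centroid_y_km)
  nb <- NULL
  if (!is.null(adjacency)) {
    nb <- vector("list", max(watersheds$watershed_id))
    for (r in seq_len(nrow(adjacency))) {
      nb[[adjacency$a[r]]] <- c(nb[[adjacency$a[r]]], adjacency$b[r])
      nb[[adjacency$b[r]]] <- c(nb[[adjacency$b[r]]], adjacency$a[r])
    }
  }
  series$introduction <- FALSE
  series$excluded <- FALSE
  years <- sort(unique(series$year))
  for (y in years[-1]) {
    new_ids <- watersheds$watershed_id[!is.na(fy_all) & fy_all == y]
    if (!length(new_ids)) next
    prev <- which(!is.na(fy_all) & fy_all < y)
    if (!length(prev)) next
    for (w in new_ids) {
      wi <- match(w, watersheds$watershed_id)
      dmin <- min(sqrt((xy[prev, 1] - xy[wi, 1])^2 +
                         (xy[prev, 2] - xy[wi, 2])^2))
      if (dmin <= dispersal_threshold_km) next
      rec <- which(series$watershed_id == w & series$year == y)
      series$introduction[rec] <- TRUE
      # re-inclusion: first later year with a new report here or adjacent
      later <- series$year[series$watershed_id == w & series$year > y]
      reinc <- if (length(later)) min(later) else NA_integer_
      if (!is.null(nb) && length(nb) >= w && length(nb[[w]])) {
        nb_first <- fy_all[match(nb[[w]], watersheds$watershed_id)]
        nb_first <- nb_first[!is.na(nb_first) & nb_first > y]
        if (length(nb_first)) reinc <- min(reinc, min(nb_first), na.rm = TRUE)
      }
      drop_until <- if (is.na(reinc)) Inf else reinc - 1L
      series$excluded[series$watershed_id == w & series$year >= y &
                        series$year <= drop_until] <- TRUE
    }
  }
  series
}

#' Data-driven dispersal threshold
#'
#' The 95th percentile of the distances between each newly occupied watershed
#' and the nearest watershed occupied in the previous year, mirroring the use
#' of the observed first-occupancy distance distribution to separate natural
#' spread from translocation.
#'
#' @param series occurrence series.
#' @param watersheds watershed table.
#' @param prob quantile of the first-occupancy distance distribution.
#' @return distance threshold in km.
#' @export
estimate_dispersal_threshold <- function(series, watersheds, prob = 0.95) {
  first_year <- tapply(series$year, series$watershed_id, min)
  ids <- as.integer(names(first_year))
  fy <- as.integer(first_year)
  xy <- cbind(watersheds$centroid_x_km, watersheds$centroid_y_km)
  pos <- match(ids, watersheds$watershed_id)
  d <- numeric(0)
  for (y in sort(unique(fy))[-1]) {
    new_i <- pos[fy == y]; prev_i <- pos[fy < y]
    if (!length(new_i) || !length(prev_i)) next
    for (wi in new_i)
      d <- c(d, min(sqrt((xy[prev_i, 1] - xy[wi, 1])^2 +
                           (xy[prev_i, 2] - xy[wi, 2])^2)))
  }
  if (!length(d)) stop("no first-occupancy distances available",
                       call. = FALSE)
  as.numeric(stats::quantile(d, prob))
}

#' Build presence and background samples
#'
#' The presence sample is the union over years of watersheds with
#' non-excluded presence records; the background sample is a seeded uniform
#' draw without replacement of `multiplier` times the presence count from
#' all watersheds (including those in the presence sample).
#'
#' @param series occurrence series (after [flag_introductions()]; if no
#'   `excluded` column is present all records count).
#' @param watersheds watershed table.
#' @param multiplier background-to-presence sample size ratio.
#' @param seed integer seed for the background draw.
#' @return a list of class `sample_design`: `presence`, `background`
#'   (watershed id vectors), `multiplier`, `seed`.
#' @export
build_samples <- function(series, watersheds, multiplier = 2, seed = 1L) {
  if (!nrow(series)) stop("occurrence series is empty", call. = FALSE)
  keep <- if ("excluded" %in% names(series)) !series$excluded else
    rep(TRUE, nrow(series))
  presence <- sort(unique(series$watershed_id[series$present & keep]))
  n_bg <- round(multiplier * length(presence))
  if (n_bg > nrow(watersheds))
    stop(sprintf(paste("background sample (%d) exceeds the %d available",
                       "watersheds; use a smaller multiplier"),
                 n_bg, nrow(watersheds)), call. = FALSE)
  background <- with_seed(derive_seed(seed, "background"),
                          sort(sample(watersheds$watershed_id, n_bg)))
  structure(list(presence = presence, background = background,
                 multiplier = multiplier, seed = as.integer(seed)),
            class = "sample_design")
}

#' Assemble the estimation data for a sample design
#'
#' Stacks presence rows (label 1) over background rows (label 0) of a
#' standardized covariate table; a watershed drawn in both roles contributes
#' one row per role.
#'
#' @param covariates standardized `covariate_table`.
#' @param samples a [build_samples()] design.
#' @return data frame with `watershed_id`, `y`, and covariate columns,
#'   carrying the standardization metadata.
#' @export
estimation_data <- function(covariates, samples) {
  stopifnot(inherits(samples, "sample_design"))
  rows <- match(c(samples$presence, samples$background),
                covariates$watershed_id)
  if (anyNA(rows)) stop("sample ids missing from covariate table",
                        call. = FALSE)
  out <- covariates[rows, , drop = FALSE]
  out$y <- rep(c(1L, 0L),
               c(length(samples$presence), length(samples$background)))
  attr(out, "standardization") <- attr(covariates, "standardization")
  rownames(out) <- NULL
  out
}
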