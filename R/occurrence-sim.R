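#' Simulate multi-year wild pig occupancy and occurrence polygons
#'
#' Drives a known logistic occupancy process over the watersheds of a
#' synthetic landscape. Year 1 seeds the top `seed_quantile` fraction of
#' watersheds by true linear predictor. In each later year, every unoccupied
#' watershed adjacent to an occupied one becomes occupied with probability
#' `plogis(intercept_true + beta_true' z)`, and additionally a
#' `Poisson(intro_rate)` number of watersheds farther than `dispersal_km`
#' (centroid distance) from every occupied watershed are occupied as
#' human-introduction events and labelled as such. Occupied watersheds stay
#' occupied. Every occupied population (connected component of occupied
#' watersheds) emits, each year, a polygon covering `polygon_fraction` of
#' each member watershed's cells.
#'
#' @param landscape a [generate_landscape()] result.
#' @param config the [landscape_config()] used to generate it.
#' @param covariates the standardized [compute_covariates()] table for the
#'   landscape (standardized over all watersheds, so the true coefficients
#'   are on a defined scale).
#' @return a list of class `occurrence_sim`: `series` (data frame
#'   `watershed_id`, `year`, `present`, `introduction`, `population_id`),
#'   `polygons` (data frame `population_id`, `year`, `area_km2` and a `cells`
#'   list-column of covered cell indices), `eta` (true linear predictor per
#'   watershed, including the intercept), and `occupied` (logical
#'   watersheds-by-years matrix).
#' @export
simulate_occurrence <- function(landscape, config, covariates) {
  stopifnot(inherits(landscape, "landscape"),
            inherits(config, "landscape_config"))
  ws <- watershed_table(landscape)
  if (!identical(sort(covariates$watershed_id), sort(ws$watershed_id)))
    stop("covariate table does not match the landscape's watersheds",
         call. = FALSE)
  if (is.null(attr(covariates, "standardization")))
    stop("covariates must be standardized before simulating occupancy",
         call. = FALSE)
  covariates <- covariates[match(ws$watershed_id, covariates$watershed_id), ]
  X <- build_design(covariates, covariate_terms(quadratic = TRUE))
  eta <- config$intercept_true + drop(X %*% config$beta_true[colnames(X)])
  n <- nrow(ws)
  adj <- watershed_adjacency(landscape$partition)
  nb <- vector("list", n)
  for (r in seq_len(nrow(adj))) {
    nb[[adj$a[r]]] <- c(nb[[adj$a[r]]], adj$b[r])
    nb[[adj$b[r]]] <- c(nb[[adj$b[r]]], adj$a[r])
  }
  cdist <- as.matrix(stats::dist(cbind(ws$centroid_x_km, ws$centroid_y_km)))

  with_seed(derive_seed(config$seed, "occupancy"), {
    occupied <- matrix(FALSE, n, config$n_years)
    intro <- first_year <- rep(NA_integer_, n)
    n_seed <- max(1L, ceiling(config$seed_quantile * n))
    start <- order(-eta, ws$watershed_id)[seq_len(n_seed)]
    occupied[start, 1] <- TRUE
    first_year[start] <- 1L
    for (y in seq.int(2L, config$n_years)) {
      prev <- occupied[, y - 1L]
      occupied[, y] <- prev
      cand <- setdiff(unique(unlist(nb[which(prev)])), which(prev))
      if (length(cand)) {
        col <- cand[stats::runif(length(cand)) < stats::plogis(eta[cand])]
        occupied[col, y] <- TRUE
        first_year[col] <- y
      }
      n_int <- stats::rpois(1, config$intro_rate)
      if (n_int > 0) {
        far <- which(!occupied[, y] &
                       apply(cdist[, prev, drop = FALSE], 1, min) >
                         config$dispersal_km)
        if (length(far)) {
          pick <- far[sample.int(length(far), min(n_int, length(far)))]
          occupied[pick, y] <- TRUE
          first_year[pick] <- y
          intro[pick] <- y
        }
      }
    }

    # per-watershed polygon blob: cells grown around the centroid cell
    cells_of <- split(seq_along(landscape$partition),
                      as.vector(landscape$partition))
    blob <- lapply(seq_len(n), function(w) {
      cells <- cells_of[[as.character(ws$watershed_id[w])]]
      k <- max(1L, round(config$polygon_fraction * length(cells)))
      nr <- nrow(landscape$partition)
      ci <- (cells - 1L) %% nr + 1L
      cj <- (cells - 1L) %/% nr + 1L
      cx <- (cj - 0.5) * landscape$cell_km
      cy <- (ci - 0.5) * landscape$cell_km
      d2 <- (cx - ws$centroid_x_km[w])^2 + (cy - ws$centroid_y_km[w])^2
      cells[order(d2, cells)[seq_len(k)]]
    })

    series <- list(); polys <- list()
    g_all <- igraph::graph_from_data_frame(adj, directed = FALSE,
                                           vertices = data.frame(seq_len(n)))
    for (y in seq_len(config$n_years)) {
      occ <- which(occupied[, y])
      sub <- igraph::induced_subgraph(g_all, occ)
      comp <- igraph::components(sub)$membership
      pop_id <- sprintf("y%02d_p%02d", y, comp)
      series[[y]] <- data.frame(
        watershed_id = ws$watershed_id[occ], year = y, present = TRUE,
        introduction = !is.na(intro[occ]) & intro[occ] == y,
        population_id = pop_id, stringsAsFactors = FALSE)
      for (cid in sort(unique(comp))) {
        members <- occ[comp == cid]
        cells <- sort(unlist(blob[members], use.names = FALSE))
        polys[[length(polys) + 1L]] <- data.frame(
          population_id = sprintf("y%02d_p%02d", y, cid), year = y,
          area_km2 = length(cells) * landscape$cell_km^2,
          stringsAsFactors = FALSE)
        polys[[length(polys)]]$cells <- list(cells)
      }
    }
    series <- do.call(rbind, series)
    polygons <- do.call(rbind, polys)
    structure(list(series = series, polygons = polygons, eta = eta,
                   occupied = occupied, first_year = first_year,
                   intro_year = intro,
                   watershed_id = ws$watershed_id),
              class = "occurrence_sim")
  })
}

#' Draw a well-specified presence-background estimation sample
#'
#' Samples presence watersheds i.i.d. with probability proportional to
#' `exp(beta' z)` over the watersheds of a standardized covariate table, and
#' background watersheds i.i.d. uniformly from all watersheds (overlap with
#' the presence sample allowed, as in the presence-background design). Under
#' this design the logistic discrimination function is exactly well
#' specified: the log odds of the presence label given the covariates is
#' linear in the model terms with slopes equal to `beta`. Used by the
#' parameter-recovery and cross-validation calibration studies, where known
#' true coefficients are required.
#'
#' @param covariates standardized `covariate_table`.
#' @param beta named true coefficient vector over model terms (quadratic term
#'   allowed).
#' @param n_presence number of presence draws.
#' @param multiplier background sample size as a multiple of `n_presence`.
#' @param seed integer seed.
#' @return data frame with `watershed_id`, `y` (1 presence / 0 background)
#'   and the standardized covariate columns, carrying the table's
#'   standardization metadata.
#' @export
sample_presence_background <- function(covariates, beta, n_presence,
                                       multiplier = 2, seed = 1L) {
  if (is.null(attr(covariates, "standardization")))
    stop("covariates must be standardized", call. = FALSE)
  X <- build_design(covariates, names(beta))
  w <- exp(drop(X %*% beta))
  with_seed(seed, {
    pres <- sample.int(nrow(covariates), n_presence, replace = TRUE,
                       prob = w / sum(w))
    bg <- sample.int(nrow(covariates), round(multiplier * n_presence),
                     replace = TRUE)
    rows <- c(pres, bg)
    out <- covariates[rows, , drop = FALSE]
    out$y <- rep(c(1L, 0L), c(length(pres), length(bg)))
    attr(out, "standardization") <- attr(covariates, "standardization")
    rownames(out) <- NULL
    out
  })
}
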