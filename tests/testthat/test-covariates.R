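test_that("lapse-rate adjustment moves temperatures with elevation", {
  expect_equal(adjust_temperature(30.0, 200, 1200), 23.51)
  expect_equal(adjust_temperature(10.0, 500, 500), 10.0)
  expect_equal(adjust_temperature(-1.0, 1500, 500), 5.49)
})

test_that("day counts average over years and respect the lapse adjustment", {
  ws <- data.frame(watershed_id = 1L, centroid_x_km = 0, centroid_y_km = 0,
                   centroid_elev_m = 100)
  # year 1: 3 hot days; year 2: 5 hot days; no cold days
  tmax <- matrix(20, 365, 2)
  tmax[1:3, 1] <- 36; tmax[1:5, 2] <- 36
  st <- toy_station("a", 0, 0, 100, tmax)
  out <- temperature_day_covariates(st$stations, st$series, ws)
  expect_equal(out$days_above_35, 4.0)
  expect_equal(out$days_below_minus4, 0.0)

  # a 35.5 degC day seen from a centroid 200 m higher adjusts to 34.202
  ws2 <- ws; ws2$centroid_elev_m <- 300
  tmax2 <- matrix(20, 365, 1); tmax2[1, 1] <- 35.5
  st2 <- toy_station("a", 0, 0, 100, tmax2)
  out2 <- temperature_day_covariates(st2$stations, st2$series, ws2)
  expect_equal(out2$days_above_35, 0.0)
  # same day from a centroid 200 m lower adjusts to 36.798 and is counted
  ws3 <- ws; ws3$centroid_elev_m <- -100
  out3 <- temperature_day_covariates(st2$stations, st2$series, ws3)
  expect_equal(out3$days_above_35, 1.0)
})

test_that("station selection honours the search radius and station cap", {
  ws <- data.frame(watershed_id = 7L, centroid_x_km = 0, centroid_y_km = 0,
                   centroid_elev_m = 0)
  hot_year <- function(n_days) {
    m <- matrix(20, 365, 1); if (n_days > 0) m[seq_len(n_days), 1] <- 40; m
  }
  near <- toy_station("near", 10, 0, 0, hot_year(2))
  far <- toy_station("far", 251, 0, 0, hot_year(100))
  stations <- rbind(near$stations, far$stations)
  series <- c(near$series, far$series)
  out <- temperature_day_covariates(stations, series, ws)
  expect_equal(out$days_above_35, 2.0)  # the 251 km station is outside 250 km

  # twelve in-radius stations, cap 10: the two farthest are ignored
  sts <- lapply(1:12, function(k)
    toy_station(sprintf("s%02d", k), k, 0, 0, hot_year(k)))
  stations <- do.call(rbind, lapply(sts, `[[`, "stations"))
  series <- do.call(c, lapply(sts, `[[`, "series"))
  out <- temperature_day_covariates(stations, series, ws, max_stations = 10)
  expect_equal(out$days_above_35, mean(1:10))

  expect_error(
    temperature_day_covariates(near$stations, near$series,
                               transform(ws, centroid_x_km = 1e4)),
    "no weather station within .* watershed 7")
})

test_that("day counts are invariant to station order and duplication", {
  ws <- data.frame(watershed_id = 1L, centroid_x_km = 0, centroid_y_km = 0,
                   centroid_elev_m = 50)
  set.seed(4)
  sts <- lapply(1:4, function(k)
    toy_station(sprintf("s%d", k), k * 10, -k * 5, 40 * k,
                matrix(rnorm(365 * 3, 24, 8), 365, 3)))
  stations <- do.call(rbind, lapply(sts, `[[`, "stations"))
  series <- do.call(c, lapply(sts, `[[`, "series"))
  base <- temperature_day_covariates(stations, series, ws)
  shuffled <- temperature_day_covariates(stations[c(3, 1, 4, 2), ], series, ws)
  duplicated <- temperature_day_covariates(rbind(stations, stations[2, ]),
                                           series, ws)
  expect_equal(shuffled, base)
  expect_equal(duplicated, base)
})

test_that("snow depth averages over years then within watersheds", {
  part <- matrix(rep(1:2, each = 8), 4, 4)
  zero <- list(matrix(0, 4, 4))
  expect_equal(mean_snow_depth(zero, part)$snow_depth, c(0, 0))
  two <- list(matrix(0.10, 4, 4), matrix(0.20, 4, 4))
  expect_equal(mean_snow_depth(two, part)$snow_depth, c(0.15, 0.15))
  set.seed(8)
  grids <- replicate(3, matrix(runif(16), 4, 4), simplify = FALSE)
  got <- mean_snow_depth(grids, part)
  # cell-wise brute force
  for (w in 1:2) {
    cells <- which(part == w)
    expect_equal(got$snow_depth[w],
                 mean(sapply(cells, function(c)
                   mean(sapply(grids, `[[`, c)))))
  }
  expect_error(mean_snow_depth(list(matrix(0, 3, 3)), part), "shape")
})

test_that("distance to water is exact and respects the flow cutoff", {
  part <- matrix(1L, 3, 3)
  ws1 <- toy_watershed_table(part, 1)
  flow <- matrix(0, 3, 3); flow[2, 2] <- 3
  got <- mean_distance_to_water(flow, part, cell_km = 1)
  expect_equal(got$dist_water, (0 + 4 * 1 + 4 * sqrt(2)) / 9,
               tolerance = 1e-12)
  # a watershed that is entirely retained water sits at distance 0
  allwater <- matrix(5, 2, 2)
  expect_equal(mean_distance_to_water(allwater, matrix(1L, 2, 2), 1)$dist_water,
               0)
  # a 2.9 cfs stream is ephemeral and leaves no retained water
  low <- matrix(0, 3, 3); low[2, 2] <- 2.9
  expect_error(mean_distance_to_water(low, part, 1), "no retained water")
})

test_that("raising the flow cutoff never shrinks distances to water", {
  land <- small_landscape()
  d1 <- mean_distance_to_water(land$flow, land$partition, land$cell_km, 1)
  d3 <- mean_distance_to_water(land$flow, land$partition, land$cell_km, 3)
  d6 <- mean_distance_to_water(land$flow, land$partition, land$cell_km, 6)
  expect_true(all(d3$dist_water >= d1$dist_water - 1e-12))
  expect_true(all(d6$dist_water >= d3$dist_water - 1e-12))
})

test_that("percent cover matches a counting-loop oracle", {
  part <- matrix(rep(1:2, each = 8), 4, 4)
  all_crop <- matrix("crop", 4, 4)
  expect_equal(percent_cover(all_crop, part, "crop")$percent, c(100, 100))
  half <- matrix(rep(c("crop", "grass"), 8), 4, 4)
  expect_equal(percent_cover(half, part, "crop")$percent, c(50, 50))
  set.seed(12)
  rnd <- matrix(sample(c("crop", "grass", "deciduous"), 16, replace = TRUE),
                4, 4)
  got <- percent_cover(rnd, part, c("crop", "deciduous"))
  for (w in 1:2) {
    cells <- which(part == w)
    expect_equal(got$percent[w],
                 100 * sum(rnd[cells] %in% c("crop", "deciduous")) /
                   length(cells))
  }
  expect_error(percent_cover(rnd, part, "swamp"), "unknown land-cover class")
})

test_that("heterogeneity equals an exhaustive window scan", {
  # single water cell, window radius 1 cell (home range = pi km^2 at 1 km cells)
  nr <- 7
  part <- matrix(1L, nr, nr)
  water <- matrix(FALSE, nr, nr); water[4, 4] <- TRUE
  none <- matrix(FALSE, nr, nr)
  got <- heterogeneity_index(water, none, none, part, cell_km = 1,
                             home_range_km2 = pi)
  brute <- 0
  for (i in 1:nr) for (j in 1:nr) {
    seen <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (sqrt(di^2 + dj^2) > 1 + 1e-9) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nr && water[ii, jj])
        seen <- TRUE
    }
    brute <- brute + seen
  }
  expect_equal(got$heterogeneity, brute / nr^2)
  expect_error(heterogeneity_index(water, none, none, part, 1, -9),
               "positive")
  expect_error(heterogeneity_index(water, none, matrix(FALSE, 2, 2), part, 1),
               "shape")
})

test_that("standardization uses the stated sample and back-transforms", {
  cov <- small_covariates()
  cz <- standardize_covariates(cov)
  meta <- attr(cz, "standardization")
  for (cn in covariate_terms()) {
    expect_lt(abs(mean(cz[[cn]])), 1e-9)
    expect_lt(abs(sd(cz[[cn]]) - 1), 1e-9)
    expect_equal(unstandardize(cz[[cn]], cz, cn), cov[[cn]],
                 tolerance = 1e-12)
  }
  # a watershed sitting at the sample mean standardizes to zero
  sub <- standardize_covariates(cov, sample_ids = cov$watershed_id[1:10])
  m <- mean(cov$snow_depth[1:10])
  expect_lt(abs(sd(sub$snow_depth[1:10]) - 1), 1e-9)
  # two-watershed sample {0, 2}: sample SD convention gives +/- 0.7071
  toy <- data.frame(watershed_id = 1:2)
  for (cn in covariate_terms()) toy[[cn]] <- c(0, 2)
  class(toy) <- c("covariate_table", "data.frame")
  tz <- standardize_covariates(toy)
  expect_equal(tz$dist_water, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # constant columns are refused by name
  toy2 <- toy; toy2$forage_pct <- 5
  expect_error(standardize_covariates(toy2), "forage_pct")
  expect_error(standardize_covariates(tz), "already standardized")
})

test_that("derived covariates respect their documented ranges", {
  cov <- small_covariates()
  expect_true(all(cov$forest_pct >= 0 & cov$forest_pct <= 100))
  expect_true(all(cov$forage_pct >= 0 & cov$forage_pct <= 100))
  expect_true(all(cov$heterogeneity >= 0 & cov$heterogeneity <= 3))
  expect_true(all(cov$dist_water >= 0))
  expect_true(all(cov$days_above_35 >= 0 & cov$days_above_35 <= 366))
  expect_true(all(cov$days_below_minus4 >= 0 & cov$days_below_minus4 <= 366))
})
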