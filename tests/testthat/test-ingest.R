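# Build a polygon row in the cell-set representation.
toy_polygon <- function(id, year, cells, cell_km) {
  out <- data.frame(population_id = id, year = year,
                    area_km2 = length(cells) * cell_km^2,
                    stringsAsFactors = FALSE)
  out$cells <- list(cells)
  out
}

test_that("presence assignment enforces both aggregation criteria", {
  # 24 km^2 watershed; a 12 km^2 polygon covers half of it but is too small
  part <- matrix(1L, 4, 6)
  ws <- toy_watershed_table(part, 1)
  p12 <- toy_polygon("a", 1, 1:12, 1)
  expect_equal(nrow(assign_presence(p12, part, ws, cell_km = 1)), 0)

  # 4900 km^2 watershed; a 100 km^2 polygon covers only 2.04% of it
  part2 <- matrix(1L, 70, 70)
  ws2 <- toy_watershed_table(part2, 1)
  p100 <- toy_polygon("b", 1, 1:100, 1)
  expect_equal(nrow(assign_presence(p100, part2, ws2, cell_km = 1)), 0)

  # 200 km^2 watershed; a 20 km^2 polygon covers 10% and passes both
  part3 <- matrix(1L, 10, 20)
  ws3 <- toy_watershed_table(part3, 1)
  p20 <- toy_polygon("c", 3, 1:20, 1)
  got <- assign_presence(p20, part3, ws3, cell_km = 1)
  expect_equal(got$watershed_id, 1L)
  expect_equal(got$year, 3)
  expect_true(got$present)

  expect_error(assign_presence(toy_polygon("bad", 1, c(1, 9999), 1),
                               part3, ws3, cell_km = 1),
               "invalid geometry for polygon `bad`")
})

test_that("tightening either criterion never adds presence records", {
  land <- small_landscape()
  ws <- small_watersheds()
  sim <- simulate_occurrence(land, small_config(), small_covariates_std())
  loose <- assign_presence(sim$polygons, land$partition, ws, 13, 0.025,
                           land$cell_km)
  tight_area <- assign_presence(sim$polygons, land$partition, ws, 100, 0.025,
                                land$cell_km)
  tight_prop <- assign_presence(sim$polygons, land$partition, ws, 13, 0.2,
                                land$cell_km)
  key <- function(s) paste(s$watershed_id, s$year)
  expect_true(all(key(tight_area) %in% key(loose)))
  expect_true(all(key(tight_prop) %in% key(loose)))
})

test_that("introduction flagging follows distance and re-inclusion rules", {
  # watersheds on a line: A,B close together; C far away
  ws <- data.frame(watershed_id = 1:3, n_cells = 1, area_km2 = 100,
                   centroid_x_km = c(0, 10, 300), centroid_y_km = 0,
                   centroid_elev_m = 0)
  mkseries <- function(...) {
    rows <- list(...)
    out <- do.call(rbind, lapply(rows, function(r)
      data.frame(watershed_id = r[1], year = r[2], present = TRUE,
                 introduction = FALSE, population_id = "p")))
    out
  }
  # B appears next to A: not flagged; C appears 300 km away: flagged
  s <- mkseries(c(1, 1), c(2, 2), c(3, 2))
  got <- flag_introductions(s, ws, dispersal_threshold_km = 30)
  expect_false(any(got$introduction[got$watershed_id == 2]))
  expect_true(all(got$introduction[got$watershed_id == 3]))
  expect_true(all(got$excluded[got$watershed_id == 3]))

  # C re-reported the following year: re-included from that year
  s2 <- mkseries(c(1, 1), c(3, 2), c(3, 3))
  got2 <- flag_introductions(s2, ws, 30)
  expect_true(got2$introduction[got2$watershed_id == 3 & got2$year == 2])
  expect_true(got2$excluded[got2$watershed_id == 3 & got2$year == 2])
  expect_false(got2$excluded[got2$watershed_id == 3 & got2$year == 3])

  # year-1 founding populations are never flagged
  s3 <- mkseries(c(1, 1), c(3, 1))
  got3 <- flag_introductions(s3, ws, 30)
  expect_false(any(got3$introduction))

  # adjacency re-inclusion: D adjacent to C occupied later
  ws4 <- rbind(ws, data.frame(watershed_id = 4, n_cells = 1, area_km2 = 100,
                              centroid_x_km = 310, centroid_y_km = 0,
                              centroid_elev_m = 0))
  adj <- data.frame(a = 3, b = 4)
  s4 <- mkseries(c(1, 1), c(3, 2), c(4, 4))
  got4 <- flag_introductions(s4, ws4, 30, adjacency = adj)
  # C flagged in year 2, but its neighbour D occupied in year 4 re-includes it
  expect_true(got4$introduction[got4$watershed_id == 3])
  expect_true(got4$excluded[got4$watershed_id == 3])  # only the year-2 record
  # D itself is 10 km from C (occupied earlier), so D is natural spread
  expect_false(got4$introduction[got4$watershed_id == 4])
  expect_equal(sum(got4$excluded), 1)
})

test_that("flags are internally consistent with the distance rule", {
  land <- small_landscape()
  ws <- small_watersheds()
  cfg <- small_config(intro_rate = 1.5)
  sim <- simulate_occurrence(land, cfg, small_covariates_std())
  series <- assign_presence(sim$polygons, land$partition, ws, 13, 0.025,
                            land$cell_km)
  series <- flag_introductions(series, ws, cfg$dispersal_km)
  first_year <- tapply(series$year, series$watershed_id, min)
  xy <- cbind(ws$centroid_x_km, ws$centroid_y_km)
  flagged <- series[series$introduction, ]
  expect_gt(nrow(flagged), 0)
  for (r in seq_len(nrow(flagged))) {
    w <- match(flagged$watershed_id[r], ws$watershed_id)
    prev_ids <- as.integer(names(first_year))[first_year < flagged$year[r]]
    prev <- match(prev_ids, ws$watershed_id)
    dmin <- min(sqrt((xy[prev, 1] - xy[w, 1])^2 + (xy[prev, 2] - xy[w, 2])^2))
    expect_gt(dmin, cfg$dispersal_km)
  }
})

test_that("background sampling is sized, seeded, and uniform", {
  ws <- data.frame(watershed_id = 1:300, n_cells = 1, area_km2 = 100,
                   centroid_x_km = runif(300), centroid_y_km = runif(300),
                   centroid_elev_m = 0)
  series <- data.frame(watershed_id = 1:100, year = 1, present = TRUE,
                       introduction = FALSE, population_id = "p",
                       excluded = FALSE)
  s <- build_samples(series, ws, multiplier = 2, seed = 5)
  expect_length(s$presence, 100)
  expect_length(s$background, 200)
  expect_identical(s$background, build_samples(series, ws, 2, 5)$background)
  expect_false(identical(s$background, build_samples(series, ws, 2, 6)$background))
  expect_error(build_samples(series, ws, multiplier = 5, seed = 1),
               "smaller multiplier")
  # overlap fraction matches the sampling expectation |presence| / N
  overlap <- vapply(1:50, function(k)
    mean(build_samples(series, ws, 2, k)$background %in% s$presence),
    numeric(1))
  expect_lt(abs(mean(overlap) - 100 / 300), 0.03)
})

test_that("excluded introduction records drop out of the presence sample", {
  ws <- data.frame(watershed_id = 1:10, n_cells = 1, area_km2 = 100,
                   centroid_x_km = c(0, 5, 500, seq(10, 40, 5)),
                   centroid_y_km = 0, centroid_elev_m = 0)
  series <- data.frame(watershed_id = c(1, 2, 3), year = c(1, 2, 2),
                       present = TRUE, introduction = FALSE,
                       population_id = "p")
  series <- flag_introductions(series, ws, 50)
  s <- build_samples(series, ws, multiplier = 2, seed = 1)
  expect_setequal(s$presence, c(1, 2))  # watershed 3 excluded as introduction
})

test_that("the estimated dispersal threshold tracks observed spread", {
  ws <- data.frame(watershed_id = 1:5, n_cells = 1, area_km2 = 1,
                   centroid_x_km = c(0, 10, 20, 30, 400), centroid_y_km = 0,
                   centroid_elev_m = 0)
  series <- data.frame(watershed_id = 1:5, year = c(1, 2, 3, 4, 5),
                       present = TRUE, introduction = FALSE,
                       population_id = "p")
  thr <- estimate_dispersal_threshold(series, ws, prob = 0.75)
  expect_equal(thr, as.numeric(quantile(c(10, 10, 10, 370), 0.75)))
})
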