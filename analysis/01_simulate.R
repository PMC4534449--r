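#!/usr/bin/env Rscript
# Stage 1: generate the synthetic landscape and the multi-year wild pig
# occupancy history, and export the raw data products (rasters, stations,
# watersheds, occurrence polygons) that the rest of the analysis ingests.

source("analysis/config.R")

land <- get_landscape()
ws <- get_watersheds()
sim <- get_sim()
lc <- get_landscape_config()

write_grid_csv(land$elevation, file.path(out_dir, "elevation.csv"),
               land$cell_km)
write_grid_csv(land$flow, file.path(out_dir, "flow.csv"), land$cell_km)
write_grid_csv(land$landcover, file.path(out_dir, "landcover.csv"),
               land$cell_km)
write_grid_csv(land$partition, file.path(out_dir, "partition.csv"),
               land$cell_km)
write_stations_csv(land, file.path(out_dir, "stations.csv"))
write_watersheds_geojson(ws, file.path(out_dir, "watersheds.geojson"))
write_polygons_geojson(sim$polygons, nrow(land$partition), land$cell_km,
                       file.path(out_dir, "occurrence_polygons.geojson"))

cat(sprintf("Landscape: %d x %d cells of %g km, %d watersheds (mean %.0f km2, range %.0f-%.0f)\n",
            lc$nrow, lc$ncol, lc$cell_km, nrow(ws), mean(ws$area_km2),
            min(ws$area_km2), max(ws$area_km2)))
occ <- colSums(sim$occupied)
cat(sprintf("Occupancy: year 1 = %d watersheds; year %d = %d; year %d = %d (monotone spread)\n",
            occ[1], ceiling(lc$n_years / 2), occ[ceiling(lc$n_years / 2)],
            lc$n_years, occ[lc$n_years]))
cat(sprintf("Human introductions simulated: %d (farther than %g km from the occupied front)\n",
            sum(!is.na(sim$intro_year)), lc$dispersal_km))
cat(sprintf("Occurrence polygons emitted: %d population-years\n",
            nrow(sim$polygons)))
cat("Raw products written under", out_dir, "\n")
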