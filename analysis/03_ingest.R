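#!/usr/bin/env Rscript
# Stage 3: aggregate occurrence polygons to watershed presences, flag likely
# human introductions from first-occupancy distances, and draw the presence
# and background samples.

source("analysis/config.R")

series <- get_series()
samples <- get_samples()

utils::write.csv(series, file.path(out_dir, "occurrence_series.csv"),
                 row.names = FALSE)
utils::write.csv(
  data.frame(role = rep(c("presence", "background"),
                        c(length(samples$presence),
                          length(samples$background))),
             watershed_id = c(samples$presence, samples$background)),
  file.path(out_dir, "samples.csv"), row.names = FALSE)

cat(sprintf("Occurrence records (watershed-years): %d\n", nrow(series)))
cat(sprintf("Dispersal threshold: %.1f km%s\n", .state$dispersal_km,
            if (is.null(cfg$dispersal_km))
              " (95th percentile of observed first-occupancy distances)"
            else " (configured)"))
cat(sprintf("Flagged introduction events: %d; records excluded: %d (%.1f%% of all records)\n",
            sum(series$introduction), sum(series$excluded),
            100 * mean(series$excluded)))
cat(sprintf("Presence sample: %d watersheds; background sample: %d (x%g, drawn from all %d watersheds, overlap allowed)\n",
            length(samples$presence), length(samples$background),
            cfg$background_multiplier, nrow(get_watersheds())))
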