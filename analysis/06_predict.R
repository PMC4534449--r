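#!/usr/bin/env Rscript
# Stage 6: map the relative probability of wild pig occurrence across all
# watersheds with the exponential form of the averaged model.

source("analysis/config.R")

avg <- get_averaged()
cov_fit <- get_cov_fit()
pe <- predict_relative_occurrence(avg, cov_fit, "exponential")
pl <- predict_relative_occurrence(avg, cov_fit, "logistic")
preds <- data.frame(watershed_id = pe$watershed_id, eta = pe$eta,
                    score_exponential = pe$score, score_logistic = pl$score)
utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                 row.names = FALSE)

ord <- order(-preds$score_exponential)
cat("Relative occurrence probability (exponential form, intercept-free):\n")
cat("  highest-risk watersheds:",
    paste(preds$watershed_id[ord[1:5]], collapse = ", "), "\n")
cat("  lowest-risk watersheds:",
    paste(preds$watershed_id[rev(ord)[1:5]], collapse = ", "), "\n")
occupied <- get_sim()$occupied[, ncol(get_sim()$occupied)]
cat(sprintf("  median score, occupied vs never-occupied: %.2f vs %.2f\n",
            median(preds$score_exponential[occupied]),
            median(preds$score_exponential[!occupied])))

# raster map of the prediction painted over the watershed partition
land <- get_landscape()
score_map <- matrix(preds$score_exponential[match(as.vector(land$partition),
                                                  preds$watershed_id)],
                    nrow(land$partition))
pdf(file.path(out_dir, "occurrence_map.pdf"), width = 6, height = 6)
image(t(score_map)[, nrow(score_map):1], axes = FALSE, useRaster = TRUE,
      col = hcl.colors(64, "YlOrRd", rev = TRUE),
      main = "Relative probability of wild pig occurrence")
dev.off()
cat("Prediction map written to", file.path(out_dir, "occurrence_map.pdf"), "\n")
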