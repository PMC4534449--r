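#!/usr/bin/env Rscript
# Stage 4: fit all additive subsets of the global logistic discrimination
# model and average them with AICc shrinkage weights.

source("analysis/config.R")

ledger <- get_ledger()
avg <- get_averaged()

utils::write.csv(ledger$table, file.path(out_dir, "subset_ledger.csv"),
                 row.names = FALSE)
utils::write.csv(avg$table, file.path(out_dir, "averaged_model.csv"),
                 row.names = FALSE)

cat(sprintf("All-subsets ledger: %d models over %d terms (marginality %s), n = %d\n",
            nrow(ledger$table), length(get_model_spec()$terms),
            ifelse(cfg$marginality, "on", "off"), ledger$n))
top <- ledger$table[1, ]
null_row <- ledger$table[ledger$table$terms == "", ]
cat(sprintf("Top model: weight %.2f; null model is %.0f AICc units worse\n",
            top$weight, null_row$AICc - top$AICc))
cat("\nModel-averaged estimates (shrinkage), unconditional SEs, 95% CIs, importance:\n")
print(transform(avg$table, estimate = round(estimate, 3), se = round(se, 3),
                ci_low = round(ci_low, 4), ci_high = round(ci_high, 4),
                importance = round(importance, 2)), row.names = FALSE)

pred <- predict_relative_occurrence(avg, get_cov_fit(), "exponential")
opt <- attr(pred, "optimum")
if (!is.null(opt))
  cat(sprintf("\nHot-days response peaks at z* = %.2f SD, i.e. %.0f days above 35 degC per year on the natural scale\n",
              opt$z_star, opt$x_star))
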