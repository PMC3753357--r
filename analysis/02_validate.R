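#!/usr/bin/env Rscript
# Stage 2: repeated 80/20 holdout validation of the two forest models on the
# stage-1 dataset (averaged R-squared for the continuous model, averaged
# Cohen's kappa for the binomial one; 30 repeats, lakes split as units).
#
# Reads:  results/lakes_synthetic.csv
# Writes: results/validation.json, results/validation_repeats.csv

suppressPackageStartupMessages(library(lakescen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

d <- read_lake_table("results/lakes_synthetic.csv")
cat(sprintf("validating on %d lakes / %d observations (seed %d)\n",
            nrow(d$records), nrow(d$observations), seed))
val <- repeated_holdout(d$records, d$observations, train_frac = 0.8,
                        n_repeats = 30, split_unit = "lake",
                        rng_seed = seed + 1L, pooled = TRUE)
print(val)
cat(sprintf("  pooled across repeats: R2 %.3f, kappa %.3f\n",
            val$pooled_r2, val$pooled_kappa))
write.csv(val$per_repeat, "results/validation_repeats.csv", row.names = FALSE)
jsonlite::write_json(
  list(mean_r2 = val$mean_r2, mean_kappa = val$mean_kappa,
       pooled_r2 = val$pooled_r2, pooled_kappa = val$pooled_kappa,
       n_repeats = val$n_repeats, train_frac = val$train_frac,
       split_unit = val$split_unit, rng_seed = val$rng_seed),
  "results/validation.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/validation.json\n")
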