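#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Draws one default cohort of 71 farrow-to-finish farms (census plus latent
# per-animal usage targets), emits the matching prescription records against
# the demo formulary, and writes the monitoring-programme style input files
# under results/data/.

library(pigamu)

seed <- 1L
out_dir <- "results/data"

sim <- simulate_to_csv(default_config(), seed = seed, out_dir = out_dir)

census <- sim$cohort$census
sows <- census$n_animals[census$age_category == "sow"]
records <- read_usage(sim$usage)

cat("Simulated cohort (seed ", seed, "):\n", sep = "")
cat("  farms:            ", default_config()$n_farms, "\n")
cat("  sows kept:         mean ", round(mean(sows), 1), ", sd ",
    round(sd(sows), 1), ", range ", min(sows), "-", max(sows), "\n", sep = "")
cat("  usage records:    ", nrow(records), "\n")
cat("  farms with zero usage: ",
    sum(!census$farm_id %in% records$farm_id) / 4, "\n")
cat("  files: ", sim$usage, ", ", sim$census, ", ", sim$provenance, "\n",
    sep = "")
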