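#!/usr/bin/env Rscript
# Step 1: simulate the registry-style cohort.
#
# Generates the default synthetic cohort (n = 372): two competing causes
# of death, Weibull event times with covariate-linked scales, ~66%
# right-censoring, covariate margins emulating a colorectal-cancer
# registry. Writes the cohort, its latent truth table, and a baseline
# descriptive summary.

suppressPackageStartupMessages(library(crweibull))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(n = 372, seed = 20260922)
d <- generate_cohort(cfg)

write_cohort(d, "results/cohort.csv")
utils::write.csv(attr(d, "truth"), "results/cohort.truth.csv",
                 row.names = FALSE)

s <- summarize_cohort(d)
write_summary(s, tsv_path = "results/table1_baseline.tsv",
              json_path = "results/table1_baseline.json")

cat("Simulated cohort written to results/cohort.csv\n")
print(s)
cat("\nEvent mix vs the emulated registry: ~29.8% colorectal-cancer",
    "deaths,\n~3.8% other-cause deaths, ~66% censored.\n")
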