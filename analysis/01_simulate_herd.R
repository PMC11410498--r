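#!/usr/bin/env Rscript
# Stage 1 — simulate the study-scale herd and write the raw input tables.
#
# 79 cow datasets (NOC 36, DTC 25, WDC 18) over 29 calendar days starting
# at 57 days in milk, minute-resolution motion index with circadian and
# ultradian harmonics, milking-anchored peaks, estrus days, and sensor
# dropout. Tables land in scratch/data/ in the same CSV dialect a farm
# export would use (local-time ISO-8601 timestamps with UTC offsets).

library(cowrhythms)

scenario <- herd_scenario(seed = 20210901)
sim <- simulate_herd(scenario)
paths <- write_scenario_tables(sim, "scratch/data")

cat("Simulated", length(unique(sim$activity$cow_id)), "cows,",
    nrow(sim$activity), "minute records over", scenario$days, "days\n")
cat("Estrus cows:", sum(lengths(sim$meta$estrus_dates) > 0), "\n")
cat("Wrote:", paste(basename(paths), collapse = ", "), "\n")
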