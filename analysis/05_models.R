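#!/usr/bin/env Rscript
# Stage 5 — assemble the cow-day model frame and fit the two mixed
# models: binomial (logit) for the median-split DFC and Gaussian for the
# IQR-filtered DI, both with nested random intercepts and AR(1) serial
# correlation.

library(cowrhythms)
suppressMessages({library(readr); library(dplyr)})

dfc <- read_csv("scratch/dfc_records.csv", show_col_types = FALSE)
di <- read_csv("scratch/di_records.csv", show_col_types = FALSE)
deviation <- read_csv("results/milking_deviation.csv",
                      show_col_types = FALSE)
meta <- read_csv("scratch/data/cow_meta.csv", show_col_types = FALSE)
ed <- as.character(meta$estrus_dates)
meta$estrus_dates <- lapply(strsplit(ifelse(is.na(ed), "", ed), ";"),
                            as.Date)

frame <- assemble_model_frame(dfc, di, deviation, meta)
write_csv(frame, "scratch/model_frame.csv")
cat("Model frame:", nrow(frame), "cow-day rows,",
    length(unique(frame$dataset_id)), "cow datasets\n")

dfc_model <- fit_dfc_model(frame)
if (length(dfc_model$excluded_clusters)) {
  cat("Excluded (no outcome variation):",
      paste(dfc_model$excluded_clusters, collapse = ", "), "\n")
}
di_model <- fit_di_model(frame)

write_csv(dfc_model$tidy, "results/dfc_model.csv")
write_csv(di_model$tidy, "results/di_model.csv")
lines <- format_model_table(dfc_model, di_model)
writeLines(lines, "results/model_table.txt")
cat(lines, sep = "\n")
cat("\nEstimated marginal DI means per treatment:\n")
print(di_model$emmeans)
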