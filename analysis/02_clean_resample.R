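#!/usr/bin/env Rscript
# Stage 2 — read the raw tables, convert CET/CEST to GMT, drop unreliable
# and boundary days, restrict to 59-83 days in milk, and resample to
# 15-min bins by summation.

library(cowrhythms)
suppressMessages(library(readr))

activity <- read_activity("scratch/data/activity.csv")
schedule <- read_milking_schedule("scratch/data/milking_schedule.csv")
meta <- read_csv("scratch/data/cow_meta.csv", show_col_types = FALSE)
meta$calving_date <- as.Date(meta$calving_date)

gmt <- convert_to_gmt(activity, schedule)
cleaned <- exclude_invalid_days(gmt$series)
log <- attr(cleaned, "exclusion_log")
write_csv(log, "results/exclusion_log.csv")

restricted <- restrict_dim_window(cleaned, meta)
flagged <- attr(restricted, "flagged_excluded")
activity15 <- resample_15min(restricted)
write_csv(activity15, "scratch/activity_15min.csv")
write_csv(gmt$schedule, "scratch/schedule_utc.csv")

cat("Excluded day rows:", nrow(log), "(",
    sum(grepl("zero-run", log$rule)), "zero-run,",
    sum(grepl("first/last", log$rule)), "boundary,",
    sum(grepl("incomplete", log$rule)), "incomplete )\n")
cat("Cows flagged out for < 15 retained days:",
    if (length(flagged)) paste(flagged, collapse = ", ") else "none", "\n")
cat("15-min records:", nrow(activity15), "for",
    length(unique(activity15$cow_id)), "cows\n")
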