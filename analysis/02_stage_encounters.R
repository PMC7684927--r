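#!/usr/bin/env Rscript

# Step 2: apply the exclusion cascade and run the event-driven AKIN staging
# engine over every retained encounter of both phases.
#
# Writes per-phase stages.csv (encounter_id, timestamp, source, stage) and
# exclusion_report.json under results/.

suppressPackageStartupMessages(library(akiflow))

dir.create("results", showWarnings = FALSE)

for (phase in c("control", "intervention")) {
  cohort <- read_chart_events(file.path("data", phase, "events.csv"),
                              file.path("data", phase, "encounters.csv"))
  res <- apply_exclusions(cohort)
  cat(sprintf("%s: %d -> %d retained\n", phase, res$report$initial,
              res$report$retained))
  print(res$report)
  write_exclusion_report(res$report,
                         file.path("results",
                                   paste0(phase, "_exclusion_report.json")))
  series <- stage_cohort(res$retained)
  readr::write_csv(stages_table(series),
                   file.path("results", paste0(phase, "_stages.csv")))
  saveRDS(series, file.path("results", paste0(phase, "_series.rds")))
  saveRDS(res$retained, file.path("results", paste0(phase, "_retained.rds")))
}
cat("stage series written under results/\n")
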