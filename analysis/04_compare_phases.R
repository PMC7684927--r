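#!/usr/bin/env Rscript

# Step 4: two-cohort comparison statistics.
#
# Compares the phases on the primary outcome (stage-1 progression), AKI
# development, discharge stage and dosing errors with the pooled
# two-proportion z test, and reruns the design power calculation with the
# one-tailed Fisher exact simulation.

suppressPackageStartupMessages(library(akiflow))

out <- lapply(c("control", "intervention"), function(phase) {
  list(outcomes = readr::read_csv(
         file.path("results", paste0(phase, "_outcomes.csv")),
         show_col_types = FALSE),
       doses = readr::read_csv(
         file.path("results", paste0(phase, "_doses.csv")),
         show_col_types = FALSE))
})
names(out) <- c("control", "intervention")

cmp <- function(label, x1, n1, x2, n2) {
  r <- two_proportion_test(x1, n1, x2, n2)
  cat(sprintf("%-28s %4d/%4d (%5.1f%%) vs %4d/%4d (%5.1f%%)  z = %6.3f  p = %.4g\n",
              label, x1, n1, 100 * r$p1, x2, n2, 100 * r$p2, r$z, r$p_value))
  list(metric = label, x1 = x1, n1 = n1, x2 = x2, n2 = n2,
       p1 = r$p1, p2 = r$p2, z = r$z, p_value = r$p_value)
}

oc <- out$control$outcomes
oi <- out$intervention$outcomes
results <- list(
  cmp("progressed from stage 1",
      sum(oc$progressed_from_1), sum(oc$max_stage >= 1),
      sum(oi$progressed_from_1), sum(oi$max_stage >= 1)),
  cmp("developed AKI in ICU",
      sum(!oc$aki_at_admission & oc$max_stage >= 1), nrow(oc),
      sum(!oi$aki_at_admission & oi$max_stage >= 1), nrow(oi)),
  cmp("discharged with AKI",
      sum(oc$discharge_stage >= 1, na.rm = TRUE), nrow(oc),
      sum(oi$discharge_stage >= 1, na.rm = TRUE), nrow(oi)),
  cmp("incorrect enoxaparin doses",
      out$control$doses$incorrect_doses, out$control$doses$total_doses,
      out$intervention$doses$incorrect_doses,
      out$intervention$doses$total_doses)
)
jsonlite::write_json(results, "results/comparison.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)

# design power at the study's own parameters: baseline progression 42%, a 15%
# relative reduction, alpha 0.04, one-tailed Fisher exact test
pw <- fisher_power_simulation(baseline_rate = 0.42, relative_reduction = 0.15,
                              n_per_arm = 3000, alpha = 0.04,
                              replicates = 5000, seed = 20201123)
cat("\n")
print(pw)
jsonlite::write_json(
  list(baseline_rate = pw$baseline_rate, relative_reduction = 0.15,
       n_per_arm = pw$n_per_arm, alpha = pw$alpha, power = pw$power,
       replicates = pw$replicates),
  "results/power.json", auto_unbox = TRUE, digits = NA)
cat("comparison written to results/comparison.json and results/power.json\n")
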