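#!/usr/bin/env Rscript
# In vivo analogue: a 22-subject synthetic neonate cohort generated from the
# printed cohort statistics is pushed through the full pipeline
# (separation -> fat-fraction map -> signal mask -> seeded segmentation ->
# quantification), producing the depot volume / fat-fraction summary table,
# the paired white-vs-brown comparison and fat-fraction/volume correlations.

suppressPackageStartupMessages(library(neobat))
dir.create("results", showWarnings = FALSE)

message("Running the 22-subject cohort pipeline (default grid) ...")
run <- run_cohort_pipeline(cohort_spec(n_subjects = 22, seed = 42),
                           progress = TRUE)

write.csv(run$stats, "results/cohort_stats.csv", row.names = FALSE)
write.csv(run$summary, "results/cohort_summary.csv", row.names = FALSE)
jsonlite::write_json(list(paired = run$paired,
                          correlations = run$correlations),
                     "results/cohort_comparisons.json",
                     auto_unbox = TRUE, digits = NA)

message("Depot summary (volume cc, fat fraction %):")
print(run$summary, digits = 3)
message("Paired WAT - BAT fat-fraction difference: ",
        round(run$paired$delta_pct, 1), " points (p = ",
        format(run$paired$p_value, digits = 3), ")")
for (r in names(run$correlations)) {
  cc <- run$correlations[[r]]
  if (!is.null(cc)) {
    message("FF-volume correlation, ", r, ": r = ", round(cc$r, 2),
            " (p = ", format(cc$p_value, digits = 2), ")")
  }
}
if (nrow(run$exclusions)) {
  message(nrow(run$exclusions), " subject(s) excluded for swap artifacts.")
}
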