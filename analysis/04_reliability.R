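#!/usr/bin/env Rscript
# Rater reliability, two ways.
#
# (a) Jitter study: every subject of a 12-subject cohort is segmented three
#     times (rater 1 twice, rater 2 once), each rating with independently
#     jittered seed points (expected displacement 1 mm); ICC/WSC/N per
#     region and metric. On these phantoms the protocol converges to the
#     same eligibility component from any in-depot seed, so the study
#     measures the protocol's seed robustness (near-perfect ICC) rather
#     than the in vivo rater variance, which is driven by tissue ambiguity
#     the phantom deliberately lacks.
# (b) Variance-component simulation: rater tables drawn at the ICC/WSC/N
#     fractions reported for each region and metric, decomposed back, to
#     show the estimator recovers that regime at the study's sample size.

suppressPackageStartupMessages(library(neobat))
dir.create("results", showWarnings = FALSE)

message("Jitter-based three-rating study (12 subjects) ...")
rt <- run_rater_study(cohort_spec(n_subjects = 12, seed = 7),
                      jitter_mm = 1, seed = 77)
rep_jitter <- reliability_report(rt)
write.csv(rep_jitter, "results/reliability_jitter.csv", row.names = FALSE)
print(rep_jitter, digits = 3)

message("Variance-component simulation across the reported regime ...")
# reported ICC/WSC/N fractions per region x metric x comparison
regimes <- data.frame(
  region = rep(c("supraclavicular", "axillary", "union", "spine"), 2),
  metric = rep(c("volume_cc", "mean_ff"), each = 4),
  icc = c(0.61, 0.79, 0.86, 0.87, 0.83, 0.41, 0.91, 0.96),
  wsc = c(0.11, 0.07, 0.00, 0.00, 0.00, 0.04, 0.00, 0.01))
regimes$noise <- pmax(1 - regimes$icc - regimes$wsc, 0)

set.seed(99)
sim_rows <- lapply(seq_len(nrow(regimes)), function(i) {
  g <- regimes[i, ]
  est <- colMeans(do.call(rbind, lapply(1:40, function(k) {
    tab <- simulate_rater_table(
      22, raters = c("a", "b"),
      sigma_subject = sqrt(g$icc), sigma_rater = sqrt(g$wsc),
      sigma_error = sqrt(g$noise))
    d <- icc_decompose(tab)
    c(icc = d$icc, wsc = d$wsc, noise = d$noise)
  })))
  data.frame(region = g$region, metric = g$metric,
             icc_population = g$icc, icc_recovered = est[["icc"]],
             wsc_population = g$wsc, wsc_recovered = est[["wsc"]],
             noise_population = g$noise, noise_recovered = est[["noise"]])
})
sim <- do.call(rbind, sim_rows)
write.csv(sim, "results/reliability_simulation.csv", row.names = FALSE)
print(sim, digits = 2)
message("Mean absolute ICC recovery error at n = 22: ",
        round(mean(abs(sim$icc_recovered - sim$icc_population)), 3))
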