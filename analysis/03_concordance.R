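#!/usr/bin/env Rscript
# Run the full concordance study on each benchmark scenario: six dataset
# variants (three habitat scopes x raw / Q-filtered), four R-squared
# summaries each, with per-point audit trails. Writes one report table
# per scenario under results/ and prints the headline comparison.

suppressPackageStartupMessages(library(gtlbiomass))

seed <- 1
scenarios <- benchmark_scenarios(seed = seed)

headline <- NULL
for (nm in names(scenarios)) {
  out_dir <- file.path("results", paste0("run_", nm))
  res <- suppressMessages(run_full_analysis(list(
    simulate = scenarios[[nm]], seed = seed, out_dir = out_dir)))
  r <- res$reports
  cat(sprintf("== %s ==\n", nm))
  print(r[, c("dataset_label", "n_points", "slope", "r2_regression",
              "r2_identity", "n_influential", "r2_identity_removed")],
        digits = 4, row.names = FALSE)
  headline <- rbind(headline, data.frame(
    scenario = nm,
    identity_r2_raw = r$r2_identity[r$dataset_label == "whole_raw"],
    identity_r2_qfiltered =
      r$r2_identity[r$dataset_label == "whole_qfiltered"],
    n_q_removed = r$n_points[r$dataset_label == "whole_raw"] -
      r$n_points[r$dataset_label == "whole_qfiltered"]))
  cat("\n")
}

write.csv(headline, "results/scenario_headline.csv", row.names = FALSE)
cat("Headline identity-line R^2 (whole-community scope):\n")
print(headline, digits = 4, row.names = FALSE)
cat("\nNote how Q > 6 filtering matters most where juvenile cohorts\n")
cat("contaminate the survey, and how wide length dispersion (the\n")
cat("seawater-like regime) degrades agreement even after filtering.\n")
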