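#!/usr/bin/env Rscript
# Baseline (6 months pre-index) characteristics of the 3L+ cohorts:
# demographics, modified CCI excluding CML, severity class, comorbidity
# flags, hydroxyurea pretreatment and HSCT-unfitness.

suppressMessages({ library(cmllines); library(data.table) })

out_root <- "results/baseline"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

for (payer in c("commercial", "medicare")) {
  cfg <- study_config(payer)
  bundle <- read_claims_bundle(file.path("results/data-synth", payer), cfg)
  cohort <- fread(file.path("results/cohort", paste0("cohort_", payer, ".csv")))
  prof <- baseline_profile(bundle, cohort, cfg)
  sm <- summarize_baseline(prof)
  fwrite(prof, file.path(out_root, paste0("profile_", payer, ".csv")))
  fwrite(sm$continuous, file.path(out_root, paste0("continuous_", payer, ".csv")))
  fwrite(sm$categorical, file.path(out_root, paste0("categorical_", payer, ".csv")))
  message(sprintf("\n== %s (n = %d) ==", payer, nrow(prof)))
  print(sm$continuous)
  print(sm$categorical[variable %in% c("severity", "hsct_unfit_flag",
                                       "hypertension", "diabetes")])
}
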