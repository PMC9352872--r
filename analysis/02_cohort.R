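#!/usr/bin/env Rscript
# Apply the patient-selection cascade to both synthetic populations and
# write the attrition tables and 3L+ cohort definitions.

suppressMessages({ library(cmllines); library(data.table) })

in_root <- "results/data-synth"
out_root <- "results/cohort"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

for (payer in c("commercial", "medicare")) {
  cfg <- study_config(payer)
  bundle <- read_claims_bundle(file.path(in_root, payer), cfg)
  sel <- apply_selection(bundle, cfg)
  fwrite(sel$attrition, file.path(out_root, paste0("attrition_", payer, ".csv")))
  fwrite(sel$cohort, file.path(out_root, paste0("cohort_", payer, ".csv")))
  fwrite(sel$lines, file.path(out_root, paste0("lines_", payer, ".csv")))
  message(sprintf("\n== %s ==", payer))
  print(sel$attrition[, .(criterion, n_remaining, n_excluded)])
  message(sprintf("3L+ cohort: %d of %d patients (%s%%)",
                  nrow(sel$cohort), sel$attrition$n_remaining[1],
                  format_percent(nrow(sel$cohort),
                                 sel$attrition$n_remaining[1])))
}
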