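#!/usr/bin/env Rscript
# Generate the two synthetic study populations (commercial and Medicare)
# with ground-truth trajectories, and write the claims tables that the rest
# of the workflow consumes. Adds non-line-defining noise (unlisted drugs,
# pre-diagnosis hydroxyurea, non-CML outpatient claims) to the commercial
# extract so downstream stages are exercised against realistic clutter.

suppressMessages({ library(cmllines); library(data.table) })

out_root <- "results/data-synth"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

message("Simulating commercial population (n = 1500) ...")
spec_c <- trajectory_spec(n_patients = 1500, payer = "commercial", seed = 101)
sim_c <- generate_cohort(spec_c)
sim_c$bundle <- inject_noise(sim_c$bundle, n_other_fills = 400,
                             n_noncml_op = 800, n_pre_dx_hydroxyurea = 100,
                             seed = 102)
write_claims_bundle(sim_c$bundle, file.path(out_root, "commercial"))
fwrite(sim_c$truth$lines, file.path(out_root, "commercial", "truth_lines.csv"))
fwrite(sim_c$truth$patients,
       file.path(out_root, "commercial", "truth_patients.csv"))

message("Simulating Medicare population (n = 400) ...")
spec_m <- trajectory_spec(n_patients = 400, payer = "medicare", seed = 201)
sim_m <- generate_cohort(spec_m)
write_claims_bundle(sim_m$bundle, file.path(out_root, "medicare"))
fwrite(sim_m$truth$lines, file.path(out_root, "medicare", "truth_lines.csv"))
fwrite(sim_m$truth$patients,
       file.path(out_root, "medicare", "truth_patients.csv"))

for (nm in c("commercial", "medicare")) {
  b <- read_claims_bundle(file.path(out_root, nm))
  message(sprintf("%-10s: %d patients, %d pharmacy, %d medical claims", nm,
                  nrow(b$patients), nrow(b$pharmacy), nrow(b$medical)))
}
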