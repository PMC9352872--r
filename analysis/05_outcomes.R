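#!/usr/bin/env Rscript
# HRU and cost outcomes over the 3L+, 3L and 4L periods: annual incidence
# rates (all-cause and CML-related), PPPM costs by component in 2019 USD,
# HSCT event-level costs, and the HSCT-exclusion sensitivity analysis.

suppressMessages({ library(cmllines); library(data.table) })

out_root <- "results/outcomes"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

for (payer in c("commercial", "medicare")) {
  cfg <- study_config(payer)
  bundle <- read_claims_bundle(file.path("results/data-synth", payer), cfg)
  cohort <- fread(file.path("results/cohort", paste0("cohort_", payer, ".csv")))
  lines <- fread(file.path("results/cohort", paste0("lines_", payer, ".csv")))
  cl <- lines[patient_id %in% cohort$patient_id]

  per <- period_person_days(cl, cohort)
  fwrite(per, file.path(out_root, paste0("periods_", payer, ".csv")))

  hru <- summarize_hru(bundle$medical, per, cfg)
  fwrite(hru, file.path(out_root, paste0("hru_", payer, ".csv")))
  message(sprintf("\n== %s: annual incidence rates, 3L+ ==", payer))
  print(dcast(hru[period == "3L+"], measure ~ cause, value.var = "rate"))

  costs <- summarize_costs(bundle, per, cfg)
  fwrite(costs, file.path(out_root, paste0("costs_", payer, ".csv")))
  message(sprintf("== %s: PPPM costs (2019 USD), all-cause ==", payer))
  print(dcast(costs[cause == "all"], component ~ period, value.var = "mean"))

  hd <- cohort[!is.na(hsct_date), .(patient_id, hsct_date)]
  if (nrow(hd)) {
    hev <- hsct_event_cost(bundle, hd, cfg)
    fwrite(hev, file.path(out_root, paste0("hsct_events_", payer, ".csv")))
    message(sprintf("%s: %d HSCT events, mean (median) cost %s (%s)",
                    payer, nrow(hev),
                    format(round(mean(hev$event_cost)), big.mark = ","),
                    format(round(median(hev$event_cost)), big.mark = ",")))
    sens <- summarize_costs(sensitivity_exclude_hsct(bundle, hd, cfg), per, cfg)
    fwrite(sens, file.path(out_root, paste0("costs_sensitivity_", payer, ".csv")))
    d <- merge(costs[cause == "all" & component == "total", .(period, mean)],
               sens[cause == "all" & component == "total", .(period, mean)],
               by = "period", suffixes = c("_main", "_excl_hsct"))
    message(sprintf("%s: total PPPM with vs without HSCT costs:", payer))
    print(d)
  }
}
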