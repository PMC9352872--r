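# Cost attribution: CPI inflation, PPPM arithmetic, component additivity,
# HSCT event costing and the HSCT-exclusion sensitivity analysis.

mk_cohort <- function(id = "A", fu_start = 0, fu_end = 300) {
  data.table::data.table(patient_id = id, fu_start = dday(fu_start),
                         fu_end = dday(fu_end))
}

mk_lines <- function(id = "A", starts = c(0, 100), ends = c(100, 250),
                     numbers = c(3L, 4L)) {
  data.table::data.table(
    patient_id = id, line_number = numbers, drug = "nilotinib",
    start_date = dday(starts), end_date = dday(ends),
    supply_end_date = dday(ends), end_event = "censored",
    n_fills = 2L, interruption_count = 0L,
    treatment_free_days_to_next = NA_real_)
}

test_that("CPI inflation is the index ratio, with identity at the target year", {
  cpi <- data.table::data.table(year = c(2013L, 2019L), index = c(400, 500))
  expect_equal(inflate(100, 2019, cpi, 2019), 100)
  expect_equal(inflate(100, 2013, cpi, 2019), 125)
  expect_error(inflate(100, 2012, cpi, 2019), "2012")
  expect_error(inflate(100, 2013, cpi, 2020), "2020")
  ## random tables vs the direct ratio
  set.seed(4)
  for (i in 1:20) {
    yrs <- 2001:2019
    tab <- data.table::data.table(year = yrs,
                                  index = stats::runif(length(yrs), 100, 600))
    amt <- stats::runif(1, 1, 1e5)
    sy <- sample(yrs, 1)
    expect_equal(inflate(amt, sy, tab, 2019),
                 amt * tab[year == 2019, index] / tab[year == sy, index])
  }
  ## inflate-then-sum equals sum-then-inflate within a service year
  amts <- stats::runif(10, 0, 1000)
  tab <- default_cpi_table()
  expect_equal(sum(inflate(amts, 2010, tab)), inflate(sum(amts), 2010, tab))
})

test_that("PPPM divides by person-months and summarises over patients", {
  s <- pppm(3043.75, 304.375)
  expect_equal(s$pppm, 304.375)        # ten 30.4375-day months
  s2 <- pppm(rep(100, 5), rep(365.25 / 12, 5))
  expect_equal(s2$sd, 0)
  expect_equal(s2$mean, 100)
  ## zero person-days excluded, not divided
  s3 <- pppm(c(100, 50), c(30.4375, 0))
  expect_equal(s3$n, 1L)
  expect_equal(s3$n_excluded, 1L)
  ## brute-force per-patient division
  set.seed(9)
  costs <- stats::runif(100, 0, 1e5); pd <- stats::runif(100, 1, 2000)
  expect_equal(pppm(costs, pd)$pppm, costs / (pd / (365.25 / 12)))
})

test_that("component costs attribute claims by setting with IP pro-ration", {
  cfg <- study_config()
  per <- period_person_days(mk_lines(), mk_cohort())[period == "3L+"]
  ## an IP stay half inside the period is half attributed
  md <- mk_medical("A", -10, end = 9, setting = "inpatient", dx = "C92.10",
                   paid = 1000)
  b <- claims_bundle(empty_pharmacy(), md, mk_enrollment("A", -400, 400),
                     mk_patient("A"))
  cc <- component_costs(b, per, cfg, "all")
  infl <- inflate(1000, 2012, cfg$cpi_table)  # stay starts in 2012
  expect_equal(cc$ip, infl / 2)
  expect_equal(cc$total, cc$pharmacy + cc$ip + cc$op + cc$ed)
  ## by_start attribution assigns the whole stay to the period containing
  ## its admission date
  cfg2 <- study_config(ip_proration = "by_start")
  cc2 <- component_costs(b, per, cfg2, "all")
  expect_equal(cc2$ip, 0)   # admission started before the period
  ## omacetaxine pharmacy counts as all-cause but not CML-related pharmacy
  ph <- mk_pharmacy("A", 10, "omacetaxine", paid = 500)
  b3 <- claims_bundle(ph, mk_medical("A", 0, dx = "C92.10"),
                      mk_enrollment("A", -400, 400), mk_patient("A"))
  all3 <- component_costs(b3, per, cfg, "all")
  cml3 <- component_costs(b3, per, cfg, "cml")
  expect_gt(all3$pharmacy, 0)
  expect_equal(cml3$pharmacy, 0)
  ## random claims vs brute-force categorisation
  set.seed(13)
  st <- sample(0:290, 50, replace = TRUE)
  md4 <- mk_medical("A", st, setting = sample(c("outpatient", "emergency"), 50,
                                              replace = TRUE),
                    dx = "C92.10", paid = stats::runif(50, 10, 500))
  b4 <- claims_bundle(empty_pharmacy(), md4, mk_enrollment("A", -400, 400),
                      mk_patient("A"))
  cc4 <- component_costs(b4, per, cfg, "all")
  md4$infl <- inflate(md4$paid_amount, md4$service_year, cfg$cpi_table)
  expect_equal(cc4$op, sum(md4$infl[md4$setting == "outpatient"]))
  expect_equal(cc4$ed, sum(md4$infl[md4$setting == "emergency"]))
})

test_that("HSCT event cost sums the containing admission, with flagged fallback", {
  cfg <- study_config()
  md <- rbind(
    mk_medical("A", 50, end = 57, setting = "inpatient", dx = "C92.10",
               paid = 50000),
    mk_medical("A", 50, end = 57, setting = "inpatient", dx = "C92.10",
               paid = 60000),
    mk_medical("A", 52, end = 52, setting = "inpatient", dx = "C92.10",
               px = "38240", paid = 40000))
  b <- claims_bundle(empty_pharmacy(), md, mk_enrollment("A", -400, 400),
                     mk_patient("A"))
  hd <- data.table::data.table(patient_id = "A", hsct_date = dday(52))
  ev <- hsct_event_cost(b, hd, cfg)
  expect_false(ev$no_admission_flag)
  expect_equal(ev$event_cost,
               sum(inflate(c(50000, 60000, 40000), 2013, cfg$cpi_table)))
  expect_equal(ev$admission_start, dday(50))
  ## no containing admission: only the procedure claim, flagged
  md2 <- mk_medical("B", 52, px = "38240", paid = 40000)
  md2$setting <- "outpatient"
  b2 <- claims_bundle(empty_pharmacy(), md2, mk_enrollment("B", -400, 400),
                      mk_patient("B"))
  ev2 <- hsct_event_cost(b2, data.table::data.table(patient_id = "B",
                                                    hsct_date = dday(52)), cfg)
  expect_true(ev2$no_admission_flag)
  expect_equal(ev2$event_cost, inflate(40000, 2013, cfg$cpi_table))
})

test_that("the HSCT sensitivity analysis is a conservative no-op without HSCT and removes exactly the event claims", {
  cfg <- study_config()
  sim <- generate_cohort(trajectory_spec(
    n_patients = 120, seed = 61,
    line_count_probs = c(`1` = 0, `2` = 0, `3` = .7, `4` = .3, `5` = 0, `6` = 0),
    p_hsct_after_3L = 0.4))
  sel <- apply_selection(sim$bundle, cfg)
  per <- period_person_days(sel$lines[patient_id %in% sel$cohort$patient_id],
                            sel$cohort)
  hd <- sel$cohort[!is.na(hsct_date), .(patient_id, hsct_date)]
  expect_gt(nrow(hd), 0)
  main <- component_costs(sim$bundle, per[period == "3L+"], cfg, "all")
  sens_bundle <- sensitivity_exclude_hsct(sim$bundle, hd, cfg)
  sens <- component_costs(sens_bundle, per[period == "3L+"], cfg, "all")
  m <- merge(main, sens, by = c("patient_id", "period"), suffixes = c("", ".s"))
  ## removal can only decrease each patient's total
  expect_true(all(m$total.s <= m$total + 1e-9))
  ## conservation: the removed in-period amount equals the in-period share of
  ## the dropped claims, recomputed brute force
  dropped <- data.table::fsetdiff(
    sim$bundle$medical[, .(patient_id, start_date, end_date, setting,
                           paid_amount, service_year)],
    sens_bundle$medical[, .(patient_id, start_date, end_date, setting,
                            paid_amount, service_year)])
  dropped <- merge(dropped, per[period == "3L+",
                                .(patient_id, start, end)], by = "patient_id")
  dropped[, infl := inflate(paid_amount, service_year, cfg$cpi_table)]
  dropped[, frac := pmax(0, as.numeric(pmin(end_date + 1L, end) -
                                         pmax(start_date, start))) /
            (as.numeric(end_date - start_date) + 1)]
  expect_equal(sum(m$total) - sum(m$total.s), dropped[, sum(infl * frac)],
               tolerance = 1e-8)
  ## cohorts without HSCT: identical summaries
  hd0 <- hd[0]
  expect_identical(sensitivity_exclude_hsct(sim$bundle, hd0, cfg)$medical,
                   sim$bundle$medical)
})

test_that("component additivity holds for every patient, period and cause", {
  cfg <- study_config()
  sim <- generate_cohort(trajectory_spec(
    n_patients = 80, seed = 71,
    line_count_probs = c(`1` = 0, `2` = 0, `3` = .6, `4` = .4, `5` = 0, `6` = 0)))
  sel <- apply_selection(sim$bundle, cfg)
  per <- period_person_days(sel$lines[patient_id %in% sel$cohort$patient_id],
                            sel$cohort)
  for (cz in c("all", "cml")) {
    cc <- component_costs(sim$bundle, per[person_days > 0], cfg, cz)
    expect_true(all(abs(cc$total - (cc$pharmacy + cc$ip + cc$op + cc$ed)) <=
                      1e-6 * pmax(1, abs(cc$total))))
  }
  ## CML-related component totals never exceed all-cause
  a <- component_costs(sim$bundle, per[person_days > 0], cfg, "all")
  c_ <- component_costs(sim$bundle, per[person_days > 0], cfg, "cml")
  m <- merge(a, c_, by = c("patient_id", "period"), suffixes = c("", ".cml"))
  for (comp in c("pharmacy", "ip", "op", "ed", "total"))
    expect_true(all(m[[paste0(comp, ".cml")]] <= m[[comp]] + 1e-9))
})
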