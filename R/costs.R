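## Healthcare costs: component attribution, CPI inflation to target-year
## dollars, per-patient-per-month standardisation, HSCT event costing and the
## HSCT-exclusion sensitivity analysis. Payer perspective: paid_amount is the
## plan-paid amount.

#' Inflate an amount to target-year dollars
#'
#' Multiplies by the ratio of the target year's to the service year's
#' medical-care CPI index.
#'
#' @param amount Numeric amounts in service-year dollars.
#' @param service_year Calendar year(s) of service.
#' @param cpi_table data.table `year`, `index`.
#' @param target_year Target year (must be in the table, as must every
#'   service year).
#' @return Amounts in target-year dollars.
#' @export
inflate <- function(amount, service_year, cpi_table = default_cpi_table(),
                    target_year = 2019L) {
  idx <- stats::setNames(cpi_table$index, cpi_table$year)
  if (!as.character(target_year) %in% names(idx))
    stop("cpi_table has no entry for target year ", target_year)
  sy <- as.character(service_year)
  miss <- unique(sy[!sy %in% names(idx)])
  if (length(miss))
    stop("cpi_table has no entry for service year(s): ",
         paste(miss, collapse = ", "))
  amount * idx[[as.character(target_year)]] / unname(idx[sy])
}

#' Per-patient-per-month statistics
#'
#' Each patient's PPPM = total cost / (person_days / month length); the
#' summary is the mean, SD and median over patients. Patients with zero
#' person-days are excluded (and counted in `n_excluded`).
#'
#' @param costs Numeric per-patient totals (target-year dollars).
#' @param person_days Matching per-patient person-days.
#' @param month_length_days Days per month (default 365.25/12).
#' @return list `pppm` (per-patient vector), `mean`, `sd`, `median`, `n`,
#'   `n_excluded`.
#' @export
pppm <- function(costs, person_days, month_length_days = 365.25 / 12) {
  stopifnot(length(costs) == length(person_days))
  keep <- person_days > 0
  v <- costs[keep] / (person_days[keep] / month_length_days)
  list(pppm = v, mean = mean(v), sd = stats::sd(v),
       median = stats::median(v), n = sum(keep), n_excluded = sum(!keep))
}

## claim-level cost attribution for one period table. Returns long data.table
## patient_id, period, component (pharmacy/ip/op/ed), amount (target-year
## dollars). IP paid amounts are pro-rated by the fraction of stay days
## inside the period (config$ip_proration = "by_days"), or attributed wholly
## to the period containing the admission start ("by_start"); pharmacy fills
## attach wholly to their fill date.
component_costs_long <- function(bundle, periods, config, cause = "all") {
  per <- as.data.table(periods)[person_days > 0]
  if (!nrow(per))
    return(data.table(patient_id = character(), period = character(),
                      component = character(), amount = numeric()))
  cpi <- config$cpi_table; ty <- config$target_cost_year
  ph <- as.data.table(bundle$pharmacy)[patient_id %in% unique(per$patient_id)]
  md <- as.data.table(bundle$medical)[patient_id %in% unique(per$patient_id)]
  if (cause == "cml") {
    md <- md[codes_match(diagnosis_codes, config$codes$cml_dx) |
               codes_match(procedure_codes, config$codes$omacetaxine_procedure)]
    ## CML-related pharmacy: prescriptions filled for a TKI
    ph <- ph[drug %in% c("imatinib", "dasatinib", "nilotinib", "bosutinib",
                         "ponatinib")]
  }
  ## only claims that can intersect an analysis window need inflating
  hull_lo <- min(per$start); hull_hi <- max(per$end)
  ph <- ph[fill_date >= hull_lo & fill_date < hull_hi]
  md <- md[end_date >= hull_lo & start_date < hull_hi]
  ph[, amount_2019 := inflate(paid_amount, service_year, cpi, ty)]
  md[, amount_2019 := inflate(paid_amount, service_year, cpi, ty)]
  setkey(ph, patient_id); setkey(md, patient_id)

  out <- per[, {
    w_s <- start; w_e <- end
    p <- ph[.BY$patient_id, nomatch = NULL]
    m <- md[.BY$patient_id, nomatch = NULL]
    pharm <- sum(p[fill_date >= w_s & fill_date < w_e, amount_2019])
    ip <- m[setting == "inpatient"]
    if (nrow(ip)) {
      if (identical(config$ip_proration, "by_start")) {
        ip_amt <- sum(ip[start_date >= w_s & start_date < w_e, amount_2019])
      } else {
        stay_len <- as.numeric(ip$end_date - ip$start_date) + 1
        frac <- days_inside(ip$start_date, ip$end_date, w_s, w_e) / stay_len
        ip_amt <- sum(ip$amount_2019 * frac)
      }
    } else ip_amt <- 0
    op <- sum(m[setting == "outpatient" & start_date >= w_s & start_date < w_e,
                amount_2019])
    ed <- sum(m[setting == "emergency" & start_date >= w_s & start_date < w_e,
                amount_2019])
    data.table(component = c("pharmacy", "ip", "op", "ed"),
               amount = c(pharm, ip_amt, op, ed))
  }, by = .(patient_id, period)]
  out[]
}

#' Per-patient component costs within analysis periods
#'
#' @param bundle A [claims_bundle()].
#' @param periods Period table from [period_person_days()].
#' @param config A [study_config()].
#' @param cause `"all"` or `"cml"` (CML-related medical claims carry a CML
#'   diagnosis or omacetaxine procedure code; CML-related pharmacy is
#'   restricted to the five TKIs).
#' @return data.table `patient_id`, `period`, `pharmacy`, `ip`, `op`, `ed`,
#'   `total` in target-year dollars.
#' @export
component_costs <- function(bundle, periods, config = study_config(),
                            cause = c("all", "cml")) {
  cause <- match.arg(cause)
  long <- component_costs_long(bundle, periods, config, cause)
  if (!nrow(long))
    return(data.table(patient_id = character(), period = character(),
                      pharmacy = numeric(), ip = numeric(), op = numeric(),
                      ed = numeric(), total = numeric()))
  wide <- dcast(long, patient_id + period ~ component, value.var = "amount",
                fill = 0)
  for (cl in c("pharmacy", "ip", "op", "ed"))
    if (!cl %in% names(wide)) wide[, (cl) := 0]
  wide[, total := pharmacy + ip + op + ed]
  wide[]
}

#' HSCT event-level cost
#'
#' The cost of an HSCT event is the inflated sum of the paid amounts of all
#' inpatient claims belonging to the (merged) admission whose span contains
#' the procedure date. When no admission contains the date, the inflated
#' amount of the procedure-bearing claim alone is used and the event is
#' flagged.
#'
#' @param bundle A [claims_bundle()].
#' @param hsct_dates data.table `patient_id`, `hsct_date`.
#' @param config A [study_config()].
#' @return data.table `patient_id`, `hsct_date`, `admission_start`,
#'   `admission_end`, `event_cost` (target-year dollars),
#'   `no_admission_flag`.
#' @export
hsct_event_cost <- function(bundle, hsct_dates, config = study_config()) {
  hd <- as.data.table(hsct_dates)
  md <- copy(as.data.table(bundle$medical))
  md[, amount_2019 := inflate(paid_amount, service_year, config$cpi_table,
                              config$target_cost_year)]
  out <- hd[, {
    m <- md[patient_id == .BY$patient_id]
    ip <- m[setting == "inpatient"]
    adm <- merge_admissions(cbind(data.table(patient_id = .BY$patient_id),
                                  ip[, .(start_date, end_date)]))
    win <- adm[start_date <= hsct_date & end_date >= hsct_date]
    if (nrow(win)) {
      inwin <- ip[start_date <= win$end_date[1L] & end_date >= win$start_date[1L]]
      data.table(admission_start = win$start_date[1L],
                 admission_end = win$end_date[1L],
                 event_cost = sum(inwin$amount_2019),
                 no_admission_flag = FALSE)
    } else {
      pc <- m[codes_match(procedure_codes, config$codes$hsct_procedures) &
                start_date == hsct_date]
      data.table(admission_start = as.Date(NA), admission_end = as.Date(NA),
                 event_cost = sum(pc$amount_2019),
                 no_admission_flag = TRUE)
    }
  }, by = .(patient_id, hsct_date)]
  out[]
}

#' Remove HSCT-attributed claims (sensitivity analysis)
#'
#' Drops all inpatient claims belonging to admissions containing an HSCT
#' procedure date (or, failing an admission, the procedure claim itself) so
#' that all cost summaries can be recomputed without HSCT costs.
#'
#' @param bundle A [claims_bundle()].
#' @param hsct_dates data.table `patient_id`, `hsct_date`.
#' @param config A [study_config()].
#' @return A `claims_bundle` without the HSCT-attributed medical claims.
#' @export
sensitivity_exclude_hsct <- function(bundle, hsct_dates,
                                     config = study_config()) {
  hd <- as.data.table(hsct_dates)
  if (!nrow(hd)) return(bundle)
  md <- copy(as.data.table(bundle$medical))
  md[, .rowid := .I]
  drop <- integer()
  for (i in seq_len(nrow(hd))) {
    pid <- hd$patient_id[i]; dte <- hd$hsct_date[i]
    ip <- md[patient_id == pid & setting == "inpatient"]
    adm <- merge_admissions(ip[, .(patient_id, start_date, end_date)])
    win <- adm[start_date <= dte & end_date >= dte]
    if (nrow(win)) {
      drop <- c(drop, ip[start_date <= win$end_date[1L] &
                           end_date >= win$start_date[1L], .rowid])
    } else {
      drop <- c(drop, md[patient_id == pid & start_date == dte &
                           codes_match(procedure_codes,
                                       config$codes$hsct_procedures), .rowid])
    }
  }
  md2 <- md[!.rowid %in% drop][, .rowid := NULL]
  out <- bundle
  out$medical <- md2[]
  out
}

#' Cost summary over periods and causes
#'
#' PPPM mean/SD/median for total, pharmacy, medical and the medical
#' sub-components, per period and cause.
#'
#' @param bundle A [claims_bundle()].
#' @param periods Period table from [period_person_days()].
#' @param config A [study_config()].
#' @return data.table `period`, `cause`, `component`, `mean`, `sd`,
#'   `median`, `n` (all PPPM, target-year dollars).
#' @export
summarize_costs <- function(bundle, periods, config = study_config()) {
  per <- as.data.table(periods)[person_days > 0]
  res <- lapply(c("all", "cml"), function(cz) {
    cc <- component_costs(bundle, per, config, cz)
    cc <- merge(cc, per[, .(patient_id, period, person_days)],
                by = c("patient_id", "period"))
    cc[, medical := ip + op + ed]
    melt(cc, id.vars = c("patient_id", "period", "person_days"),
         measure.vars = c("total", "pharmacy", "medical", "ip", "op", "ed"),
         variable.name = "component", value.name = "amount"
    )[, {
      s <- pppm(amount, person_days, config$month_length_days)
      data.table(cause = cz, mean = s$mean, sd = s$sd, median = s$median,
                 n = s$n)
    }, by = .(period, component)]
  })
  out <- rbindlist(res)
  setcolorder(out, c("period", "cause", "component"))
  out[]
}
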