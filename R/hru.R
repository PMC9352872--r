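## Healthcare resource utilization over the 3L+, 3L and 4L analysis periods.
##
## Periods are half-open in days, [start, end): person-days = end - start.
## Inpatient stays are closed intervals [start_date, end_date]; overlapping
## stays are merged into single admissions before counting. Annual incidence
## rates are cohort aggregates: total events / total person-days x 365.25.

#' Per-patient analysis periods
#'
#' `3L+` runs over the whole follow-up window; `3L` (`4L`) from the line's
#' start to the earlier of the line's end and the follow-up end. Windows are
#' clipped to follow-up; patients without the line get zero person-days and
#' drop out of that period's denominators.
#'
#' @param lines Constructed lines for the cohort.
#' @param cohort Cohort table from [apply_selection()] (needs `patient_id`,
#'   `fu_start`, `fu_end`).
#' @return data.table `patient_id`, `period` (`"3L+"`, `"3L"`, `"4L"`),
#'   `start`, `end`, `person_days`.
#' @export
period_person_days <- function(lines, cohort) {
  co <- as.data.table(cohort)
  ln <- as.data.table(lines)[patient_id %in% co$patient_id]
  all3 <- co[, .(patient_id, period = "3L+", start = fu_start, end = fu_end)]
  one <- function(k, lab) {
    lk <- ln[line_number == k, .(patient_id, line_start = start_date,
                                 line_end = end_date)]
    m <- merge(co[, .(patient_id, fu_start, fu_end)], lk, by = "patient_id")
    m[, .(patient_id, period = lab,
          start = pmax(line_start, fu_start),
          end = pmin(line_end, fu_end))][end >= start]
  }
  out <- rbind(all3, one(3L, "3L"), one(4L, "4L"))
  out[, person_days := as.numeric(end - start)]
  out[]
}

## merge overlapping/abutting IP claims into admissions (per patient)
merge_admissions <- function(ip) {
  if (!nrow(ip)) {
    return(data.table(patient_id = character(),
                      start_date = as.Date(character()),
                      end_date = as.Date(character())))
  }
  merge_enrollment(ip[, .(patient_id, start_date, end_date)], 0L)
}

## number of days of [s, e] (closed) falling inside [ws, we) (half-open)
days_inside <- function(s, e, ws, we) {
  pmax(0, as.numeric(pmin(e + 1L, we) - pmax(s, ws)))
}

#' Count HRU measures within an analysis period
#'
#' IP admissions = merged inpatient stays intersecting the period; IP days =
#' stay days clipped to the period; OP days / ED visits = distinct calendar
#' dates with at least one claim of that setting in the period. The
#' CML-related filter keeps medical claims bearing a CML diagnosis code or an
#' omacetaxine procedure code.
#'
#' @param medical Medical claims.
#' @param periods Period table from [period_person_days()].
#' @param config A [study_config()].
#' @param cause `"all"` or `"cml"`.
#' @return data.table `patient_id`, `period`, `measure` (`ip_admissions`,
#'   `ip_days`, `op_days`, `ed_visits`), `count`.
#' @export
count_hru <- function(medical, periods, config = study_config(),
                      cause = c("all", "cml")) {
  cause <- match.arg(cause)
  md <- as.data.table(medical)[patient_id %in% unique(periods$patient_id)]
  is_cml <- codes_match(md$diagnosis_codes, config$codes$cml_dx) |
    codes_match(md$procedure_codes, config$codes$omacetaxine_procedure)
  ## admissions are merged over ALL inpatient claims and an admission is
  ## CML-related when any constituent claim is; this keeps CML-related
  ## admission/day counts a subset of the all-cause counts even when CML and
  ## non-CML claims chain into one stay
  mdo <- if (cause == "cml") md[is_cml] else md  # outpatient/ED filter
  md[, cml_related := is_cml]
  setkey(md, patient_id); setkey(mdo, patient_id)
  per <- as.data.table(periods)
  out <- per[, {
    w_s <- start; w_e <- end
    mm <- md[.(.BY$patient_id), nomatch = NULL]
    ip_cl <- mm[setting == "inpatient"]
    ip <- merge_admissions(ip_cl)
    if (nrow(ip) && cause == "cml") {
      flag <- vapply(seq_len(nrow(ip)), function(j)
        any(ip_cl$cml_related & ip_cl$start_date <= ip$end_date[j] &
              ip_cl$end_date >= ip$start_date[j]), logical(1))
      ip <- ip[flag]
    }
    ipd <- days_inside(ip$start_date, ip$end_date, w_s, w_e)
    mo <- mdo[.(.BY$patient_id), nomatch = NULL]
    op <- mo[setting == "outpatient" & start_date >= w_s & start_date < w_e]
    ed <- mo[setting == "emergency" & start_date >= w_s & start_date < w_e]
    data.table(measure = c("ip_admissions", "ip_days", "op_days", "ed_visits"),
               count = c(sum(ipd > 0), sum(ipd),
                         uniqueN(op$start_date), uniqueN(ed$start_date)))
  }, by = .(patient_id, period)]
  out[]
}

#' Annual incidence rate
#'
#' @param count Total event count.
#' @param person_days Total person-days at risk.
#' @param year_length_days Days per year (default 365.25).
#' @return events per person-year; `NA` when `person_days` is 0 (undefined,
#'   not zero).
#' @export
annual_rate <- function(count, person_days, year_length_days = 365.25) {
  ifelse(person_days > 0, count / person_days * year_length_days, NA_real_)
}

#' HRU summary over all periods and causes
#'
#' @param medical Medical claims.
#' @param periods Period table from [period_person_days()].
#' @param config A [study_config()].
#' @return data.table `period`, `cause`, `measure`, `n_patients`,
#'   `person_days`, `count`, `rate` (annual incidence rate, cohort
#'   aggregate).
#' @export
summarize_hru <- function(medical, periods, config = study_config()) {
  per <- as.data.table(periods)[person_days > 0]
  res <- lapply(c("all", "cml"), function(cz) {
    cnt <- count_hru(medical, per, config, cz)
    tot <- merge(cnt, per[, .(patient_id, period, person_days)],
                 by = c("patient_id", "period"))
    s <- tot[, .(n_patients = uniqueN(patient_id),
                 person_days = sum(person_days[!duplicated(patient_id)]),
                 count = sum(count)), keyby = .(period, measure)]
    s[, cause := cz]
    s
  })
  out <- rbindlist(res)
  out[, rate := annual_rate(count, person_days, config$year_length_days)]
  setcolorder(out, c("period", "cause", "measure"))
  out[]
}
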