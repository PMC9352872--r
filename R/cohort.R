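## Cohort selection: the patient-selection cascade that yields the 3L+
## analytic sample, plus index/baseline/follow-up window definitions.
##
## Cascade (fixed order):
##  1. >= 1 CML diagnosis (payer-appropriate code list) within the data window
##  2. adult (>= 18) at 1L initiation
##  3. 1L drug is imatinib/dasatinib/nilotinib/bosutinib on/after approval
##  4. 1L initiation within the window around first CML diagnosis
##     (-30 days to +91 days commercial / +365 days Medicare)
##  5. washout: continuous enrollment and no CML-CP therapy in the 183 days
##     before 1L (hydroxyurea is pretreatment, not therapy)
##  6. continuous enrollment from washout start through first diagnosis +
##     365 days (Medicare: waived when the patient dies in that window)
##  7. no HMO-flagged coverage during that interval (Medicare only)
##  8. no CML remission/relapse code on/before 1L start
##  9. no clinical-trial claim on/before the index date (3L start)
## 10. reached a third line of therapy

#' Date of first CML diagnosis
#'
#' Earliest medical-claim service start bearing any configured CML diagnosis
#' code (prefix match).
#'
#' @param medical Medical claims for one or more patients.
#' @param cml_dx Character vector of code stems.
#' @return data.table `patient_id`, `first_cml_dx_date` (patients without a
#'   qualifying claim are absent).
#' @export
first_cml_diagnosis <- function(medical, cml_dx) {
  stopifnot(length(cml_dx) > 0L)
  md <- as.data.table(medical)
  hit <- md[codes_match(diagnosis_codes, cml_dx)]
  if (!nrow(hit))
    return(data.table(patient_id = character(),
                      first_cml_dx_date = as.Date(character())))
  hit[, .(first_cml_dx_date = min(start_date)), keyby = patient_id]
}

#' Washout check
#'
#' TRUE iff enrollment continuously covers `[line1_start - washout_days,
#' line1_start)` and no CML-CP therapy claim (the six line-defining drugs;
#' hydroxyurea does not count) falls in that window.
#'
#' @param therapy_dates Dates of the patient's CML-CP therapy events (from
#'   [collect_therapy_events()], any kind `therapy_fill`).
#' @param line1_start 1L initiation date.
#' @param enrollment The patient's (merged) enrollment spans.
#' @param washout_days Window length (default 183).
#' @return logical scalar.
#' @export
check_washout <- function(therapy_dates, line1_start, enrollment,
                          washout_days = 183L) {
  w0 <- line1_start - washout_days
  if (any(therapy_dates >= w0 & therapy_dates < line1_start)) return(FALSE)
  covers_interval(enrollment, w0, line1_start - 1L)
}

## closed-interval coverage of [from, to] by merged spans
covers_interval <- function(spans, from, to) {
  sp <- merge_enrollment(as.data.table(spans)[, .(start_date, end_date)])
  if (!nrow(sp)) return(FALSE)
  any(sp$start_date <= from & sp$end_date >= to)
}

#' Follow-up window
#'
#' The follow-up period runs from 3L initiation (the index date) to the
#' earliest of end of data availability, end of continuous enrollment, HSCT,
#' or initiation of a chemotherapy not listed for CML-CP.
#'
#' @param index_date 3L start.
#' @param enrollment_end,data_end,hsct_date,apbc_date Candidate end dates
#'   (the last two may be `NA`).
#' @return Named list `start`, `end` (a zero-length window is allowed).
#' @export
define_follow_up <- function(index_date, enrollment_end, data_end,
                             hsct_date = as.Date(NA), apbc_date = as.Date(NA)) {
  end <- min(c(enrollment_end, data_end, hsct_date, apbc_date), na.rm = TRUE)
  if (end < index_date)
    stop("define_follow_up: follow-up end precedes the index date")
  list(start = index_date, end = end)
}

## Per-patient selection features used by the cascade; lines are constructed
## internally because criteria 2-10 are defined relative to 1L/3L.
cohort_features <- function(bundle, config) {
  events <- collect_therapy_events(bundle, config)
  enr <- merge_enrollment(bundle$enrollment,
                          config$enrollment_merge_gap_days)
  pts <- copy(bundle$patients)

  dx <- first_cml_diagnosis(bundle$medical, config$codes$cml_dx_eligibility)
  dx <- dx[first_cml_dx_date >= config$data_start &
             first_cml_dx_date <= config$data_end]
  ## imatinib approval anchors the observable era for commercial claims
  if (config$payer == "commercial")
    dx <- dx[first_cml_dx_date >= as.Date("2001-05-10")]

  ## observation end: end of the enrollment span covering 1L (fallback: last
  ## span end), capped at end of data
  feat <- pts[, .(patient_id, birth_year, death_date)]
  feat <- merge(feat, dx, by = "patient_id", all.x = TRUE)

  first_fill <- events[kind == "therapy_fill",
                       .(line1_start = min(date)), keyby = patient_id]
  feat <- merge(feat, first_fill, by = "patient_id", all.x = TRUE)

  enr_end <- enr[, .(enroll_end = max(end_date), enroll_start = min(start_date)),
                 keyby = patient_id]
  feat <- merge(feat, enr_end, by = "patient_id", all.x = TRUE)
  feat[, obs_end := pmin(enroll_end, config$data_end)]

  lines <- build_lines(events,
                       stats::setNames(feat$obs_end, feat$patient_id)[unique(events$patient_id)],
                       config$gap_days)
  list(events = events, enrollment = enr, lines = lines, features = feat)
}

#' Apply the patient-selection cascade
#'
#' Runs the ten-step cascade documented above and returns the attrition
#' table together with the 3L+ analytic cohort and its per-patient index
#' dates and windows.
#'
#' @param bundle A [claims_bundle()].
#' @param config A [study_config()].
#' @return list with elements
#'   * `attrition`: data.table `criterion`, `n_remaining`, `n_excluded`
#'     (first row is the input count);
#'   * `cohort`: data.table of survivors with `patient_id`,
#'     `first_cml_dx_date`, `line1_start`, `index_date`, baseline window,
#'     follow-up window and `obs_end`;
#'   * `lines`: constructed lines for all input patients;
#'   * `events`: the therapy-event stream.
#' @export
apply_selection <- function(bundle, config = study_config()) {
  cf <- cohort_features(bundle, config)
  feat <- cf$features
  lines <- cf$lines
  enr <- cf$enrollment

  steps <- list()
  note <- function(lbl, ids) steps[[length(steps) + 1L]] <<- list(lbl, ids)

  ids <- feat$patient_id
  note("Patients in input data", ids)

  f <- feat[patient_id %in% ids]
  ids <- f[!is.na(first_cml_dx_date), patient_id]
  note("≥ 1 CML diagnosis in data window", ids)

  f <- feat[patient_id %in% ids][!is.na(line1_start)]
  ids <- f[as.integer(format(line1_start, "%Y")) - birth_year >= 18, patient_id]
  note("Adult (≥ 18 years) at 1L initiation", ids)

  l1 <- lines[line_number == 1L]
  ok_drug <- l1[drug %in% FIRST_LINE_DRUGS, patient_id]
  ids <- intersect(ids, ok_drug)
  note("1L therapy is an approved CML-CP TKI (imatinib/dasatinib/nilotinib/bosutinib)", ids)

  f <- feat[patient_id %in% ids]
  ids <- f[line1_start >= first_cml_dx_date - config$dx_to_1L_before_days &
             line1_start <= first_cml_dx_date + config$dx_to_1L_after_days,
           patient_id]
  note(sprintf("1L initiation within -%d/+%d days of first CML diagnosis",
               config$dx_to_1L_before_days, config$dx_to_1L_after_days), ids)

  ## coverage helper: patients (rows of `win`: patient_id, from, upto) whose
  ## merged enrollment has a span containing [from, upto]
  covered_ids <- function(win) {
    if (!nrow(win)) return(character())
    m <- merge(win, enr, by = "patient_id", allow.cartesian = TRUE)
    unique(m[start_date <= from & end_date >= upto, patient_id])
  }
  f <- feat[patient_id %in% ids]
  ## no CML-CP therapy claim in the washout window
  ft <- cf$events[kind == "therapy_fill" & patient_id %in% ids,
                  .(patient_id, date)]
  viol <- merge(ft, f[, .(patient_id, line1_start)],
                by = "patient_id")[date >= line1_start - config$washout_days &
                                     date < line1_start, unique(patient_id)]
  win <- f[, .(patient_id, from = line1_start - config$washout_days,
               upto = line1_start - 1L)]
  ids <- setdiff(intersect(ids, covered_ids(win)), viol)
  note(sprintf("Washout: %d clean pre-1L days with continuous enrollment",
               config$washout_days), ids)

  f <- feat[patient_id %in% ids]
  win <- f[, .(patient_id, from = line1_start - config$washout_days,
               upto = first_cml_dx_date + config$post_dx_enrollment_days,
               death_date)]
  if (config$payer == "medicare")
    win[!is.na(death_date) & death_date <= upto,
        upto := death_date]   # death waiver for the 12-month requirement
  ids <- intersect(ids, covered_ids(win[, .(patient_id, from, upto)]))
  note("Continuous enrollment from washout through 12 months post-diagnosis", ids)

  if (config$payer == "medicare") {
    hmo <- as.data.table(bundle$enrollment)[hmo_flag == TRUE]
    f <- feat[patient_id %in% ids]
    win <- f[, .(patient_id, from = line1_start - config$washout_days,
                 upto = pmin(obs_end,
                             first_cml_dx_date + config$post_dx_enrollment_days))]
    bad <- if (nrow(hmo)) {
      m <- merge(win, hmo, by = "patient_id", allow.cartesian = TRUE)
      unique(m[start_date <= upto & end_date >= from, patient_id])
    } else character()
    ids <- setdiff(ids, bad)
    note("No HMO (Part C) coverage during continuous enrollment", ids)
  }

  md <- bundle$medical
  remrel <- md[codes_match(diagnosis_codes,
                           c(config$codes$cml_remission, config$codes$cml_relapse)),
               .(patient_id, start_date)]
  f <- feat[patient_id %in% ids]
  bad <- unique(merge(remrel, f[, .(patient_id, line1_start)],
                      by = "patient_id")[start_date <= line1_start, patient_id])
  ids <- setdiff(ids, bad)
  note("No CML remission/relapse code on/before 1L initiation", ids)

  idx <- lines[line_number == 3L, .(patient_id, index_date = start_date)]
  trial <- md[codes_match(diagnosis_codes, config$codes$clinical_trial),
              .(patient_id, start_date)]
  bad <- unique(merge(trial, idx, by = "patient_id")[start_date <= index_date,
                                                     patient_id])
  ids <- setdiff(ids, bad)
  note("No clinical-trial claim on/before the index date", ids)

  ids <- intersect(ids, idx$patient_id)
  note("Initiated a third line of therapy (3L+)", ids)

  attrition <- data.table(
    criterion = vapply(steps, `[[`, character(1), 1L),
    n_remaining = vapply(steps, function(s) length(s[[2]]), integer(1)))
  attrition[, n_excluded := c(0L, -diff(n_remaining))]

  cohort <- feat[patient_id %in% ids,
                 .(patient_id, first_cml_dx_date, line1_start, obs_end,
                   birth_year, death_date)]
  cohort <- merge(cohort, idx, by = "patient_id")
  pl <- lines[patient_id %in% ids]
  term <- pl[end_event %in% c("hsct", "apbc_chemo"),
             .(patient_id, end_event, term_date = end_date)]
  if (nrow(term)) {
    cohort <- merge(cohort,
                    dcast(term, patient_id ~ end_event, value.var = "term_date"),
                    by = "patient_id", all.x = TRUE)
  }
  for (cl in c("hsct", "apbc_chemo"))
    if (!cl %in% names(cohort)) cohort[, (cl) := as.Date(NA)]
  cohort[, fu_start := index_date]
  cohort[, fu_end := pmin(obs_end, config$data_end,
                          fifelse(is.na(hsct), as.Date("9999-12-31"), hsct),
                          fifelse(is.na(apbc_chemo), as.Date("9999-12-31"),
                                  apbc_chemo))]
  cohort[, `:=`(baseline_start = index_date - config$baseline_days,
                baseline_end = index_date - 1L,
                age_at_index = as.integer(format(index_date, "%Y")) - birth_year)]
  setnames(cohort, c("hsct", "apbc_chemo"), c("hsct_date", "apbc_date"))
  list(attrition = attrition[], cohort = cohort[], lines = lines,
       events = cf$events)
}
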