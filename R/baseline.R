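## Baseline (pre-index) patient characteristics: modified Charlson
## comorbidity index excluding CML, a configurable CML-severity classifier,
## comorbidity flags, hydroxyurea pretreatment and HSCT-unfitness. All
## measures use only claims dated in [index - 183 days, index - 1 day].

## distinct diagnosis codes observed for a patient in a window
baseline_codes <- function(medical, patient, from, to) {
  md <- as.data.table(medical)
  cc <- md[patient_id == patient & start_date >= from & start_date <= to,
           diagnosis_codes]
  cc <- cc[!is.na(cc) & nzchar(cc)]
  unique(unlist(strsplit(cc, ";", fixed = TRUE)))
}

#' Modified Charlson comorbidity index (CML excluded)
#'
#' Sums condition weights over distinct conditions with at least one
#' qualifying baseline code. Hierarchy rules declared in the map (a
#' condition's `supersedes` entry) drop the milder form when the severe form
#' is present. The default map carries the original 17-condition weights
#' with CML excluded from the malignancy code list.
#'
#' @param dx_codes Character vector of diagnosis codes observed at baseline.
#' @param cci_map Condition map: named list of `list(weight, codes,
#'   supersedes?)`; see `default_cci_map()`.
#' @return Integer score.
#' @export
modified_cci <- function(dx_codes, cci_map = default_cci_map()) {
  if (!length(dx_codes)) return(0L)
  present <- vapply(cci_map, function(cond) {
    any(vapply(cond$codes, function(s) any(startsWith(dx_codes, s)),
               logical(1)))
  }, logical(1))
  for (nm in names(cci_map)) {
    sup <- cci_map[[nm]]$supersedes
    if (!is.null(sup) && present[[nm]] && sup %in% names(present))
      present[[sup]] <- FALSE
  }
  sum(vapply(cci_map[present], function(cond) as.integer(cond$weight),
             integer(1)))
}

#' Claims-based CML severity class
#'
#' Highest severity tier with at least one qualifying baseline code; `mild`
#' when none qualifies. Tier code lists are user-configured; the bundled
#' defaults are illustrative, not the published disease-complexity lists.
#'
#' @param codes Diagnosis/procedure codes observed at baseline.
#' @param severity_map list with elements `moderate` and `severe` (code
#'   stems).
#' @return `"mild"`, `"moderate"` or `"severe"`.
#' @export
darkow_severity <- function(codes, severity_map = default_severity_map()) {
  hit <- function(stems) length(codes) &&
    any(vapply(stems, function(s) any(startsWith(codes, s)), logical(1)))
  if (hit(severity_map$severe)) "severe"
  else if (hit(severity_map$moderate)) "moderate"
  else "mild"
}

#' HSCT-unfitness flag
#'
#' TRUE iff age at index is at least 75 years, or the patient has congestive
#' heart failure, cirrhosis, or end-stage renal disease at baseline.
#'
#' @param age_at_index Age in years at the index date.
#' @param comorbidity_flags Named logical vector including
#'   `congestive_heart_failure`, `cirrhosis`, `end_stage_renal_disease`.
#' @param unfit_age Age threshold (default 75).
#' @param unfit_conditions Names of disqualifying conditions.
#' @return logical scalar.
#' @export
hsct_unfit <- function(age_at_index, comorbidity_flags, unfit_age = 75L,
                       unfit_conditions = c("congestive_heart_failure",
                                            "cirrhosis",
                                            "end_stage_renal_disease")) {
  age_at_index >= unfit_age ||
    any(unlist(comorbidity_flags[unfit_conditions]), na.rm = TRUE)
}

#' Per-patient baseline profile
#'
#' @param bundle A [claims_bundle()].
#' @param cohort Cohort table from [apply_selection()] (needs `patient_id`,
#'   `index_date`, `baseline_start`, `baseline_end`, `age_at_index`).
#' @param config A [study_config()].
#' @return data.table with one row per patient: demographics, `cci_score`,
#'   `cci_category` (`0`, `1`, `2`, `3+`), `severity`, comorbidity flags,
#'   `hydroxyurea_pretreatment`, `hsct_unfit_flag`.
#' @export
baseline_profile <- function(bundle, cohort, config = study_config()) {
  co <- as.data.table(cohort)
  pts <- as.data.table(bundle$patients)
  ph <- as.data.table(bundle$pharmacy)
  out <- co[, {
    codes <- baseline_codes(bundle$medical, patient_id, baseline_start,
                            baseline_end)
    cci <- modified_cci(codes, config$cci_map)
    flags <- vapply(config$comorbidity_map, function(stems)
      length(codes) && any(vapply(stems, function(s)
        any(startsWith(codes, s)), logical(1))), logical(1))
    hu <- nrow(ph[patient_id == .BY$patient_id & drug == "hydroxyurea" &
                    fill_date <= baseline_end]) > 0
    c(list(cci_score = cci,
           cci_category = if (cci >= 3) "3+" else as.character(cci),
           severity = darkow_severity(codes, config$severity_map),
           hydroxyurea_pretreatment = hu,
           hsct_unfit_flag = hsct_unfit(age_at_index, as.list(flags),
                                        config$hsct_unfit_age,
                                        config$hsct_unfit_conditions)),
      as.list(flags))
  }, by = .(patient_id, index_date, age_at_index)]
  merge(pts[, .(patient_id, birth_year, sex, region, payer)], out,
        by = "patient_id")[]
}

#' Table-1-style baseline summary
#'
#' @param profile Output of [baseline_profile()].
#' @return Named list of data.tables: `continuous` (age, CCI) and
#'   `categorical` (counts and proportions).
#' @export
summarize_baseline <- function(profile) {
  pr <- as.data.table(profile)
  continuous <- rbind(
    pr[, .(variable = "age_at_index", mean = mean(age_at_index),
           sd = stats::sd(age_at_index),
           median = stats::median(as.numeric(age_at_index)))],
    pr[, .(variable = "cci_score", mean = mean(cci_score),
           sd = stats::sd(cci_score),
           median = stats::median(as.numeric(cci_score)))])
  cat_one <- function(var) {
    tb <- pr[, .(n = .N), keyby = c(var)]
    setnames(tb, var, "level")
    tb[, `:=`(variable = var, prop = n / sum(n))]
    tb
  }
  flags <- c("hsct_unfit_flag", "hydroxyurea_pretreatment",
             names(default_comorbidity_map()))
  flags <- intersect(flags, names(pr))
  flag_tb <- rbindlist(lapply(flags, function(fl)
    data.table(variable = fl, level = "TRUE", n = sum(pr[[fl]]),
               prop = mean(pr[[fl]]))))
  categorical <- rbind(
    cat_one("sex"), cat_one("cci_category"), cat_one("severity"),
    data.table(variable = "age_ge65", level = "TRUE",
               n = pr[, sum(age_at_index >= 65)],
               prop = pr[, mean(age_at_index >= 65)]),
    flag_tb, use.names = TRUE)
  setcolorder(categorical, c("variable", "level", "n", "prop"))
  list(continuous = continuous, categorical = categorical[])
}
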