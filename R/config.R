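## Study configuration: every threshold, window, code list, approval date and
## formatting rule used by the pipeline. All date windows are expressed in
## whole days (6 months = 183 d, 1 month = 30 d, 3 months = 91 d, 1 year =
## 365 d); the PPPM month is 365.25/12 = 30.4375 d.

CML_DRUGS <- c("imatinib", "dasatinib", "nilotinib", "bosutinib",
               "ponatinib", "omacetaxine")
FIRST_LINE_DRUGS <- c("imatinib", "dasatinib", "nilotinib", "bosutinib")

#' FDA approval dates for CML-CP therapies
#'
#' Initial (resistant/intolerant) and, where applicable, newly-diagnosed
#' approval dates for the six CML-CP drugs whose claims define lines of
#' therapy. Line construction conditions therapy claims on the earliest
#' applicable date.
#'
#' @return A `data.table` with columns `drug`, `resistant_intolerant_date`,
#'   `newly_diagnosed_date`.
#' @export
default_approval_dates <- function() {
  data.table(
    drug = c("imatinib", "dasatinib", "nilotinib", "bosutinib",
             "ponatinib", "omacetaxine"),
    resistant_intolerant_date = as.Date(c(
      "2001-05-10", "2006-06-28", "2007-10-29", "2012-09-04",
      "2012-12-14", "2012-10-26")),
    newly_diagnosed_date = as.Date(c(
      "2001-05-10", "2010-10-28", "2010-06-17", "2017-12-19", NA, NA))
  )
}

#' Annual medical-care CPI reference table
#'
#' Medical-care component of the US consumer price index (CPI-U, annual
#' averages), used to inflate paid amounts to target-year dollars. Values are
#' bundled for convenience and fully user-replaceable via
#' [study_config()]`$cpi_table`.
#'
#' @return A `data.table` with columns `year`, `index`.
#' @export
default_cpi_table <- function() {
  data.table(
    year = 2001:2019,
    index = c(272.8, 285.6, 297.1, 310.1, 323.2, 336.2, 351.1, 364.1,
              375.6, 388.4, 400.3, 414.9, 425.1, 435.3, 446.8, 463.7,
              475.3, 484.7, 498.4)
  )
}

#' Default drug-code map
#'
#' Maps raw claim drug codes to canonical drug tokens. The bundled map uses
#' the canonical names themselves plus a few synthetic NDC-style aliases used
#' by the claims generator; real deployments supply their own map.
#' @return Named character vector: raw code -> canonical token.
#' @export
default_drug_map <- function() {
  m <- c(
    stats::setNames(CML_DRUGS, CML_DRUGS),
    hydroxyurea = "hydroxyurea",
    NDC00078 = "imatinib", NDC00003 = "dasatinib", NDC00781 = "nilotinib",
    NDC00069 = "bosutinib", NDC57902 = "ponatinib", NDC76388 = "omacetaxine",
    NDC00054 = "hydroxyurea"
  )
  m
}

## Charlson comorbidity map, original weights, 17 conditions, with the
## malignancy category's code list written to exclude chronic myeloid
## leukemia (205.1x / C92.1x) so the score is the "modified CCI, excluding
## CML". Code lists are prefix stems (ICD-9 + ICD-10) and user-overridable.
default_cci_map <- function() {
  list(
    myocardial_infarction   = list(weight = 1, codes = c("410", "412", "I21", "I22", "I25.2")),
    congestive_heart_failure= list(weight = 1, codes = c("428", "I50")),
    peripheral_vascular     = list(weight = 1, codes = c("443.9", "441", "I73.9", "I71")),
    cerebrovascular         = list(weight = 1, codes = c("430", "431", "432", "433", "434", "435", "436", "437", "438", "I60", "I61", "I62", "I63", "G45")),
    dementia                = list(weight = 1, codes = c("290", "F00", "F01", "F02", "F03")),
    chronic_pulmonary       = list(weight = 1, codes = c("490", "491", "492", "493", "494", "495", "496", "J40", "J41", "J42", "J43", "J44", "J45", "J47")),
    rheumatologic           = list(weight = 1, codes = c("710.0", "710.1", "714.0", "M05", "M06", "M32", "M34")),
    peptic_ulcer            = list(weight = 1, codes = c("531", "532", "533", "534", "K25", "K26", "K27", "K28")),
    mild_liver              = list(weight = 1, codes = c("571.2", "571.5", "571.6", "B18", "K73", "K74")),
    diabetes                = list(weight = 1, codes = c("250.0", "250.1", "250.2", "250.3", "E10.9", "E11.9")),
    diabetes_complicated    = list(weight = 2, codes = c("250.4", "250.5", "250.6", "E10.2", "E11.2", "E11.3", "E11.4"),
                                   supersedes = "diabetes"),
    hemiplegia              = list(weight = 2, codes = c("342", "344.1", "G81", "G82")),
    renal                   = list(weight = 2, codes = c("582", "583", "585", "586", "N18", "N19", "N03")),
    malignancy_excl_cml     = list(weight = 2, codes = c("153", "162", "174", "185", "200", "201", "202", "204", "205.0",
                                                         "C18", "C34", "C50", "C61", "C81", "C82", "C83", "C85", "C91", "C92.0")),
    severe_liver            = list(weight = 3, codes = c("572.2", "572.3", "572.4", "K72", "K76.6", "K76.7"),
                                   supersedes = "mild_liver"),
    metastatic_solid_tumor  = list(weight = 6, codes = c("196", "197", "198", "199", "C77", "C78", "C79", "C80"),
                                   supersedes = "malignancy_excl_cml"),
    hiv                     = list(weight = 6, codes = c("042", "043", "044", "B20", "B21", "B22", "B24"))
  )
}

## Comorbidity flags reported at baseline (Table-1 style) plus the conditions
## entering the HSCT-unfitness rule.
default_comorbidity_map <- function() {
  list(
    cardiac_arrhythmias      = c("427", "I47", "I48", "I49"),
    chronic_pulmonary_disease= c("491", "492", "493", "494", "496", "J41", "J42", "J43", "J44", "J45", "J47"),
    congestive_heart_failure = c("428", "I50"),
    diabetes                 = c("250", "E10", "E11"),
    hypertension             = c("401", "402", "403", "404", "405", "I10", "I11", "I12", "I13", "I15"),
    valvular_disease         = c("424", "I34", "I35", "I36", "I37"),
    cirrhosis                = c("571.2", "571.5", "571.6", "K74"),
    end_stage_renal_disease  = c("585.6", "N18.6", "Z99.2", "V45.11")
  )
}

## Illustrative CML-severity classifier map (mild/moderate/severe). The
## published code lists of the underlying disease-complexity index are not
## replicated; tiers are fully user-configurable and these defaults exist so
## that the synthetic pipeline exercises the max-tier rule.
default_severity_map <- function() {
  list(
    moderate = c("285", "D64", "288.0", "D70", "780.6", "R50"),
    severe   = c("038", "A41", "578", "K92.2", "205.12", "C92.12")
  )
}

#' Build a study configuration
#'
#' Assembles every threshold, window, code list, approval date and formatting
#' rule the pipeline uses, with payer-appropriate defaults. Any element can be
#' overridden via `...` (matched by name, recursively for top-level lists).
#'
#' @param payer `"commercial"` or `"medicare"`. Switches the diagnosis-to-1L
#'   initiation window (+91 vs +365 days after first diagnosis), the
#'   eligibility code list (ICD vs oncology registry histology codes), the
#'   data window, and whether the death waiver / HMO exclusion apply.
#' @param ... Named overrides, e.g. `gap_days = 60` or
#'   `cpi_table = my_table`.
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(payer = c("commercial", "medicare"), ...) {
  payer <- match.arg(payer)
  cfg <- list(
    payer = payer,
    washout_days = 183L,
    gap_days = 90L,
    dx_to_1L_before_days = 30L,
    dx_to_1L_after_days = if (payer == "commercial") 91L else 365L,
    post_dx_enrollment_days = 365L,
    baseline_days = 183L,
    month_length_days = 365.25 / 12,
    year_length_days = 365.25,
    target_cost_year = 2019L,
    suppression_threshold = 11L,
    data_start = if (payer == "commercial") as.Date("2001-01-01") else as.Date("2007-01-01"),
    data_end   = if (payer == "commercial") as.Date("2019-06-30") else as.Date("2016-12-31"),
    enrollment_merge_gap_days = 0L,
    ip_proration = "by_days",           # or "by_start": whole stay to period containing admission start
    approval_dates = default_approval_dates(),
    drug_map = default_drug_map(),
    generation_map = c(imatinib = "1G", dasatinib = "2G", nilotinib = "2G",
                       bosutinib = "2G", ponatinib = "3G", omacetaxine = "other"),
    codes = list(
      cml_dx = c("205.1", "C92.1"),
      cml_dx_eligibility = if (payer == "commercial") c("205.1", "C92.1")
                           else c("9863", "9875", "35022"),
      cml_remission = c("205.11", "C92.11"),
      cml_relapse = c("205.12", "C92.12"),
      clinical_trial = c("V70.7", "Z00.6"),
      hsct_procedures = c("41.0", "38240", "38241", "38242"),
      ap_bc_chemo = c("96413", "96415", "96417", "J9000", "J9100"),
      omacetaxine_procedure = c("J9262")
    ),
    cci_map = default_cci_map(),
    comorbidity_map = default_comorbidity_map(),
    severity_map = default_severity_map(),
    hsct_unfit_age = 75L,
    hsct_unfit_conditions = c("congestive_heart_failure", "cirrhosis",
                              "end_stage_renal_disease"),
    cpi_table = default_cpi_table()
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown study_config field(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (is.list(cfg[[nm]]) && !is.data.frame(cfg[[nm]]) && is.list(dots[[nm]]) &&
          !is.data.frame(dots[[nm]]) && !is.null(names(dots[[nm]]))) {
        cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
      } else {
        cfg[[nm]] <- dots[[nm]]
      }
    }
  }
  cfg <- structure(cfg, class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  if (!is.numeric(cfg$gap_days) || cfg$gap_days <= 0)
    stop("gap_days must be > 0")
  if (!cfg$target_cost_year %in% cfg$cpi_table$year)
    stop("cpi_table does not contain target_cost_year ", cfg$target_cost_year)
  ad <- cfg$approval_dates
  missing_drugs <- setdiff(CML_DRUGS, ad$drug)
  if (length(missing_drugs))
    stop("approval_dates missing drug(s): ", paste(missing_drugs, collapse = ", "))
  if (anyNA(ad$resistant_intolerant_date))
    stop("approval_dates: resistant_intolerant_date must be populated for all drugs")
  invisible(cfg)
}

#' Read / write a study configuration as YAML
#'
#' Configuration round-trips through a structured text file; dates are stored
#' ISO-8601 and restored as `Date`, tables as column lists.
#'
#' @param path File path.
#' @param cfg A `study_config`.
#' @return `read_study_config()` returns a `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  payer <- raw$payer %||% "commercial"
  raw$payer <- NULL
  if (!is.null(raw$approval_dates)) {
    ad <- as.data.table(raw$approval_dates)
    ad[, resistant_intolerant_date := as.Date(resistant_intolerant_date)]
    ad[, newly_diagnosed_date := as.Date(newly_diagnosed_date)]
    raw$approval_dates <- ad
  }
  if (!is.null(raw$cpi_table)) raw$cpi_table <- as.data.table(raw$cpi_table)
  for (nm in c("data_start", "data_end"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.Date(raw[[nm]])
  for (nm in c("drug_map", "generation_map"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(study_config, c(list(payer = payer), raw))
}

#' @rdname read_study_config
#' @export
write_study_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$approval_dates <- lapply(as.list(out$approval_dates), as.character)
  out$cpi_table <- as.list(out$cpi_table)
  out$data_start <- as.character(out$data_start)
  out$data_end <- as.character(out$data_end)
  out$drug_map <- as.list(out$drug_map)
  out$generation_map <- as.list(out$generation_map)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Prefix (stem) code matching: claims code lists like "205.1x" match any code
## beginning with the stem. `codestr` is a ';'-joined code string as stored in
## claim tables.
codes_match <- function(codestr, stems) {
  if (!length(stems)) return(rep(FALSE, length(codestr)))
  out <- logical(length(codestr))
  nz <- !is.na(codestr) & nzchar(codestr)
  if (!any(nz)) return(out)
  split_codes <- strsplit(codestr[nz], ";", fixed = TRUE)
  out[nz] <- vapply(split_codes, function(cc) {
    any(vapply(stems, function(s) any(startsWith(cc, s)), logical(1)))
  }, logical(1))
  out
}
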