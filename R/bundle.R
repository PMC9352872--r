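## Claims data model. A claims_bundle is a list of four data.tables:
##   pharmacy:   patient_id, fill_date, drug, days_supply, paid_amount, service_year
##   medical:    patient_id, start_date, end_date, setting, diagnosis_codes,
##               procedure_codes, paid_amount, service_year
##   enrollment: patient_id, start_date, end_date, plan_type, hmo_flag
##   patients:   patient_id, birth_year, sex, region, death_date, payer
## Dates are `Date`, code lists are ';'-joined strings, all intervals are
## closed. Setting is one of inpatient/outpatient/emergency; only inpatient
## claims may span multiple days.

PHARMACY_COLS <- c("patient_id", "fill_date", "drug", "days_supply",
                   "paid_amount", "service_year")
MEDICAL_COLS <- c("patient_id", "start_date", "end_date", "setting",
                  "diagnosis_codes", "procedure_codes", "paid_amount",
                  "service_year")
ENROLLMENT_COLS <- c("patient_id", "start_date", "end_date", "plan_type",
                     "hmo_flag")
PATIENT_COLS <- c("patient_id", "birth_year", "sex", "region", "death_date",
                  "payer")

#' Assemble and validate a claims bundle
#'
#' @param pharmacy,medical,enrollment,patients Data frames with the columns
#'   documented in the package overview; extra columns are preserved.
#' @param validate Reject rows violating type invariants (negative
#'   days supply or paid amounts, medical end before start, multi-day
#'   non-inpatient claims, enrollment end before start)? Rejections are
#'   recorded in `attr(bundle, "rejections")` and summarised in a warning.
#' @return A `claims_bundle`.
#' @export
claims_bundle <- function(pharmacy, medical, enrollment, patients,
                          validate = TRUE) {
  b <- list(
    pharmacy = as.data.table(pharmacy),
    medical = as.data.table(medical),
    enrollment = as.data.table(enrollment),
    patients = as.data.table(patients)
  )
  ## service_year is derivable; tolerate its absence on input
  if (!"service_year" %in% names(b$pharmacy)) b$pharmacy[, service_year := NA_integer_]
  if (!"service_year" %in% names(b$medical)) b$medical[, service_year := NA_integer_]
  need <- list(pharmacy = PHARMACY_COLS, medical = MEDICAL_COLS,
               enrollment = ENROLLMENT_COLS, patients = PATIENT_COLS)
  for (tb in names(need)) {
    miss <- setdiff(need[[tb]], names(b[[tb]]))
    if (length(miss))
      stop("claims_bundle: table '", tb, "' is missing required column(s): ",
           paste(miss, collapse = ", "))
  }
  date_cols <- list(pharmacy = "fill_date",
                    medical = c("start_date", "end_date"),
                    enrollment = c("start_date", "end_date"),
                    patients = "death_date")
  rejections <- list()
  for (tb in names(date_cols)) for (cl in date_cols[[tb]]) {
    v <- b[[tb]][[cl]]
    if (!inherits(v, "Date")) {
      parsed <- as.Date(as.character(v), format = "%Y-%m-%d")
      bad <- which(!is.na(v) & nzchar(trimws(as.character(v))) & is.na(parsed))
      if (length(bad)) {
        rejections[[length(rejections) + 1L]] <- data.table(
          table = tb, row = bad,
          reason = paste0("unparseable date in '", cl, "'"))
        parsed[bad] <- NA
      }
      set(b[[tb]], j = cl, value = parsed)
    }
  }
  if (validate) {
    chk <- function(tb, bad, why) {
      if (any(bad)) {
        rejections[[length(rejections) + 1L]] <<- data.table(
          table = tb, row = which(bad), reason = why)
        b[[tb]] <<- b[[tb]][!bad]
      }
    }
    ph <- b$pharmacy
    chk("pharmacy", is.na(ph$fill_date), "missing/unparseable fill_date")
    ph <- b$pharmacy
    chk("pharmacy", !is.na(ph$days_supply) & ph$days_supply < 0,
        "days_supply < 0")
    ph <- b$pharmacy
    chk("pharmacy", !is.na(ph$paid_amount) & ph$paid_amount < 0,
        "paid_amount < 0")
    md <- b$medical
    chk("medical", is.na(md$start_date) | is.na(md$end_date),
        "missing/unparseable service date")
    md <- b$medical
    chk("medical", md$end_date < md$start_date, "end_date < start_date")
    md <- b$medical
    chk("medical", md$setting != "inpatient" & md$end_date > md$start_date,
        "multi-day claim outside inpatient setting")
    md <- b$medical
    chk("medical", !is.na(md$paid_amount) & md$paid_amount < 0,
        "paid_amount < 0")
    en <- b$enrollment
    chk("enrollment", is.na(en$start_date) | is.na(en$end_date) |
          en$end_date < en$start_date, "invalid enrollment span")
    b$pharmacy[, service_year := as.integer(format(fill_date, "%Y"))]
    b$medical[, service_year := as.integer(format(start_date, "%Y"))]
  }
  rej <- if (length(rejections)) rbindlist(rejections) else
    data.table(table = character(), row = integer(), reason = character())
  if (nrow(rej))
    warning("claims_bundle: rejected ", nrow(rej),
            " row(s); see attr(bundle, 'rejections')", call. = FALSE)
  structure(b, class = "claims_bundle", rejections = rej)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  patients:   %d\n", nrow(x$patients)))
  cat(sprintf("  pharmacy:   %d claims\n", nrow(x$pharmacy)))
  cat(sprintf("  medical:    %d claims\n", nrow(x$medical)))
  cat(sprintf("  enrollment: %d spans\n", nrow(x$enrollment)))
  invisible(x)
}

#' Read a claims bundle from delimited files
#'
#' Reads the four tables (comma- or tab-delimited, ISO-8601 dates), validates
#' them, and returns a [claims_bundle()]. A missing required column raises a
#' schema error naming the column; rows with unparseable dates or invariant
#' violations are rejected with row-level diagnostics.
#'
#' @param paths Named list/vector with elements `pharmacy`, `medical`,
#'   `enrollment`, `patients`, or a directory containing `pharmacy.csv` etc.
#' @param config A [study_config()] (reserved for schema options).
#' @return A `claims_bundle`.
#' @export
read_claims_bundle <- function(paths, config = study_config()) {
  if (length(paths) == 1L && is.character(paths) && dir.exists(paths)) {
    paths <- file.path(paths, c(pharmacy = "pharmacy.csv",
                                medical = "medical.csv",
                                enrollment = "enrollment.csv",
                                patients = "patients.csv"))
    names(paths) <- c("pharmacy", "medical", "enrollment", "patients")
  }
  rd <- function(p) fread(p, colClasses = list(character = intersect(
    c("patient_id", "diagnosis_codes", "procedure_codes"),
    names(fread(p, nrows = 0L)))), na.strings = c("", "NA"))
  tbs <- lapply(paths[c("pharmacy", "medical", "enrollment", "patients")], rd)
  claims_bundle(tbs$pharmacy, tbs$medical, tbs$enrollment, tbs$patients)
}

#' Write a claims bundle to delimited files
#'
#' @param bundle A `claims_bundle`.
#' @param dir Output directory (created if needed).
#' @param sep Field delimiter.
#' @return Invisibly, the named vector of files written.
#' @export
write_claims_bundle <- function(bundle, dir, sep = ",") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(pharmacy = "pharmacy.csv", medical = "medical.csv",
             enrollment = "enrollment.csv", patients = "patients.csv")
  for (tb in names(files)) {
    fwrite(bundle[[tb]], file.path(dir, files[[tb]]), sep = sep,
           dateTimeAs = "ISO")
  }
  invisible(file.path(dir, files))
}

#' Merge enrollment spans
#'
#' Overlapping or near-abutting spans (gap between consecutive spans no more
#' than `allowable_gap_days`) are merged; the result is sorted and disjoint.
#' Operates per patient when a `patient_id` column is present.
#'
#' @param spans data.frame with `start_date`, `end_date` (closed interval)
#'   and optionally `patient_id`.
#' @param allowable_gap_days Maximum ignorable gap in days between the end of
#'   one span and the start of the next (0 merges only overlapping/abutting).
#' @return data.table of merged spans.
#' @export
merge_enrollment <- function(spans, allowable_gap_days = 0L) {
  sp <- as.data.table(spans)
  if (!nrow(sp)) return(sp)
  has_id <- "patient_id" %in% names(sp)
  if (!has_id) sp[, patient_id := "_one_"]
  setorder(sp, patient_id, start_date, end_date)
  merge_one <- function(s, e) {
    n <- length(s)
    grp <- cumsum(c(TRUE, s[-1L] > cummax(as.integer(e))[-n] + 1L + allowable_gap_days))
    list(start_date = as.Date(tapply(as.integer(s), grp, min), origin = "1970-01-01"),
         end_date = as.Date(tapply(as.integer(e), grp, max), origin = "1970-01-01"))
  }
  out <- sp[, merge_one(start_date, end_date), by = patient_id]
  if (!has_id) out[, patient_id := NULL]
  out[]
}

#' Map a raw drug code to its canonical token
#'
#' @param raw_code Character vector of raw codes.
#' @param drug_map Named map raw code -> canonical token (see
#'   [default_drug_map()]).
#' @return Canonical tokens; unmapped codes become `"other"`.
#' @export
map_drug <- function(raw_code, drug_map = default_drug_map()) {
  out <- unname(drug_map[as.character(raw_code)])
  out[is.na(out)] <- "other"
  out
}
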