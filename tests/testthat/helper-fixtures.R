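# Builders for tiny engineered claim bundles. Dates are expressed as day
# offsets from a common anchor so scenarios read like the rule traces they
# exercise.

ANCHOR <- as.Date("2013-01-01")
dday <- function(k) ANCHOR + k

mk_pharmacy <- function(patient_id, day, drug, supply = 30L, paid = 100) {
  data.frame(patient_id = patient_id, fill_date = dday(day), drug = drug,
             days_supply = supply, paid_amount = paid,
             service_year = as.integer(format(dday(day), "%Y")))
}

mk_medical <- function(patient_id, start, end = start, setting = "outpatient",
                       dx = "", px = "", paid = 100) {
  data.frame(patient_id = patient_id, start_date = dday(start),
             end_date = dday(end), setting = setting,
             diagnosis_codes = dx, procedure_codes = px, paid_amount = paid,
             service_year = as.integer(format(dday(start), "%Y")))
}

mk_enrollment <- function(patient_id, start, end, hmo = FALSE) {
  data.frame(patient_id = patient_id, start_date = dday(start),
             end_date = dday(end), plan_type = "PPO", hmo_flag = hmo)
}

mk_patient <- function(patient_id, birth_year = 1960L, sex = "F",
                       payer = "commercial", death = NA) {
  data.frame(patient_id = patient_id, birth_year = birth_year, sex = sex,
             region = "South", death_date = as.Date(death), payer = payer)
}

empty_pharmacy <- function() {
  data.frame(patient_id = character(0), fill_date = as.Date(character(0)),
             drug = character(0), days_supply = integer(0),
             paid_amount = numeric(0), service_year = integer(0))
}

# A well-formed single patient who sails through the whole selection cascade:
# CML dx at day 0, imatinib 1L at day 10, dasatinib 2L, nilotinib 3L,
# enrollment from day -600 to day 1500. Pieces can be overridden to break
# exactly one criterion.
good_patient_bundle <- function(id = "A",
                                pharmacy = NULL, medical = NULL,
                                enrollment = NULL, patients = NULL) {
  ph <- rbind(
    mk_pharmacy(id, c(10, 40, 70, 100), "imatinib"),
    mk_pharmacy(id, c(130, 160), "dasatinib"),
    mk_pharmacy(id, c(190, 220, 250), "nilotinib"))
  md <- mk_medical(id, 0, dx = "C92.10;9863")
  en <- mk_enrollment(id, -600, 1500)
  pt <- mk_patient(id)
  claims_bundle(
    if (is.null(pharmacy)) ph else pharmacy,
    if (is.null(medical)) md else medical,
    if (is.null(enrollment)) en else enrollment,
    if (is.null(patients)) pt else patients)
}

# random engineered claim stream for oracle cross-checks
random_fill_stream <- function(n_fills = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    date = sort(sample(0:600, n_fills)),
    drug = sample(c("imatinib", "dasatinib", "nilotinib"), n_fills,
                  replace = TRUE),
    supply = sample(c(14L, 30L, 90L), n_fills, replace = TRUE))
}

events_from_stream <- function(id, fills, terminals = NULL) {
  ev <- data.table::data.table(
    patient_id = id, date = dday(fills$date), kind = "therapy_fill",
    drug = fills$drug, days_supply = fills$supply)
  if (!is.null(terminals) && nrow(terminals)) {
    ev <- rbind(ev, data.table::data.table(
      patient_id = id, date = dday(terminals$date), kind = terminals$kind,
      drug = NA_character_, days_supply = NA_integer_))
  }
  prio <- c(hsct = 1L, apbc_chemo = 2L, therapy_fill = 3L)
  ev[order(date, prio[kind], drug)]
}
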