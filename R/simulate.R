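## Synthetic longitudinal claims generator with ground-truth treatment
## trajectories. The generator emulates the structure of commercial /
## Medicare claims extracts used for CML line-of-therapy studies: multi-year
## enrollment, 30-day TKI fill cadence, refill jitter and >= 90-day
## treatment interruptions, drug switches respecting FDA approval dates,
## HSCT and AP/BC progression events, Poisson inpatient/outpatient/ED
## utilization with CML and non-CML diagnoses, and gamma-distributed paid
## amounts stated in service-year dollars (deflated from target-year means
## by the medical CPI, so inflation recovers the calibrated levels). It does
## not reproduce real claim layouts, real code dictionaries, or actuarially
## realistic cost levels.

#' Trajectory specification for the synthetic claims generator
#'
#' Defaults are calibrated to the commercial population of the study design
#' this package implements: line-count attrition 1L..6L, 1L drug mix,
#' line-duration lognormals with medians 8.47 / 4.24 / 8.32 / 8.39 months,
#' an annual outpatient-day rate of 30.8, inpatient-admission rate 0.4 with
#' mean length of stay 8.5 days, and ED-visit rate 1.2. Every element can
#' be overridden via `...`.
#'
#' @param n_patients Number of patients.
#' @param payer `"commercial"` or `"medicare"`.
#' @param seed RNG seed (the generator is fully deterministic given the
#'   seed).
#' @param ... Named overrides of any spec element (see the function body for
#'   the full list: `line_count_probs`, `first_line_drug_probs`,
#'   `transition_matrix`, `line_duration_median_months`,
#'   `line_duration_sigma`, `fill_cadence_days`, `days_supply`,
#'   `interruption_probability`, `short_gap_probability`, `gap_days`,
#'   `p_hsct_after_3L`, `p_apbc_after_3L`, `p_discontinue_last`,
#'   `switch_delay_mean_days`, `hru_rates`, `cost_gamma`,
#'   `comorbidity_prevalence`, `severity_probs`, `p_hydroxyurea_pretreat`,
#'   `dx_year_range`, `enroll_months_range`, `p_death`).
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_patients = 500L,
                            payer = c("commercial", "medicare"),
                            seed = 1L, ...) {
  payer <- match.arg(payer)
  drugs <- CML_DRUGS
  tm <- matrix(0, 6, 6, dimnames = list(drugs, drugs))
  tm["imatinib", ]    <- c(0,    0.55, 0.33, 0.08, 0.03, 0.01)
  tm["dasatinib", ]   <- c(0.18, 0,    0.52, 0.20, 0.08, 0.02)
  tm["nilotinib", ]   <- c(0.15, 0.52, 0,    0.22, 0.09, 0.02)
  tm["bosutinib", ]   <- c(0.10, 0.35, 0.35, 0,    0.15, 0.05)
  tm["ponatinib", ]   <- c(0.10, 0.30, 0.30, 0.20, 0,    0.10)
  tm["omacetaxine", ] <- c(0.10, 0.30, 0.30, 0.20, 0.10, 0)
  spec <- list(
    n_patients = as.integer(n_patients), payer = payer, seed = as.integer(seed),
    ## attrition-calibrated share of patients with exactly k lines
    line_count_probs = c(`1` = 2280, `2` = 658, `3` = 213, `4` = 59,
                         `5` = 14, `6` = 10) / 3234,
    first_line_drug_probs = c(imatinib = 0.649, dasatinib = 0.216,
                              nilotinib = 0.135, bosutinib = 0,
                              ponatinib = 0, omacetaxine = 0),
    transition_matrix = tm,
    line_duration_median_months = c(8.47, 4.24, 8.32, 8.39, 8.39, 8.39),
    line_duration_sigma = c(1.06, 1.34, 1.12, 1.04, 1.04, 1.04),
    fill_cadence_days = 30L, days_supply = 30L,
    interruption_probability = 0.15,   # chance of one >= gap_days interruption per line
    short_gap_probability = 0.25,      # chance of one sub-threshold refill jitter gap
    gap_days = 90L,
    p_hsct_after_3L = 0.085, p_apbc_after_3L = 0.08,
    p_discontinue_last = 0.25,
    switch_delay_mean_days = 12,
    hru_rates = list(ip_admissions = 0.4, ip_los_mean = 8.5,
                     op_days = 30.8, ed_visits = 1.2,
                     cml_share = c(ip = 0.831, op = 0.6, ed = 0.5)),
    cost_gamma = list(
      pharmacy = c(shape = 9, scale = 1000),    # mean 9000 / 30-day fill
      op = c(shape = 2, scale = 1250),          # mean 2500 / OP day
      ed = c(shape = 2, scale = 600),           # mean 1200 / visit
      ip_per_day = c(shape = 4, scale = 750),   # mean 3000 / IP day
      hsct_claim = c(shape = 5, scale = 14800)  # 3 claims -> mean 222k / event
    ),
    comorbidity_prevalence = if (payer == "commercial")
      c(cardiac_arrhythmias = 0.19, chronic_pulmonary_disease = 0.15,
        congestive_heart_failure = 0.11, diabetes = 0.25,
        hypertension = 0.45, valvular_disease = 0.12, cirrhosis = 0.03,
        end_stage_renal_disease = 0.02)
    else
      c(cardiac_arrhythmias = 0.38, chronic_pulmonary_disease = 0.42,
        congestive_heart_failure = 0.42, diabetes = 0.47,
        hypertension = 0.74, valvular_disease = 0.32, cirrhosis = 0.05,
        end_stage_renal_disease = 0.06),
    severity_probs = c(mild = 0.36, moderate = 0.35, severe = 0.29),
    p_hydroxyurea_pretreat = 0.07,
    p_female = if (payer == "commercial") 0.497 else 0.396,
    age_mean = if (payer == "commercial") 56 else 70,
    age_sd = if (payer == "commercial") 14 else 11,
    dx_year_range = if (payer == "commercial") c(2008L, 2014L)
                    else c(2008L, 2013L),
    ## observation from diagnosis averages ~58 months, matching the study's
    ## reported observation-period duration
    enroll_months_range = c(24, 96),
    enroll_pre_dx_extra_days = c(0L, 365L),
    p_death = if (payer == "medicare") 0.12 else 0
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(spec))
  if (length(bad)) stop("unknown trajectory_spec field(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    if (is.list(spec[[nm]]) && is.list(dots[[nm]]) && !is.null(names(dots[[nm]])))
      spec[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else spec[[nm]] <- dots[[nm]]
  }
  spec <- structure(spec, class = "trajectory_spec")
  validate_trajectory_spec(spec)
  spec
}

validate_trajectory_spec <- function(spec) {
  chk_probs <- function(p, nm) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("trajectory_spec: ", nm, " must be non-negative and sum to 1")
  }
  chk_probs(spec$line_count_probs, "line_count_probs")
  chk_probs(spec$first_line_drug_probs, "first_line_drug_probs")
  chk_probs(spec$severity_probs, "severity_probs")
  tm <- spec$transition_matrix
  if (any(diag(tm) != 0))
    stop("trajectory_spec: transition_matrix diagonal must be 0")
  for (i in seq_len(nrow(tm))) chk_probs(tm[i, ], paste0("transition row ", i))
  rt <- unlist(spec$hru_rates[c("ip_admissions", "op_days", "ed_visits")])
  if (any(rt < 0)) stop("trajectory_spec: hru rates must be >= 0")
  if (spec$gap_days <= 0) stop("trajectory_spec: gap_days must be > 0")
  invisible(spec)
}

## deflate a target-year (2019) amount to service-year dollars so that CPI
## inflation in the analysis recovers the calibrated level
deflate_amount <- function(amount, year, cpi = default_cpi_table()) {
  idx <- stats::setNames(cpi$index, cpi$year)
  yr <- pmin(pmax(year, min(cpi$year)), max(cpi$year))
  amount * unname(idx[as.character(yr)]) / idx[["2019"]]
}

rgamma1 <- function(n, par) stats::rgamma(n, shape = par[["shape"]],
                                          scale = par[["scale"]])

## sample n distinct days in [from, to]; n is capped at the window size
sample_days <- function(from, to, n) {
  days <- as.integer(to) - as.integer(from) + 1L
  if (days <= 0L || n <= 0L) return(as.Date(integer(0), origin = "1970-01-01"))
  n <- min(n, days)
  as.Date(as.integer(from) + sample.int(days, n) - 1L, origin = "1970-01-01")
}

#' Generate a synthetic claims cohort with ground truth
#'
#' Draws patient trajectories (line sequence, durations, interruptions,
#' terminal events), emits the corresponding pharmacy/medical/enrollment/
#' demographic claims tables, and returns the known truth against which line
#' construction and downstream outcome computations can be verified exactly.
#'
#' @param spec A [trajectory_spec()].
#' @return list with elements `bundle` (a [claims_bundle()]) and `truth`
#'   (list `lines`, `patients`): `truth$lines` holds the true line
#'   boundaries, end events, fill and interruption counts;
#'   `truth$patients` holds diagnosis/observation dates, terminal event
#'   dates, the 3L index date and true per-period person-days.
#' @export
generate_cohort <- function(spec = trajectory_spec()) {
  validate_trajectory_spec(spec)
  set.seed(spec$seed)
  cfg_approval <- default_approval_dates()
  approval <- stats::setNames(cfg_approval$resistant_intolerant_date,
                              cfg_approval$drug)
  data_end <- if (spec$payer == "commercial") as.Date("2019-06-30")
              else as.Date("2016-12-31")
  cad <- spec$fill_cadence_days; sup <- spec$days_supply
  gapd <- spec$gap_days
  regions <- c("South", "Midwest", "Northeast", "West")

  ph_l <- list(); md_l <- list(); en_l <- list(); pt_l <- list()
  tl_l <- list(); tp_l <- list()

  cml_code <- "C92.10"
  elig_extra <- if (spec$payer == "medicare") ";9863" else ""

  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%05d", i)
    ## --- demographics and calendar anchors -------------------------------
    dx_date <- sample_days(as.Date(paste0(spec$dx_year_range[1], "-01-01")),
                           as.Date(paste0(spec$dx_year_range[2], "-12-31")), 1L)
    age_dx <- round(min(max(stats::rnorm(1, spec$age_mean, spec$age_sd),
                            19), 90))
    birth_year <- as.integer(format(dx_date, "%Y")) - age_dx
    sex <- if (stats::runif(1) < spec$p_female) "F" else "M"
    region <- sample(regions, 1L)
    enroll_start <- dx_date - 183L -
      sample(spec$enroll_pre_dx_extra_days[1]:spec$enroll_pre_dx_extra_days[2], 1L)
    enroll_months <- stats::runif(1, spec$enroll_months_range[1],
                                  spec$enroll_months_range[2])
    enroll_end <- dx_date + round(enroll_months * 30.4375)
    obs_end <- min(enroll_end, data_end)
    death_date <- as.Date(NA)
    if (stats::runif(1) < spec$p_death) death_date <- enroll_end

    ## --- true trajectory --------------------------------------------------
    n_lines <- sample(seq_along(spec$line_count_probs), 1L,
                      prob = spec$line_count_probs)
    l1_start <- dx_date + sample(0:60, 1L)
    ## restrict to drugs approved at the line start; returns NA when no
    ## eligible (approved, non-current) drug exists so sequencing stops
    pick_drug <- function(probs, at_date) {
      ok <- approval[names(probs)] <= at_date
      p <- probs * as.numeric(ok[names(probs)])
      if (sum(p) <= 0) return(NA_character_)
      sample(names(probs), 1L, prob = p)
    }

    lines <- list(); fills_d <- list(); fills_drug <- list()
    start <- l1_start; prev_drug <- NULL
    hsct_date <- as.Date(NA); apbc_date <- as.Date(NA)
    k <- 0L
    while (k < n_lines && start < obs_end) {
      k <- k + 1L
      drug <- if (is.null(prev_drug)) {
        pick_drug(spec$first_line_drug_probs[FIRST_LINE_DRUGS], start)
      } else {
        pick_drug(spec$transition_matrix[prev_drug, ], start)
      }
      if (is.na(drug)) {
        ## no eligible drug: the intended switch never happens, so the prior
        ## line ends by the discontinuation/censoring definition instead
        k <- k - 1L
        if (k >= 1L) {
          prev <- lines[[k]]
          if (as.integer(obs_end) - prev$sup_end >= gapd) {
            prev$event <- "discontinuation"
            prev$end <- as.Date(prev$sup_end, origin = "1970-01-01")
          } else {
            prev$event <- "censored"; prev$end <- obs_end
          }
          lines[[k]] <- prev
        }
        break
      }
      li <- min(k, length(spec$line_duration_median_months))
      d_days <- max(1L, round(stats::rlnorm(
        1, log(spec$line_duration_median_months[li] * 30.4375),
        spec$line_duration_sigma[li])))

      is_last <- (k == n_lines)
      ## decide the end event for the intended span
      if (!is_last) {
        event <- "switch"
      } else if (k >= 3L && stats::runif(1) < spec$p_hsct_after_3L &&
                 start + d_days < obs_end - 1L) {
        event <- "hsct"
      } else if (k >= 3L && stats::runif(1) < spec$p_apbc_after_3L &&
                 start + d_days < obs_end - 1L) {
        event <- "apbc_chemo"
      } else if (stats::runif(1) < spec$p_discontinue_last) {
        event <- "discontinuation"
      } else {
        event <- "censored"
      }

      ## interruption / jitter gaps carved inside the span
      gap_len <- 0L; gap_after <- NA_integer_; n_interrupt <- 0L
      if (stats::runif(1) < spec$interruption_probability &&
          d_days >= gapd + 3L * cad) {
        gap_len <- gapd + round(stats::rexp(1, 1 / 45))
        n_interrupt <- 1L
      } else if (stats::runif(1) < spec$short_gap_probability &&
                 d_days >= 4L * cad) {
        gap_len <- sample(7:min(45L, gapd - 1L), 1L)
      }

      tf <- 0L
      if (event == "switch") {
        tf <- min(round(stats::rexp(1, 1 / spec$switch_delay_mean_days)), 89L)
      }
      if (event == "discontinuation") {
        d_days <- cad * max(1L, round(d_days / cad))
        if (start + d_days + gap_len + gapd > obs_end) event <- "censored"
      }
      if (event %in% c("switch", "hsct", "apbc_chemo") &&
          start + d_days + gap_len >= obs_end) {
        event <- "censored"
      }

      ## lay down fills at cadence over [start, lim]; the last fill's supply
      ## never extends past lim except for the guaranteed first fill; an
      ## interruption/jitter gap of gap_len days is inserted after the 2nd or
      ## 3rd fill when room allows
      lim <- if (event == "censored") as.integer(obs_end) else
        as.integer(start) + d_days + gap_len
      gap_idx <- if (gap_len > 0L) sample(2:3, 1L) else NA_integer_
      fdates <- integer(0); cur <- as.integer(start); gl <- gap_len
      repeat {
        if (length(fdates) && cur + sup > lim) break
        fdates <- c(fdates, cur)
        if (!is.na(gap_idx) && length(fdates) == gap_idx && gl > 0L) {
          cur <- cur + sup + gl
          gl <- 0L
        } else {
          cur <- cur + cad
        }
        if (length(fdates) > 600L) break
      }
      actual_interrupt <- if (length(fdates) > 1L)
        sum(diff(fdates) - sup >= gapd) else 0L
      sup_end <- max(fdates) + sup

      end_date <- switch(event,
        switch = as.Date(sup_end + tf, origin = "1970-01-01"),
        discontinuation = as.Date(sup_end, origin = "1970-01-01"),
        hsct = ,
        apbc_chemo = as.Date(lim, origin = "1970-01-01"),
        censored = obs_end)
      if (event == "switch" && end_date >= obs_end) {
        ## the treatment-free delay would outrun observation; the line is
        ## censored instead (the trailing gap is < gap_days by construction)
        event <- "censored"; end_date <- obs_end
      }
      if (event == "censored" && as.integer(obs_end) - sup_end >= gapd) {
        ## an inserted gap can leave a terminal off-supply stretch of
        ## >= gap_days before the observation end: by definition that is a
        ## discontinuation, not censoring
        event <- "discontinuation"
        end_date <- as.Date(sup_end, origin = "1970-01-01")
      }

      lines[[k]] <- list(drug = drug, start = start, end = end_date,
                         sup_end = sup_end, event = event,
                         n_fills = length(fdates),
                         interruptions = actual_interrupt)
      fills_d[[k]] <- fdates; fills_drug[[k]] <- drug

      if (event == "switch") {
        start <- end_date; prev_drug <- drug
      } else {
        if (event == "hsct") hsct_date <- end_date
        if (event == "apbc_chemo") apbc_date <- end_date
        break
      }
    }
    n_built <- length(lines)

    ## --- pharmacy claims for therapy fills -------------------------------
    for (k2 in seq_len(n_built)) {
      fd <- fills_d[[k2]]
      yrs <- as.integer(format(as.Date(fd, origin = "1970-01-01"), "%Y"))
      ph_l[[length(ph_l) + 1L]] <- data.table(
        patient_id = pid, fill_date = as.Date(fd, origin = "1970-01-01"),
        drug = fills_drug[[k2]], days_supply = sup,
        paid_amount = round(deflate_amount(
          rgamma1(length(fd), spec$cost_gamma$pharmacy), yrs), 2),
        service_year = yrs)
    }
    ## hydroxyurea pretreatment between diagnosis and 1L
    if (stats::runif(1) < spec$p_hydroxyurea_pretreat && l1_start > dx_date + 7L) {
      hu_d <- sample_days(dx_date, l1_start - 1L, 2L)
      yrs <- as.integer(format(hu_d, "%Y"))
      ph_l[[length(ph_l) + 1L]] <- data.table(
        patient_id = pid, fill_date = hu_d, drug = "hydroxyurea",
        days_supply = 14L,
        paid_amount = round(deflate_amount(stats::rgamma(length(hu_d), 2, scale = 25), yrs), 2),
        service_year = yrs)
    }

    ## --- medical claims ----------------------------------------------------
    md_p <- list()
    win_start <- dx_date - 183L         # utilization window with stationary rates
    win_end <- obs_end
    yrs_at <- function(d) as.integer(format(d, "%Y"))
    window_years <- as.numeric(win_end - win_start + 1L) / 365.25

    comorbid <- names(spec$comorbidity_prevalence)[
      stats::runif(length(spec$comorbidity_prevalence)) <
        spec$comorbidity_prevalence]
    severity <- sample(names(spec$severity_probs), 1L,
                       prob = spec$severity_probs)
    sev_code <- switch(severity, mild = NULL,
                       moderate = default_severity_map()$moderate[1L],
                       severe = default_severity_map()$severe[1L])
    extra_codes <- function(n) {
      ## attach comorbidity/severity codes to a share of OP claims
      vapply(seq_len(n), function(j) {
        cc <- character(0)
        for (cm in comorbid)
          if (stats::runif(1) < 0.3)
            cc <- c(cc, default_comorbidity_map()[[cm]][1L])
        if (!is.null(sev_code) && stats::runif(1) < 0.3) cc <- c(cc, sev_code)
        paste(cc, collapse = ";")
      }, character(1))
    }

    ## diagnosis-confirming OP claim
    md_p[[length(md_p) + 1L]] <- data.table(
      patient_id = pid, start_date = dx_date, end_date = dx_date,
      setting = "outpatient",
      diagnosis_codes = paste0(cml_code, elig_extra),
      procedure_codes = "",
      paid_amount = round(deflate_amount(rgamma1(1, spec$cost_gamma$op),
                                         yrs_at(dx_date)), 2),
      service_year = yrs_at(dx_date))

    ## outpatient service days
    n_op <- stats::rpois(1, spec$hru_rates$op_days * window_years)
    op_days <- sample_days(win_start, win_end, n_op)
    if (length(op_days)) {
      ## CML-coded claims can only occur on/after the diagnosis date
      is_cml <- stats::runif(length(op_days)) < spec$hru_rates$cml_share[["op"]] &
        op_days >= dx_date
      ex <- extra_codes(length(op_days))
      dxs <- ifelse(is_cml, ifelse(nzchar(ex), paste(cml_code, ex, sep = ";"),
                                   cml_code),
                    ifelse(nzchar(ex), ex, "R53.8"))
      md_p[[length(md_p) + 1L]] <- data.table(
        patient_id = pid, start_date = op_days, end_date = op_days,
        setting = "outpatient", diagnosis_codes = dxs, procedure_codes = "",
        paid_amount = round(deflate_amount(
          rgamma1(length(op_days), spec$cost_gamma$op), yrs_at(op_days)), 2),
        service_year = yrs_at(op_days))
    }
    ## ED visits
    n_ed <- stats::rpois(1, spec$hru_rates$ed_visits * window_years)
    ed_days <- sample_days(win_start, win_end, n_ed)
    if (length(ed_days)) {
      is_cml <- stats::runif(length(ed_days)) < spec$hru_rates$cml_share[["ed"]] &
        ed_days >= dx_date
      md_p[[length(md_p) + 1L]] <- data.table(
        patient_id = pid, start_date = ed_days, end_date = ed_days,
        setting = "emergency",
        diagnosis_codes = ifelse(is_cml, cml_code, "R07.9"),
        procedure_codes = "",
        paid_amount = round(deflate_amount(
          rgamma1(length(ed_days), spec$cost_gamma$ed), yrs_at(ed_days)), 2),
        service_year = yrs_at(ed_days))
    }
    ## inpatient admissions (non-overlapping, contained in the window)
    n_ip <- stats::rpois(1, spec$hru_rates$ip_admissions * window_years)
    ip_s <- integer(0); ip_e <- integer(0)
    for (j in seq_len(n_ip)) {
      los <- 1L + stats::rpois(1, spec$hru_rates$ip_los_mean - 1)
      for (try in 1:8) {
        s <- as.integer(sample_days(win_start, win_end - los, 1L))
        if (!length(s)) break
        e <- s + los - 1L
        if (!any(ip_e >= s - 1L & ip_s <= e + 1L)) {   # keep stays disjoint, non-abutting
          ip_s <- c(ip_s, s); ip_e <- c(ip_e, e)
          is_cml <- stats::runif(1) < spec$hru_rates$cml_share[["ip"]] &&
            s >= as.integer(dx_date)
          sd <- as.Date(s, origin = "1970-01-01")
          md_p[[length(md_p) + 1L]] <- data.table(
            patient_id = pid, start_date = sd,
            end_date = as.Date(e, origin = "1970-01-01"),
            setting = "inpatient",
            diagnosis_codes = if (is_cml) cml_code else "I21.9",
            procedure_codes = "",
            paid_amount = round(deflate_amount(
              los * rgamma1(1, spec$cost_gamma$ip_per_day), yrs_at(sd)), 2),
            service_year = yrs_at(sd))
          break
        }
      }
    }
    ## HSCT event: procedure claim inside an IP admission
    if (!is.na(hsct_date)) {
      adm_s <- hsct_date - 2L
      adm_e <- min(hsct_date + 5L, enroll_end)
      amts <- rgamma1(3, spec$cost_gamma$hsct_claim)
      md_p[[length(md_p) + 1L]] <- data.table(
        patient_id = pid,
        start_date = c(adm_s, adm_s, hsct_date),
        end_date = c(adm_e, adm_e, hsct_date),
        setting = "inpatient",
        diagnosis_codes = cml_code,
        procedure_codes = c("", "", "38240"),
        paid_amount = round(deflate_amount(amts, rep(yrs_at(hsct_date), 3)), 2),
        service_year = rep(yrs_at(hsct_date), 3))
    }
    ## AP/BC progression: non-listed chemotherapy administration
    if (!is.na(apbc_date)) {
      md_p[[length(md_p) + 1L]] <- data.table(
        patient_id = pid, start_date = apbc_date, end_date = apbc_date,
        setting = "outpatient", diagnosis_codes = cml_code,
        procedure_codes = "96413",
        paid_amount = round(deflate_amount(rgamma1(1, spec$cost_gamma$op),
                                           yrs_at(apbc_date)), 2),
        service_year = yrs_at(apbc_date))
    }
    md_l[[length(md_l) + 1L]] <- rbindlist(md_p)

    en_l[[length(en_l) + 1L]] <- data.table(
      patient_id = pid, start_date = enroll_start, end_date = enroll_end,
      plan_type = if (spec$payer == "commercial") "PPO" else "FFS",
      hmo_flag = FALSE)
    pt_l[[length(pt_l) + 1L]] <- data.table(
      patient_id = pid, birth_year = birth_year, sex = sex, region = region,
      death_date = death_date, payer = spec$payer)

    ## --- ground truth -----------------------------------------------------
    tl <- rbindlist(lapply(seq_len(n_built), function(k2) {
      L <- lines[[k2]]
      data.table(patient_id = pid, line_number = k2, drug = L$drug,
                 start_date = L$start, end_date = as.Date(L$end),
                 supply_end_date = as.Date(L$sup_end, origin = "1970-01-01"),
                 end_event = L$event, n_fills = L$n_fills,
                 interruption_count = L$interruptions)
    }))
    tl[, treatment_free_days_to_next := c(
      if (.N > 1L) pmax(0, as.numeric(start_date[-1L]) -
                           as.numeric(supply_end_date[-.N])) else numeric(),
      NA_real_)]
    tl_l[[length(tl_l) + 1L]] <- tl

    idx3 <- if (n_built >= 3L) tl$start_date[3L] else as.Date(NA)
    fu_end <- min(c(obs_end, hsct_date, apbc_date), na.rm = TRUE)
    pd3p <- if (!is.na(idx3)) as.numeric(fu_end - idx3) else NA_real_
    pd3 <- if (!is.na(idx3))
      max(0, as.numeric(min(tl$end_date[3L], fu_end) - idx3)) else NA_real_
    pd4 <- if (n_built >= 4L)
      max(0, as.numeric(min(tl$end_date[4L], fu_end) -
                          max(tl$start_date[4L], idx3))) else NA_real_
    tp_l[[length(tp_l) + 1L]] <- data.table(
      patient_id = pid, dx_date = dx_date, line1_start = l1_start,
      obs_end = obs_end, n_lines = n_built, hsct_date = hsct_date,
      apbc_date = apbc_date, index_date = idx3, fu_end = fu_end,
      pd_3Lplus = pd3p, pd_3L = pd3, pd_4L = pd4)
  }

  bundle <- claims_bundle(rbindlist(ph_l), rbindlist(md_l), rbindlist(en_l),
                          rbindlist(pt_l), validate = FALSE)
  truth <- list(lines = rbindlist(tl_l), patients = rbindlist(tp_l))
  list(bundle = bundle, truth = truth)
}

#' Inject non-line-defining noise into a bundle
#'
#' Adds claims that must not alter constructed lines: fills of unlisted
#' (`other`) drugs, pre-diagnosis hydroxyurea fills, and non-CML outpatient
#' claims.
#'
#' @param bundle A [claims_bundle()].
#' @param n_other_fills,n_noncml_op,n_pre_dx_hydroxyurea Counts of injected
#'   rows (spread uniformly over patients and their enrollment windows).
#' @param seed RNG seed.
#' @param max_date Latest allowed claim date (defaults to the commercial
#'   data window end so injected claims stay inside the CPI table's range).
#' @return The augmented `claims_bundle`.
#' @export
inject_noise <- function(bundle, n_other_fills = 100L, n_noncml_op = 200L,
                         n_pre_dx_hydroxyurea = 50L, seed = 42L,
                         max_date = as.Date("2019-06-30")) {
  set.seed(seed)
  en <- as.data.table(bundle$enrollment)
  pick <- function(n) {
    rows <- en[sample.int(nrow(en), n, replace = TRUE)]
    rows[, date := as.Date(as.integer(start_date) +
                             floor(stats::runif(.N) *
                                     (as.integer(end_date) - as.integer(start_date) + 1L)),
                           origin = "1970-01-01")]
    rows[, date := pmin(date, max_date)]
    rows[, .(patient_id, date)]
  }
  out <- bundle
  if (n_other_fills > 0) {
    p <- pick(n_other_fills)
    out$pharmacy <- rbind(out$pharmacy, data.table(
      patient_id = p$patient_id, fill_date = p$date, drug = "other",
      days_supply = 30L, paid_amount = round(stats::rgamma(nrow(p), 2, scale = 40), 2),
      service_year = as.integer(format(p$date, "%Y"))), fill = TRUE)
  }
  if (n_pre_dx_hydroxyurea > 0) {
    p <- pick(n_pre_dx_hydroxyurea)
    en_min <- en[, .(first_date = min(start_date)), by = patient_id]
    p <- merge(p, en_min, by = "patient_id")
    p[, date := first_date + 7L]
    out$pharmacy <- rbind(out$pharmacy, data.table(
      patient_id = p$patient_id, fill_date = p$date, drug = "hydroxyurea",
      days_supply = 14L, paid_amount = round(stats::rgamma(nrow(p), 2, scale = 25), 2),
      service_year = as.integer(format(p$date, "%Y"))), fill = TRUE)
  }
  if (n_noncml_op > 0) {
    p <- pick(n_noncml_op)
    out$medical <- rbind(out$medical, data.table(
      patient_id = p$patient_id, start_date = p$date, end_date = p$date,
      setting = "outpatient", diagnosis_codes = "Z00.0", procedure_codes = "",
      paid_amount = round(stats::rgamma(nrow(p), 2, scale = 150), 2),
      service_year = as.integer(format(p$date, "%Y"))), fill = TRUE)
  }
  out
}
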