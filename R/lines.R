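## Line-of-therapy construction from therapy claims.
##
## A line starts at the first claim for a CML-CP drug and ends at the earliest
## of: a fill for a different CML-CP drug (switch; the next line starts that
## same day), initiation of a chemotherapy not listed for CML-CP (AP/BC
## progression), an HSCT procedure, treatment discontinuation (a gap of >= 90
## consecutive days off supply with no further therapy), or the end of the
## observation period (censoring). A >= 90-day off-supply gap followed by a
## fill of the *same* drug is a treatment interruption and does not end the
## line. Hydroxyurea and unlisted ("other") drugs never define lines.

#' Collect line-defining therapy events for one or more patients
#'
#' Filters pharmacy fills to the six CML-CP drugs on/after each drug's
#' earliest applicable FDA approval date, identifies omacetaxine administered
#' via procedure-coded medical claims, and appends HSCT and AP/BC
#' chemotherapy events from procedure codes. Hydroxyurea and `other` fills
#' are dropped (hydroxyurea is pretreatment only).
#'
#' @param bundle A [claims_bundle()].
#' @param config A [study_config()].
#' @return data.table with columns `patient_id`, `date`, `kind`
#'   (`therapy_fill`, `hsct`, `apbc_chemo`), `drug`, `days_supply`, ordered
#'   by patient, date, and event priority (hsct > apbc_chemo > fill).
#' @export
collect_therapy_events <- function(bundle, config = study_config()) {
  ad <- config$approval_dates
  approval <- stats::setNames(ad$resistant_intolerant_date, ad$drug)

  ph <- bundle$pharmacy[drug %in% CML_DRUGS]
  ph <- ph[fill_date >= approval[drug]]
  fills <- ph[, .(patient_id, date = fill_date, kind = "therapy_fill",
                  drug, days_supply = as.integer(days_supply))]

  md <- bundle$medical
  oma <- md[codes_match(procedure_codes, config$codes$omacetaxine_procedure)]
  if (nrow(oma)) {
    oma <- oma[start_date >= approval[["omacetaxine"]]]
    ## procedure-administered omacetaxine: treat as a 1-day-supply therapy event
    fills <- rbind(fills, oma[, .(patient_id, date = start_date,
                                  kind = "therapy_fill", drug = "omacetaxine",
                                  days_supply = 1L)])
  }
  hsct <- md[codes_match(procedure_codes, config$codes$hsct_procedures),
             .(patient_id, date = start_date, kind = "hsct",
               drug = NA_character_, days_supply = NA_integer_)]
  apbc <- md[codes_match(procedure_codes, config$codes$ap_bc_chemo),
             .(patient_id, date = start_date, kind = "apbc_chemo",
               drug = NA_character_, days_supply = NA_integer_)]
  ev <- rbind(fills, hsct, apbc)
  if (!nrow(ev)) return(ev)
  prio <- c(hsct = 1L, apbc_chemo = 2L, therapy_fill = 3L)
  ev[, kind := as.character(kind)]
  setorderv(ev[, `:=`(.prio = prio[kind])],
            c("patient_id", "date", ".prio", "drug"))
  ev[, .prio := NULL]
  ev[]
}

#' Drug generation classification
#'
#' @param drug Canonical drug token(s).
#' @return `"1G"` (imatinib), `"2G"` (dasatinib, nilotinib, bosutinib),
#'   `"3G"` (ponatinib) or `"other"` (omacetaxine).
#' @export
classify_generation <- function(drug) {
  map <- c(imatinib = "1G", dasatinib = "2G", nilotinib = "2G",
           bosutinib = "2G", ponatinib = "3G", omacetaxine = "other")
  out <- unname(map[drug])
  if (anyNA(out))
    stop("classify_generation: unknown drug(s): ",
         paste(unique(drug[is.na(out)]), collapse = ", "))
  out
}

## Core single-patient scan over plain vectors (hot path: called once per
## patient). `d` integer dates, `k` kinds, `dr` drugs, `sp` supplies, in the
## order produced by collect_therapy_events(); returns a list of parallel
## vectors describing the patient's lines, or NULL when no line exists.
scan_lines_one <- function(d, k, dr, sp, obs_i, gapd) {
  isf <- k == "therapy_fill" & d <= obs_i
  if (!any(isf)) return(NULL)
  first_fill <- min(d[isf])
  ti <- which(k != "therapy_fill" & d <= obs_i & d >= first_fill)
  t_date <- if (length(ti)) d[ti[1L]] else NA_integer_   # priority pre-sorted
  t_kind <- if (length(ti)) k[ti[1L]] else NA_character_
  keep <- isf & (if (is.na(t_date)) TRUE else d < t_date)  # same-day terminal outranks the fill
  if (!any(keep)) return(NULL)
  fd <- d[keep]; fdr <- dr[keep]; fse <- d[keep] + sp[keep]; fsp <- sp[keep]
  o <- order(fd, fdr)
  fd <- fd[o]; fdr <- fdr[o]; fse <- fse[o]; fsp <- fsp[o]
  starts <- which(!duplicated(fd))
  ends <- c(starts[-1L] - 1L, length(fd))
  n_days <- length(starts)

  cap <- n_days + 1L
  L_drug <- character(cap); L_start <- integer(cap); L_end <- integer(cap)
  L_se <- integer(cap); L_ev <- character(cap); L_nf <- integer(cap)
  L_int <- integer(cap); nl <- 0L

  ## pick the defining drug among candidate fills: larger days_supply, ties
  ## broken alphabetically
  pick_idx <- function(idx) idx[order(-fsp[idx], fdr[idx])][1L]

  cur_drug <- NA_character_; cur_start <- NA_integer_
  cur_se <- NA_integer_; cur_nf <- 0L; cur_int <- 0L
  for (j in seq_len(n_days)) {
    idx <- starts[j]:ends[j]
    day_date <- fd[idx[1L]]
    if (is.na(cur_drug)) {
      pk <- pick_idx(idx)
      cur_drug <- fdr[pk]; cur_start <- day_date
      sel <- idx[fdr[idx] == cur_drug]
      cur_se <- max(fse[sel]); cur_nf <- length(sel); cur_int <- 0L
      next
    }
    same <- idx[fdr[idx] == cur_drug]
    other <- idx[fdr[idx] != cur_drug]
    if (length(same)) {
      if (day_date - cur_se >= gapd) cur_int <- cur_int + 1L
      cur_nf <- cur_nf + length(same)
      cur_se <- max(cur_se, fse[same])
    }
    if (length(other)) {
      nl <- nl + 1L
      L_drug[nl] <- cur_drug; L_start[nl] <- cur_start; L_end[nl] <- day_date
      L_se[nl] <- cur_se; L_ev[nl] <- "switch"; L_nf[nl] <- cur_nf
      L_int[nl] <- cur_int
      pk <- pick_idx(other)
      cur_drug <- fdr[pk]; cur_start <- day_date
      sel <- other[fdr[other] == cur_drug]
      cur_se <- max(fse[sel]); cur_nf <- length(sel); cur_int <- 0L
    }
  }
  nl <- nl + 1L
  L_drug[nl] <- cur_drug; L_start[nl] <- cur_start; L_se[nl] <- cur_se
  L_nf[nl] <- cur_nf; L_int[nl] <- cur_int
  if (!is.na(t_date)) {
    L_end[nl] <- t_date; L_ev[nl] <- t_kind
  } else if (obs_i - cur_se >= gapd) {
    L_end[nl] <- cur_se; L_ev[nl] <- "discontinuation"
  } else {
    L_end[nl] <- obs_i; L_ev[nl] <- "censored"
  }
  list(drug = L_drug[1:nl], start = L_start[1:nl], end = L_end[1:nl],
       sup_end = L_se[1:nl], event = L_ev[1:nl], n_fills = L_nf[1:nl],
       interruptions = L_int[1:nl])
}

#' Build lines of therapy from an ordered therapy-event stream
#'
#' Applies the start/interruption/termination rules described in the package
#' overview. Ties on the same day are deterministic: an HSCT outranks AP/BC
#' chemotherapy outranks a fill; when two different CML-CP drugs are first
#' filled the same day, the larger days-supply (then alphabetical order)
#' defines the line.
#'
#' @param events Event table from [collect_therapy_events()] (one or many
#'   patients).
#' @param observation_end Named `Date` vector (by patient id) or single date:
#'   end of each patient's observation period.
#' @param gap_days Discontinuation/interruption threshold in days (default
#'   90).
#' @return data.table of therapy lines with one row per (patient, line):
#'   `patient_id`, `line_number`, `drug`, `start_date`, `end_date`,
#'   `supply_end_date`, `end_event` (switch / apbc_chemo / hsct /
#'   discontinuation / censored), `n_fills`, `interruption_count`,
#'   `treatment_free_days_to_next`.
#' @export
build_lines <- function(events, observation_end, gap_days = 90L) {
  empty <- data.table(
    patient_id = character(), line_number = integer(), drug = character(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    supply_end_date = as.Date(character()), end_event = character(),
    n_fills = integer(), interruption_count = integer(),
    treatment_free_days_to_next = numeric())
  if (!nrow(events)) return(empty)
  ev <- as.data.table(events)
  ids <- unique(ev$patient_id)
  if (length(observation_end) == 1L && is.null(names(observation_end))) {
    obs <- stats::setNames(rep(as.Date(observation_end), length(ids)), ids)
  } else {
    obs <- observation_end
    miss <- setdiff(ids, names(obs))
    if (length(miss))
      stop("build_lines: no observation_end for patient(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
  }
  obs_i <- stats::setNames(as.integer(as.Date(unname(obs))), names(obs))

  pid <- ev$patient_id; d <- as.integer(ev$date); k <- ev$kind
  dr <- ev$drug; sp <- ev$days_supply
  sp[is.na(sp)] <- 0L
  idx_by_pat <- split(seq_along(pid), pid)   # row order preserved per patient

  res <- vector("list", length(idx_by_pat))
  for (p in seq_along(idx_by_pat)) {
    ii <- idx_by_pat[[p]]
    id <- pid[ii[1L]]
    sc <- scan_lines_one(d[ii], k[ii], dr[ii], sp[ii], obs_i[[id]], gap_days)
    if (is.null(sc)) next
    nL <- length(sc$drug)
    res[[p]] <- data.table(
      patient_id = id, line_number = seq_len(nL), drug = sc$drug,
      start_date = as.Date(sc$start, origin = "1970-01-01"),
      end_date = as.Date(sc$end, origin = "1970-01-01"),
      supply_end_date = as.Date(sc$sup_end, origin = "1970-01-01"),
      end_event = sc$event, n_fills = sc$n_fills,
      interruption_count = sc$interruptions,
      treatment_free_days_to_next = c(
        if (nL > 1L) pmax(0, as.numeric(sc$start[-1L] - sc$sup_end[-nL]))
        else numeric(), NA_real_))
  }
  out <- rbindlist(res)
  if (!nrow(out)) return(empty)
  setorder(out, patient_id, line_number)
  out[]
}

#' Per-line-number treatment-pattern summary
#'
#' Produces the publication-style per-line summary: patients per line, drug
#' and generation frequencies, line duration statistics (months of 30.4375
#' days), duration buckets (one fill, <=3 months, >3 to <=6, plus cumulative
#' >6 and >12), treatment-free period statistics among patients with an
#' observed next line, and end-of-line event tallies.
#'
#' @param lines Line table from [build_lines()], restricted to the cohort of
#'   interest.
#' @param config A [study_config()].
#' @param max_line Summarise lines 1..`max_line` (default 4).
#' @return Named list of data.tables: `overview`, `drugs`, `generations`,
#'   `end_events`.
#' @export
summarize_lines <- function(lines, config = study_config(), max_line = 4L) {
  ln <- as.data.table(lines)[line_number <= max_line]
  ln[, duration_months := as.numeric(end_date - start_date) / config$month_length_days]
  ln[, tf_months := treatment_free_days_to_next / config$month_length_days]
  overview <- ln[, .(
    n = .N,
    duration_mean = mean(duration_months),
    duration_sd = stats::sd(duration_months),
    duration_median = stats::median(duration_months),
    one_fill = sum(n_fills == 1L),
    le3mo = sum(duration_months <= 3),
    gt3_le6mo = sum(duration_months > 3 & duration_months <= 6),
    gt6mo = sum(duration_months > 6),
    gt12mo = sum(duration_months > 12),
    tf_mean = mean(tf_months, na.rm = TRUE),
    tf_sd = stats::sd(tf_months[!is.na(tf_months)]),
    tf_median = stats::median(tf_months, na.rm = TRUE),
    interruptions_total = sum(interruption_count)
  ), keyby = line_number]
  drugs <- ln[, .(n = .N), keyby = .(line_number, drug)]
  drugs[, prop := n / sum(n), by = line_number]
  ln[, generation := classify_generation(drug)]
  gens <- ln[, .(n = .N), keyby = .(line_number, generation)]
  gens[, prop := n / sum(n), by = line_number]
  evs <- ln[, .(n = .N), keyby = .(line_number, end_event)]
  list(overview = overview[], drugs = drugs[], generations = gens[],
       end_events = evs[])
}

#' Treatment-sequence frequencies
#'
#' Frequencies of ordered drug tuples (1L, ..., depth-L), and of the
#' corresponding generation tuples, among patients who reached `depth` lines.
#'
#' @param lines Line table from [build_lines()].
#' @param depth Number of leading lines in the tuple (>= 2).
#' @return list with data.tables `drug_sequences` and
#'   `generation_sequences` (`n`, `frequency`, frequencies summing to 1).
#' @export
sequence_frequencies <- function(lines, depth = 2L) {
  stopifnot(depth >= 2L)
  ln <- as.data.table(lines)
  reached <- ln[, .N, by = patient_id][N >= depth, patient_id]
  ln <- ln[patient_id %in% reached & line_number <= depth]
  setorder(ln, patient_id, line_number)
  seqs <- ln[, .(drug_seq = paste(drug, collapse = " -> "),
                 gen_seq = paste(classify_generation(drug), collapse = " -> ")),
             by = patient_id]
  ds <- seqs[, .(n = .N), keyby = drug_seq][, frequency := n / sum(n)][]
  gs <- seqs[, .(n = .N), keyby = gen_seq][, frequency := n / sum(n)][]
  setorder(ds, -n); setorder(gs, -n)
  list(drug_sequences = ds, generation_sequences = gs)
}
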