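## Publication-style formatting: one-decimal half-up percentages, small-cell
## suppression (counts below a display threshold masked, with complementary
## masking so no masked count is recoverable by subtraction), and the
## end-to-end pipeline runner.

#' Percentage formatted to one decimal, half-up
#'
#' `100 * numerator / denominator`, rounded half-up (so 0.05 always rounds
#' away from zero at the displayed precision, unlike banker's rounding) and
#' formatted with exactly one decimal.
#'
#' @param numerator,denominator Numeric vectors.
#' @return Character vector (e.g. `"64.9"`); `NA` where the denominator is 0.
#' @export
format_percent <- function(numerator, denominator) {
  out <- rep(NA_character_, length(numerator))
  ok <- denominator > 0
  pct <- 100 * numerator[ok] / denominator[ok]
  ## half-up at one decimal; the 1e-9 nudge guards against values like
  ## 51.349999999 that are exactly-representable halves in decimal
  rounded <- floor(pct * 10 + 0.5 + 1e-9) / 10
  out[ok] <- sprintf("%.1f", rounded)
  out
}

#' Apply small-cell suppression to a count table
#'
#' Counts in `[1, threshold - 1]` are replaced by a mask token (zero is
#' displayable). Within each group whose total is displayed, masked cells
#' must not be recoverable by subtraction: if exactly one cell of a group is
#' masked, the smallest remaining displayed cell is masked as well
#' (complementary suppression). Percentages derived from masked cells are
#' masked by the caller via the returned `masked` flag.
#'
#' @param tbl data.frame with a count column.
#' @param threshold Smallest displayable nonzero count (default 11).
#' @param count_col Name of the count column.
#' @param group_col Optional grouping column; complementary suppression is
#'   applied within groups (whose totals are assumed displayed). Without a
#'   group column the whole table is one group and the total is assumed
#'   displayed only when `total` is given.
#' @param total Optional displayed group total(s): single number or named
#'   vector by group.
#' @param mask Mask token (default `"<11"` style, built from the threshold).
#' @return data.table: the input plus `masked` (logical) and `display`
#'   (character: formatted count or mask token).
#' @export
apply_suppression <- function(tbl, threshold = 11L, count_col = "n",
                              group_col = NULL, total = NULL,
                              mask = paste0("<", threshold)) {
  dt <- as.data.table(tbl)
  cnt <- dt[[count_col]]
  dt[, masked := cnt >= 1 & cnt <= threshold - 1L]
  grp <- if (is.null(group_col)) rep("_all_", nrow(dt)) else
    as.character(dt[[group_col]])
  has_total <- function(g) {
    if (is.null(total)) return(!is.null(group_col))
    TRUE
  }
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (!has_total(g)) next
    ## keep masking until no single masked cell is recoverable from the
    ## displayed cells and the group total
    repeat {
      m <- dt$masked[idx]
      if (sum(m) != 1L) break
      shown <- idx[!m]
      if (!length(shown)) break
      cand <- shown[order(cnt[shown])][1L]
      dt$masked[cand] <- TRUE
    }
  }
  dt[, display := ifelse(masked, mask, format(cnt, trim = TRUE,
                                              scientific = FALSE))]
  dt[]
}

#' Run the full pipeline
#'
#' simulate/ingest -> selection cascade -> lines -> baseline -> HRU ->
#' costs (+ HSCT sensitivity) -> assembled report. With a fixed seed the
#' report is fully deterministic.
#'
#' @param config A [study_config()].
#' @param bundle A [claims_bundle()]; alternatively supply `spec` to
#'   simulate one.
#' @param spec A [trajectory_spec()] used with [generate_cohort()] when
#'   `bundle` is missing.
#' @param out_dir Optional directory; when given, every table is written as
#'   a CSV.
#' @param suppress Apply small-cell suppression to the report's count tables
#'   (the Medicare display convention)?
#' @return list of class `cohort_report`: `attrition`, `cohort`, `lines`,
#'   `line_summary`, `sequences`, `baseline`, `periods`, `hru`, `costs`,
#'   `costs_sensitivity`, `hsct_events`, `suppressed`, `manifest`.
#' @export
run_pipeline <- function(config = study_config(), bundle = NULL, spec = NULL,
                         out_dir = NULL, suppress = FALSE) {
  t0 <- Sys.time()
  truth <- NULL
  if (is.null(bundle)) {
    if (is.null(spec)) stop("run_pipeline: supply a bundle or a spec")
    sim <- generate_cohort(spec)
    bundle <- sim$bundle
    truth <- sim$truth
  }
  sel <- apply_selection(bundle, config)
  cohort <- sel$cohort
  cohort_lines <- sel$lines[patient_id %in% cohort$patient_id]

  line_summary <- summarize_lines(cohort_lines, config)
  sequences <- if (nrow(cohort)) sequence_frequencies(cohort_lines, depth = 2L)
               else NULL
  baseline <- if (nrow(cohort)) {
    summarize_baseline(baseline_profile(bundle, cohort, config))
  } else NULL

  periods <- period_person_days(cohort_lines, cohort)
  hru <- summarize_hru(bundle$medical, periods, config)
  costs <- summarize_costs(bundle, periods, config)

  hsct_tab <- cohort[!is.na(hsct_date), .(patient_id, hsct_date)]
  hsct_events <- if (nrow(hsct_tab)) hsct_event_cost(bundle, hsct_tab, config)
                 else NULL
  costs_sens <- if (nrow(hsct_tab)) {
    summarize_costs(sensitivity_exclude_hsct(bundle, hsct_tab, config),
                    periods, config)
  } else costs

  attrition <- sel$attrition
  if (suppress) {
    thr <- config$suppression_threshold
    for (nm in c("drugs", "generations", "end_events"))
      line_summary[[nm]] <- apply_suppression(line_summary[[nm]], thr,
                                              group_col = "line_number")
    attrition <- apply_suppression(attrition, thr, count_col = "n_excluded",
                                   group_col = NULL)
  }

  report <- structure(list(
    attrition = attrition, cohort = cohort, lines = cohort_lines,
    line_summary = line_summary, sequences = sequences, baseline = baseline,
    periods = periods, hru = hru, costs = costs,
    costs_sensitivity = costs_sens, hsct_events = hsct_events,
    truth = truth, suppressed = suppress,
    manifest = list(
      payer = config$payer, n_input = nrow(bundle$patients),
      n_cohort = nrow(cohort),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), class = "cohort_report")

  if (!is.null(out_dir)) write_cohort_report(report, out_dir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", x$manifest$payer, "payer;",
      x$manifest$n_input, "patients in,", x$manifest$n_cohort,
      "in 3L+ cohort\n")
  invisible(x)
}

#' Write a cohort report's tables to CSV files
#'
#' @param report A `cohort_report` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_cohort_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, nm) if (!is.null(x) && is.data.frame(x))
    fwrite(x, file.path(dir, paste0(nm, ".csv")), dateTimeAs = "ISO")
  wr(report$attrition, "attrition")
  wr(report$cohort, "cohort")
  wr(report$lines, "lines")
  for (nm in names(report$line_summary))
    wr(report$line_summary[[nm]], paste0("line_summary_", nm))
  if (!is.null(report$sequences)) {
    wr(report$sequences$drug_sequences, "sequences_drug")
    wr(report$sequences$generation_sequences, "sequences_generation")
  }
  if (!is.null(report$baseline)) {
    wr(report$baseline$continuous, "baseline_continuous")
    wr(report$baseline$categorical, "baseline_categorical")
  }
  wr(report$periods, "periods")
  wr(report$hru, "hru")
  wr(report$costs, "costs")
  wr(report$costs_sensitivity, "costs_sensitivity")
  wr(report$hsct_events, "hsct_events")
  invisible(dir)
}
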