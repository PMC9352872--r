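# Line-of-therapy construction: hand-traced rule examples verified against
# the independent single-pass oracle, tie-break determinism, permutation
# invariance, and event filtering.

build_from_stream <- function(fills, terminals = NULL, obs_end = 600,
                              gap = 90L) {
  ev <- events_from_stream("P1", fills,
                           if (is.null(terminals)) NULL else terminals)
  build_lines(ev, stats::setNames(dday(obs_end), "P1"), gap)
}

test_that("a different-drug fill ends the line as a switch with supply-adjusted treatment-free time", {
  fills <- data.frame(date = c(0, 30, 60, 120),
                      drug = c("imatinib", "imatinib", "imatinib", "dasatinib"),
                      supply = 30L)
  ln <- build_from_stream(fills)
  expect_equal(nrow(ln), 2L)
  expect_equal(ln$drug, c("imatinib", "dasatinib"))
  ## line 2 runs off supply at day 150 with >= 90 claim-free days to the
  ## observation end, so it discontinues rather than being censored
  expect_equal(ln$end_event, c("switch", "discontinuation"))
  expect_equal(ln$end_date[1], dday(120))          # line ends at the new drug's fill
  expect_equal(ln$start_date[2], dday(120))        # next line starts the same day
  expect_equal(ln$treatment_free_days_to_next[1], 30)  # 120 - (60 + 30)
  ## oracle agreement
  or <- oracle_lines(fills, data.frame(), 600)
  expect_equal(ln$end_event, or$event)
  expect_equal(as.integer(ln$start_date) - as.integer(ANCHOR), or$start)
})

test_that("a >=90-day gap with resumption of the same drug is an interruption, not a new line", {
  fills <- data.frame(date = c(0, 200), drug = "imatinib", supply = 30L)
  ln <- build_from_stream(fills, obs_end = 400)
  expect_equal(nrow(ln), 1L)
  expect_equal(ln$interruption_count, 1L)
  expect_equal(ln$end_event, "discontinuation")
  expect_equal(ln$end_date, dday(230))             # supply end of the last fill
  or <- oracle_lines(fills, data.frame(), 400)
  expect_equal(or$event, "discontinuation")
  expect_equal(or$end, 230)
  expect_equal(or$interruptions, 1L)
  ## a sub-threshold gap is not an interruption
  ln2 <- build_from_stream(data.frame(date = c(0, 100), drug = "imatinib",
                                      supply = 30L), obs_end = 150)
  expect_equal(ln2$interruption_count, 0L)
})

test_that("HSCT and AP/BC chemotherapy terminate the line and all sequencing", {
  fills <- data.frame(date = c(0, 60), drug = c("imatinib", "dasatinib"),
                      supply = 30L)
  ln <- build_from_stream(fills, terminals = data.frame(date = 45, kind = "hsct"))
  ## the HSCT at day 45 pre-empts the dasatinib fill at day 60
  expect_equal(nrow(ln), 1L)
  expect_equal(ln$end_event, "hsct")
  expect_equal(ln$end_date, dday(45))
  ln2 <- build_from_stream(fills,
                           terminals = data.frame(date = 100, kind = "apbc_chemo"))
  expect_equal(ln2$end_event, c("switch", "apbc_chemo"))
  expect_equal(ln2$end_date[2], dday(100))
  ## same-day tie: hsct outranks apbc_chemo outranks the fill
  ln3 <- build_from_stream(
    data.frame(date = 0, drug = "imatinib", supply = 30L),
    terminals = data.frame(date = c(40, 40), kind = c("apbc_chemo", "hsct")))
  expect_equal(ln3$end_event, "hsct")
})

test_that("a line still on supply at the end of observation is censored there", {
  ln <- build_from_stream(data.frame(date = 0, drug = "imatinib", supply = 30L),
                          obs_end = 60)
  expect_equal(ln$end_event, "censored")
  expect_equal(ln$end_date, dday(60))
  expect_equal(ln$n_fills, 1L)
})

test_that("same-day fills of two drugs at a line start resolve by supply then alphabet", {
  f <- data.frame(date = c(0, 0), drug = c("nilotinib", "dasatinib"),
                  supply = c(90L, 30L))
  ln <- build_from_stream(f, obs_end = 400)
  expect_equal(ln$drug[1], "nilotinib")     # larger days supply wins
  f2 <- data.frame(date = c(0, 0), drug = c("nilotinib", "dasatinib"),
                   supply = c(30L, 30L))
  ln2 <- build_from_stream(f2, obs_end = 400)
  expect_equal(ln2$drug[1], "dasatinib")    # tie broken alphabetically
})

test_that("claim order never changes constructed lines", {
  fills <- random_fill_stream(25, seed = 77)
  terms <- data.frame(date = 580, kind = "hsct")
  base <- build_from_stream(fills, terms)
  for (s in 1:5) {
    set.seed(s)
    shuf <- fills[sample(nrow(fills)), ]
    expect_equal(build_from_stream(shuf, terms), base)
  }
})

test_that("random event streams match the single-pass oracle", {
  for (s in 1:20) {
    fills <- random_fill_stream(n_fills = sample(5:40, 1), seed = 1000 + s)
    terms <- if (s %% 3 == 0)
      data.frame(date = sample(300:650, 1),
                 kind = sample(c("hsct", "apbc_chemo"), 1)) else data.frame()
    ln <- build_from_stream(fills, if (nrow(terms)) terms else NULL,
                            obs_end = 700)
    or <- oracle_lines(fills, terms, 700)
    expect_equal(nrow(ln), nrow(or))
    expect_equal(ln$drug, or$drug)
    expect_equal(as.integer(ln$start_date) - as.integer(ANCHOR), or$start)
    expect_equal(as.integer(ln$end_date) - as.integer(ANCHOR), or$end)
    expect_equal(ln$end_event, or$event)
    expect_equal(ln$n_fills, or$n_fills)
    expect_equal(ln$interruption_count, or$interruptions)
  }
})

test_that("therapy events respect approval dates and drop non-line-defining drugs", {
  cfg <- study_config()
  ph <- rbind(
    mk_pharmacy("A", 0, "ponatinib"),     # 2013 anchor: fine
    mk_pharmacy("A", 30, "hydroxyurea"),
    mk_pharmacy("A", 60, "other"),
    mk_pharmacy("A", 90, "imatinib"))
  ph$fill_date[1] <- as.Date("2011-01-01")   # before ponatinib approval
  b <- claims_bundle(ph, mk_medical("A", 0, dx = "C92.10"),
                     mk_enrollment("A", -400, 400), mk_patient("A"))
  ev <- collect_therapy_events(b, cfg)
  expect_equal(ev$drug, "imatinib")       # ponatinib pre-approval, HU/other dropped
  ## omacetaxine via procedure-coded medical claim
  md <- rbind(mk_medical("A", 0, dx = "C92.10"),
              mk_medical("A", 50, px = "J9262"))
  b2 <- claims_bundle(mk_pharmacy("A", 0, "imatinib"), md,
                      mk_enrollment("A", -400, 400), mk_patient("A"))
  ev2 <- collect_therapy_events(b2, cfg)
  expect_true(any(ev2$drug == "omacetaxine" & ev2$kind == "therapy_fill"))
})

test_that("generation classification follows the 1G/2G/3G taxonomy", {
  expect_equal(classify_generation("imatinib"), "1G")
  expect_equal(classify_generation(c("dasatinib", "nilotinib", "bosutinib")),
               rep("2G", 3))
  expect_equal(classify_generation("ponatinib"), "3G")
  expect_equal(classify_generation("omacetaxine"), "other")
  expect_error(classify_generation("aspirin"), "unknown drug")
})

test_that("line summaries bucket durations as printed and partition the cohort", {
  cfg <- study_config()
  ## duration exactly 3.0 months sits in the <=3 bucket; >6 and >12 are
  ## cumulative
  mk_line <- function(id, months, nf = 2L) {
    days <- round(months * cfg$month_length_days)
    data.table::data.table(
      patient_id = id, line_number = 1L, drug = "imatinib",
      start_date = dday(0), end_date = dday(days),
      supply_end_date = dday(days), end_event = "censored", n_fills = nf,
      interruption_count = 0L, treatment_free_days_to_next = NA_real_)
  }
  ln <- rbind(mk_line("a", 3.0), mk_line("b", 4.5), mk_line("c", 7),
              mk_line("d", 14), mk_line("e", 0.5, nf = 1L))
  ov <- summarize_lines(ln, cfg)$overview
  expect_equal(ov$le3mo, 2L)          # 3.0 months and 0.5 months
  expect_equal(ov$gt3_le6mo, 1L)
  expect_equal(ov$gt6mo, 2L)          # 7 and 14
  expect_equal(ov$gt12mo, 1L)         # 14 only, a subset of >6
  expect_equal(ov$le3mo + ov$gt3_le6mo + ov$gt6mo, ov$n)
  expect_equal(ov$one_fill, 1L)
})

test_that("sequence frequencies normalise to one and match brute-force grouping", {
  sim <- generate_cohort(trajectory_spec(
    n_patients = 60, seed = 19,
    line_count_probs = c(`1` = 0, `2` = 0.5, `3` = 0.5, `4` = 0, `5` = 0, `6` = 0)))
  tl <- sim$truth$lines
  sf <- sequence_frequencies(tl, depth = 2L)
  expect_equal(sum(sf$drug_sequences$frequency), 1)
  expect_equal(sum(sf$generation_sequences$frequency), 1)
  ## brute-force recount
  wide <- data.table::dcast(tl[line_number <= 2], patient_id ~ line_number,
                            value.var = "drug")
  wide <- wide[!is.na(wide$`2`)]
  man <- table(paste(wide$`1`, "->", wide$`2`))
  got <- stats::setNames(sf$drug_sequences$n, sf$drug_sequences$drug_seq)
  expect_equal(got[sort(names(got))], c(man)[sort(names(man))],
               ignore_attr = TRUE)
  ## all same sequence -> frequency 1
  one <- tl[patient_id %in% tl[line_number == 2][drug == tl[line_number == 2]$drug[1]]$patient_id[1]]
  sf1 <- sequence_frequencies(one, 2L)
  expect_equal(sf1$drug_sequences$frequency, 1)
})
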