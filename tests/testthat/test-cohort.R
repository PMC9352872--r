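# Cohort selection: first-diagnosis detection, washout, follow-up windows,
# and the cascade's single-criterion behaviour.

test_that("first CML diagnosis is the earliest qualifying claim", {
  md <- rbind(mk_medical("A", 59, dx = "C92.10"),
              mk_medical("A", 14, dx = "C92.10"),
              mk_medical("A", 2, dx = "I10"))
  got <- first_cml_diagnosis(md, c("205.1", "C92.1"))
  expect_equal(got$first_cml_dx_date, dday(14))
  expect_equal(nrow(first_cml_diagnosis(mk_medical("A", 3, dx = "I10"),
                                        c("C92.1"))), 0L)
  ## brute-force scan over a random claim set
  set.seed(8)
  n <- 200
  md2 <- mk_medical(sample(c("A", "B"), n, replace = TRUE),
                    sample(0:1000, n, replace = TRUE),
                    dx = sample(c("C92.10", "C92.11", "I10", "E11.9"), n,
                                replace = TRUE))
  md2$end_date <- md2$start_date
  got2 <- first_cml_diagnosis(md2, "C92.1")
  for (id in got2$patient_id) {
    rows <- md2[md2$patient_id == id & startsWith(md2$diagnosis_codes, "C92.1"), ]
    expect_equal(got2[got2$patient_id == id]$first_cml_dx_date,
                 min(rows$start_date))
  }
})

test_that("washout requires clean therapy history and continuous coverage", {
  enr <- mk_enrollment("A", -400, 400)
  l1 <- dday(0)
  ## TKI fill 100 days before 1L start violates the washout
  expect_false(check_washout(dday(-100), l1, enr))
  ## clean window with continuous enrollment passes
  expect_true(check_washout(dday(c(0, 30)), l1, enr))
  ## fills outside the window are irrelevant
  expect_true(check_washout(dday(-200), l1, enr))
  ## an enrollment hole inside the window fails
  enr2 <- rbind(mk_enrollment("A", -400, -100), mk_enrollment("A", -50, 400))
  expect_false(check_washout(dday(integer(0)), l1, enr2))
  ## hydroxyurea is pretreatment: its dates are never passed as therapy
  b <- good_patient_bundle("A", pharmacy = rbind(
    mk_pharmacy("A", -100, "hydroxyurea"),
    mk_pharmacy("A", c(10, 40, 70, 100), "imatinib"),
    mk_pharmacy("A", 130, "dasatinib"),
    mk_pharmacy("A", 190, "nilotinib")))
  ev <- collect_therapy_events(b, study_config())
  expect_true(check_washout(ev[kind == "therapy_fill", date], dday(10), enr))
})

test_that("follow-up ends at the earliest candidate end", {
  fu <- define_follow_up(dday(0), dday(300), dday(500))
  expect_equal(fu$end, dday(300))
  fu2 <- define_follow_up(dday(0), dday(300), dday(500), hsct_date = dday(100))
  expect_equal(as.numeric(fu2$end - fu2$start), 100)
  ## zero-length window allowed; inverted window is a defect
  expect_equal(define_follow_up(dday(0), dday(0), dday(9))$end, dday(0))
  expect_error(define_follow_up(dday(10), dday(0), dday(9)), "precedes")
  ## randomized min over four candidates
  set.seed(3)
  for (i in 1:25) {
    ends <- dday(sample(0:500, 4))
    fu3 <- define_follow_up(dday(0), ends[1], ends[2], ends[3], ends[4])
    expect_equal(fu3$end, min(ends))
  }
})

test_that("each selection criterion excludes exactly the engineered patient", {
  cfg <- study_config()
  probe <- function(bundle) apply_selection(bundle, cfg)

  ## the reference patient survives everything
  sel <- probe(good_patient_bundle("A"))
  expect_equal(sel$cohort$patient_id, "A")
  expect_equal(sel$attrition$n_remaining, rep(1L, 10))
  expect_equal(sel$cohort$index_date, dday(190))
  expect_equal(sel$cohort$baseline_end, dday(189))

  ## (washout) an imatinib fill 100 days before 1L
  b <- good_patient_bundle("A", pharmacy = rbind(
    mk_pharmacy("A", -100, "imatinib"),
    good_patient_bundle("A")$pharmacy))
  ## the earlier fill becomes 1L start, so the patient violates the
  ## diagnosis-window criterion instead; engineer a washout-only failure via
  ## an enrollment hole
  b2 <- good_patient_bundle("A", enrollment = rbind(
    mk_enrollment("A", -600, -150), mk_enrollment("A", -120, 1500)))
  sel2 <- probe(b2)
  expect_equal(nrow(sel2$cohort), 0L)
  expect_equal(sel2$attrition[criterion %like% "Washout", n_excluded], 1L)

  ## (approval) dasatinib 1L dated before its approval
  ph <- rbind(mk_pharmacy("B", 0, "dasatinib"),
              mk_pharmacy("B", c(40, 80), "imatinib"),
              mk_pharmacy("B", 120, "nilotinib"))
  b3 <- good_patient_bundle("B", pharmacy = ph,
                            medical = mk_medical("B", 0, dx = "C92.10"),
                            enrollment = mk_enrollment("B", -600, 1500),
                            patients = mk_patient("B"))
  b3$pharmacy[, fill_date := fill_date - as.integer(dday(0) - as.Date("2006-06-01"))]
  b3$medical[, `:=`(start_date = start_date - as.integer(dday(0) - as.Date("2006-06-01")),
                    end_date = end_date - as.integer(dday(0) - as.Date("2006-06-01")))]
  b3$enrollment[, `:=`(start_date = start_date - as.integer(dday(0) - as.Date("2006-06-01")),
                       end_date = end_date - as.integer(dday(0) - as.Date("2006-06-01")))]
  sel3 <- probe(b3)
  ## the pre-approval dasatinib fill is not a therapy event, so 1L becomes
  ## imatinib 40 days later - still within the diagnosis window, but the
  ## washout now contains no claim; the patient fails only if nothing else
  ## qualifies. Line 3 no longer exists, so they drop at the 3L criterion.
  expect_equal(nrow(sel3$cohort), 0L)

  ## (remission) a remission code before 1L start
  b4 <- good_patient_bundle("A", medical = rbind(
    mk_medical("A", 0, dx = "C92.10"),
    mk_medical("A", 5, dx = "C92.11")))
  sel4 <- probe(b4)
  expect_equal(nrow(sel4$cohort), 0L)
  expect_equal(sel4$attrition[criterion %like% "remission", n_excluded], 1L)

  ## (clinical trial) a trial claim before the index date
  b5 <- good_patient_bundle("A", medical = rbind(
    mk_medical("A", 0, dx = "C92.10"),
    mk_medical("A", 100, dx = "Z00.6")))
  sel5 <- probe(b5)
  expect_equal(sel5$attrition[criterion %like% "trial", n_excluded], 1L)
  ## ... but a trial claim after the index is harmless
  b6 <- good_patient_bundle("A", medical = rbind(
    mk_medical("A", 0, dx = "C92.10"),
    mk_medical("A", 400, dx = "Z00.6")))
  expect_equal(nrow(probe(b6)$cohort), 1L)

  ## (diagnosis window) 1L more than 91 days after the first diagnosis
  b7 <- good_patient_bundle("A", medical = mk_medical("A", -120, dx = "C92.10"))
  sel7 <- probe(b7)
  expect_equal(sel7$attrition[criterion %like% "within", n_excluded], 1L)

  ## (adult) a minor at 1L
  b8 <- good_patient_bundle("A", patients = mk_patient("A", birth_year = 2000L))
  expect_equal(probe(b8)$attrition[criterion %like% "Adult", n_excluded], 1L)

  ## (3L) only two lines
  b9 <- good_patient_bundle("A", pharmacy = rbind(
    mk_pharmacy("A", c(10, 40), "imatinib"),
    mk_pharmacy("A", c(70, 100, 130, 160, 190, 220, 250), "dasatinib")))
  sel9 <- probe(b9)
  expect_equal(sel9$attrition[criterion %like% "third line", n_excluded], 1L)
})

test_that("medicare-only criteria: HMO exclusion and the death waiver", {
  cfgm <- study_config("medicare")
  ## HMO coverage during the continuous-enrollment interval excludes
  b <- good_patient_bundle("A",
    enrollment = rbind(mk_enrollment("A", -600, 100),
                       mk_enrollment("A", 101, 200, hmo = TRUE),
                       mk_enrollment("A", 201, 1500)),
    patients = mk_patient("A", payer = "medicare"))
  sel <- apply_selection(b, cfgm)
  expect_equal(sel$attrition[criterion %like% "HMO", n_excluded], 1L)

  ## death inside the 12-month post-diagnosis window waives that requirement
  ## (the patient still needs 3 lines, compressed before death)
  ph <- rbind(mk_pharmacy("C", c(10, 40), "imatinib"),
              mk_pharmacy("C", c(70, 100), "dasatinib"),
              mk_pharmacy("C", c(130, 160), "nilotinib"))
  bd <- good_patient_bundle("C", pharmacy = ph,
    medical = mk_medical("C", 0, dx = "C92.10;9863"),
    enrollment = mk_enrollment("C", -600, 200),
    patients = mk_patient("C", payer = "medicare", death = dday(200)))
  seld <- apply_selection(bd, cfgm)
  expect_equal(nrow(seld$cohort), 1L)
  ## without the waiver (commercial), truncated enrollment excludes
  bc <- good_patient_bundle("C", pharmacy = ph,
    medical = mk_medical("C", 0, dx = "C92.10"),
    enrollment = mk_enrollment("C", -600, 200),
    patients = mk_patient("C"))
  selc <- apply_selection(bc, study_config())
  expect_equal(selc$attrition[criterion %like% "Continuous", n_excluded], 1L)
})

test_that("attrition is monotone, conserves counts, and ignores row order", {
  sim <- generate_cohort(trajectory_spec(n_patients = 120, seed = 14))
  cfg <- study_config()
  sel <- apply_selection(sim$bundle, cfg)
  at <- sel$attrition
  expect_true(all(diff(at$n_remaining) <= 0))
  expect_equal(at$n_remaining[1] - sum(at$n_excluded),
               at$n_remaining[nrow(at)])
  expect_true(all(sel$lines[patient_id %in% sel$cohort$patient_id,
                            .N, by = patient_id]$N >= 3))
  idx <- merge(sel$cohort[, .(patient_id, index_date)],
               sel$lines[line_number == 3L, .(patient_id, start_date)],
               by = "patient_id")
  expect_equal(idx$index_date, idx$start_date)

  shuffled <- sim$bundle
  set.seed(2)
  shuffled$pharmacy <- shuffled$pharmacy[sample(.N)]
  shuffled$medical <- shuffled$medical[sample(.N)]
  sel2 <- apply_selection(shuffled, cfg)
  expect_equal(sel2$attrition, sel$attrition)
  expect_equal(sort(sel2$cohort$patient_id), sort(sel$cohort$patient_id))
})

test_that("selection on a synthetic batch matches independent per-criterion filters", {
  sim <- generate_cohort(trajectory_spec(
    n_patients = 150, seed = 31,
    line_count_probs = c(`1` = .2, `2` = .2, `3` = .3, `4` = .2, `5` = .07,
                         `6` = .03)))
  cfg <- study_config()
  sel <- apply_selection(sim$bundle, cfg)
  ## independent oracle: intersect per-criterion sets computed from truth
  tp <- sim$truth$patients
  pts <- sim$bundle$patients
  ok_dx <- tp$patient_id                                     # all have a dx claim
  age <- merge(tp, pts, by = "patient_id")
  ok_adult <- age[as.integer(format(line1_start, "%Y")) - birth_year >= 18,
                  patient_id]
  ok_3l <- tp[n_lines >= 3, patient_id]
  ok_win <- tp[line1_start <= dx_date + 91, patient_id]
  expected <- Reduce(intersect, list(ok_dx, ok_adult, ok_3l, ok_win))
  expect_setequal(sel$cohort$patient_id, expected)
})
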