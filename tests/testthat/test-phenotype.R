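test_that("suspected infection pairing windows are honoured", {
  # antibiotics first: culture within 24 h qualifies, suspicion at the antibiotic
  expect_equal(detect_suspected_infection(0, 20), 0)
  expect_true(is.na(detect_suspected_infection(0, 30)))
  # culture first: antibiotics within 72 h qualify, suspicion at the culture
  expect_equal(detect_suspected_infection(71, 0), 0)
  expect_true(is.na(detect_suspected_infection(73, 0)))
  # boundary cases are inclusive; empty streams give none
  expect_equal(detect_suspected_infection(0, 24), 0)
  expect_equal(detect_suspected_infection(72, 0), 0)
  expect_true(is.na(detect_suspected_infection(numeric(), 5)))
  expect_true(is.na(detect_suspected_infection(5, numeric())))
  # earliest qualifying pair wins
  expect_equal(detect_suspected_infection(c(10, 50), c(12, 40)), 10)
})

test_that("multiple-antibiotic suspicion rule fires on the second dose", {
  expect_equal(detect_suspected_infection_abx2(c(2, 30)), 30)
  expect_true(is.na(detect_suspected_infection_abx2(c(2, 80))))
  expect_true(is.na(detect_suspected_infection_abx2(5)))
})

test_that("sepsis onset combines suspicion and the SOFA rise window", {
  # SOFA rise at 2 h, suspicion at 10 h -> onset at the earlier time
  tl <- make_timeline(antibiotics = 10, cultures = 12,
                      sofa = data.frame(t_hours = c(2, 26), score = c(4, 4)))
  ep <- detect_sepsis_onset(tl)
  expect_s3_class(ep, "sepsis_episode")
  expect_equal(ep$sofa_time, 2)
  expect_equal(ep$onset_time, 2)

  # SOFA time more than 12 h after suspicion: no episode
  tl2 <- make_timeline(antibiotics = 10, cultures = 12,
                       sofa = data.frame(t_hours = 40, score = 5))
  expect_null(detect_sepsis_onset(tl2))

  # first ICU SOFA of 2 at 1 h counts as a rise from the assumed pre-ICU zero
  tl3 <- make_timeline(antibiotics = 2, cultures = 4,
                       sofa = data.frame(t_hours = c(1, 30), score = c(2, 2)))
  expect_equal(detect_sepsis_onset(tl3)$sofa_time, 1)

  # a stable high score after the 24-h lookback has left admission: no rise
  tl4 <- make_timeline(antibiotics = 30, cultures = 32,
                       sofa = data.frame(t_hours = c(26, 40, 60), score = c(3, 3, 3)))
  expect_null(detect_sepsis_onset(tl4))
})

test_that("MDRD back-calculation matches the bisection oracle", {
  for (case in list(list(70, "M", "other"), list(40, "F", "white"),
                    list(55, "M", "black"), list(83, "F", "black"))) {
    expect_equal(mdrd_baseline_creatinine(case[[1]], case[[2]], case[[3]]),
                 mdrd_bisect(case[[1]], case[[2]], case[[3]]),
                 tolerance = 1e-6)
  }
  # 70-year-old non-Black male at eGFR 75 is just under 1 mg/dL
  expect_equal(mdrd_baseline_creatinine(70, "M", "white"), 0.99,
               tolerance = 0.01)
  # the 0.742 sex factor forces a lower creatinine at equal eGFR
  expect_lt(mdrd_baseline_creatinine(70, "F", "white"),
            mdrd_baseline_creatinine(70, "M", "white"))
  expect_error(mdrd_baseline_creatinine(NA, "M"), "required")
})

test_that("reference creatinine is min(baseline, first admission)", {
  tl <- make_timeline(prior = data.frame(t_hours = c(-4000, -3000, -2000),
                                         value = c(0.8, 1.0, 1.2)),
                      first_admission_value = 0.9)
  ref <- compute_reference_creatinine(tl)
  expect_equal(ref$baseline, 1.0)
  expect_equal(ref$first_admission, 0.9)
  expect_equal(ref$reference, 0.9)
  expect_identical(ref$baseline_source, "measured-median")

  # without priors the baseline comes from MDRD
  tl2 <- make_timeline(prior = NULL, age = 70, sex = "M", race = "white",
                       first_admission_value = 1.4)
  ref2 <- compute_reference_creatinine(tl2)
  expect_identical(ref2$baseline_source, "mdrd-imputed")
  expect_equal(ref2$baseline, mdrd_bisect(70, "M"), tolerance = 1e-6)
  expect_equal(ref2$reference, ref2$baseline)  # baseline < 1.4
})

test_that("KDIGO staging thresholds and the 48-h delta branch", {
  expect_identical(stage_creatinine(1.5, 1.0), 1L)   # boundary inclusive
  expect_identical(stage_creatinine(1.49, 1.0), 0L)
  expect_identical(stage_creatinine(2.0, 1.0), 2L)
  expect_identical(stage_creatinine(3.1, 1.0), 3L)
  expect_identical(stage_creatinine(4.0, 2.5), 3L)   # absolute 4.0 branch
  expect_identical(stage_creatinine(1.31, 1.0, delta48_met = TRUE), 1L)
  expect_identical(stage_creatinine(1.31, 1.0, delta48_met = FALSE), 0L)
  expect_error(stage_creatinine(-1, 1), "positive")

  # staging is monotone in the value and zero at the reference
  for (ref in c(0.6, 1.0, 1.8)) {
    vals <- seq(ref, 4 * ref, length.out = 80)
    st <- stage_creatinine(vals, ref)
    expect_identical(st[1], 0L)
    expect_true(all(diff(st) >= 0L))
  }
})

test_that("AKI detection fires on either criterion at the right time", {
  ref <- structure(list(baseline = 1, first_admission = 1, reference = 1,
                        baseline_source = "measured-median"),
                   class = "reference_creatinine")
  tl <- make_timeline(creatinine = data.frame(t_hours = c(0, 24),
                                              value = c(1.00, 1.31)))
  ep <- detect_aki(tl, ref)
  expect_equal(ep$onset_time, 24)
  expect_identical(ep$criterion_triggered, "delta-48h")
  expect_identical(ep$stage_at_onset, 1L)

  tl2 <- make_timeline(creatinine = data.frame(t_hours = c(0, 24),
                                               value = c(1.00, 1.25)))
  expect_null(detect_aki(tl2, ref))

  tl3 <- make_timeline(creatinine = data.frame(t_hours = c(0, 30),
                                               value = c(1.0, 3.2)))
  ep3 <- detect_aki(tl3, ref)
  expect_equal(ep3$onset_time, 30)
  expect_identical(ep3$stage_at_onset, 3L)
  expect_identical(ep3$max_stage, 3L)

  # ratio criterion only applies within 7 days of the window start
  tl4 <- make_timeline(creatinine = data.frame(t_hours = c(0, 200),
                                               value = c(1.0, 1.6)),
                       icu_discharge = 300)
  expect_null(detect_aki(tl4, ref))
})

test_that("cohort selection applies the ordered exclusion rules", {
  ok <- make_timeline(patient_id = "OK",
                      creatinine = data.frame(t_hours = c(2, 24, 48, 72),
                                              value = c(1.0, 1.6, 1.7, 1.6)))
  minor <- make_timeline(patient_id = "MINOR", age = 17)
  no_sepsis <- make_timeline(patient_id = "NOSEP", antibiotics = numeric())
  no_aki <- make_timeline(patient_id = "NOAKI")    # flat creatinine
  high_base <- make_timeline(patient_id = "BASE4",
                             prior = data.frame(t_hours = c(-4000, -3000, -2000),
                                                value = c(4.4, 4.5, 4.6)),
                             creatinine = data.frame(t_hours = c(2, 24),
                                                     value = c(4.5, 6.9)))
  early_death <- make_timeline(patient_id = "DIED90",
                               creatinine = data.frame(t_hours = c(2, 24, 48),
                                                       value = c(1.0, 1.6, 1.7)),
                               death_time = 90, icu_discharge = 90)
  eskd <- make_timeline(patient_id = "ESKD",
                        creatinine = data.frame(t_hours = c(2, 24),
                                                value = c(1.0, 1.6)),
                        flags = list(eskd = TRUE))
  preicu <- make_timeline(patient_id = "PREICU",
                          creatinine = data.frame(t_hours = c(-10, 2, 24),
                                                  value = c(1.8, 1.9, 2.0)))

  sel <- select_cohort(list(ok, minor, no_sepsis, no_aki, high_base,
                            early_death, eskd, preicu))
  expect_identical(sel$included, "OK")
  reasons <- stats::setNames(sel$ledger$reason, sel$ledger$patient_id)
  expect_identical(reasons[["MINOR"]], "age<18")
  expect_identical(reasons[["NOSEP"]], "no_sepsis_24h")
  expect_identical(reasons[["NOAKI"]], "no_aki_48h")
  expect_identical(reasons[["BASE4"]], "baseline_gt4")
  expect_identical(reasons[["DIED90"]], "exit_before_96h")
  expect_identical(reasons[["ESKD"]], "eskd_or_transplant")
  expect_identical(reasons[["PREICU"]], "preicu_aki")

  # idempotence and a complete ledger
  again <- select_cohort(list(ok, minor, no_sepsis, no_aki, high_base,
                              early_death, eskd, preicu))
  expect_identical(sel, again)
  expect_equal(length(sel$included) + nrow(sel$ledger), 8)
})

test_that("trajectories apply the percent-change formula and round-trip", {
  ref <- structure(list(reference = 0.8), class = "reference_creatinine")
  tl <- make_timeline(creatinine = data.frame(t_hours = c(2, 12, 40),
                                              value = c(0.8, 1.0, 1.6)))
  tr <- build_trajectory(tl, ref)
  expect_equal(tr$pct, c(0, 25, 100))
  expect_equal(tr$t_hours, c(2, 12, 40))

  # reconstruction returns the measured creatinine to machine precision
  rebuilt <- ref$reference * (1 + tr$pct / 100)
  expect_equal(rebuilt, c(0.8, 1.0, 1.6), tolerance = 1e-9)

  # fewer than two in-window points is an error
  tl2 <- make_timeline(creatinine = data.frame(t_hours = 2, value = 1))
  expect_error(build_trajectory(tl2, ref), "fewer than 2")
})

test_that("AKD and composite outcomes follow the day-7 and discharge rules", {
  ref <- structure(list(reference = 1.0), class = "reference_creatinine")
  aki <- structure(list(onset_time = 24, stage_at_onset = 1L, max_stage = 1L,
                        criterion_triggered = "delta-48h"),
                   class = "aki_episode")

  # survivor still 1.6x reference at day 7.2 after onset: AKD
  t7 <- 24 + 7.2 * 24
  tl <- make_timeline(creatinine = data.frame(t_hours = c(2, 24, t7),
                                              value = c(1.0, 1.4, 1.6)),
                      hospital_discharge = 500)
  out <- determine_outcomes(tl, ref, aki)
  expect_true(out$akd_day7)
  expect_true(out$composite7_event)
  expect_equal(out$composite7_time, 7)

  # recovered by day 7: no AKD, composite censored at 7 days
  tl2 <- make_timeline(creatinine = data.frame(t_hours = c(2, 24, t7),
                                               value = c(1.0, 1.4, 1.2)),
                       hospital_discharge = 500)
  out2 <- determine_outcomes(tl2, ref, aki)
  expect_false(out2$akd_day7)
  expect_false(out2$composite7_event)
  expect_equal(out2$composite7_time, 7)
  # discharge composite censored at discharge, no event (last value 1.2x)
  expect_false(out2$composite_discharge_event)
  expect_equal(out2$composite_discharge_time, (500 - 24) / 24)

  # death on day 3 after onset: composite event at 3 d, AKD undefined
  tl3 <- make_timeline(creatinine = data.frame(t_hours = c(2, 24),
                                               value = c(1.0, 1.4)),
                       death_time = 24 + 3 * 24, icu_discharge = 96.5,
                       hospital_discharge = 24 + 3 * 24)
  out3 <- determine_outcomes(tl3, ref, aki)
  expect_true(is.na(out3$akd_day7))
  expect_true(out3$composite7_event)
  expect_equal(out3$composite7_time, 3)
  expect_true(out3$composite_discharge_event)

  # survivor with no creatinine after day 7: indeterminate, flagged
  tl4 <- make_timeline(creatinine = data.frame(t_hours = c(2, 24),
                                               value = c(1.0, 1.4)),
                       hospital_discharge = 500)
  out4 <- determine_outcomes(tl4, ref, aki)
  expect_true(out4$akd_indeterminate)
  expect_true(is.na(out4$akd_day7))
})

test_that("noise-free synthetic phenotypes are recovered exactly", {
  base <- preset_published_classes()
  cfg <- generator_config(
    n_patients = 80, class_proportions = base$class_proportions,
    class_mean_params = base$class_mean_params,
    random_intercept_sd = 0, residual_sd = 0,
    outcome_model = base$outcome_model,
    event_model = list(frac_prior_creatinine = 1, frac_under18 = 0,
                       frac_eskd = 0, frac_krt = 0, frac_preicu_aki = 0,
                       frac_baseline_gt4 = 0, frac_early_exit = 0),
    seed = 17)
  co <- generate_cohort(cfg)
  ph <- phenotype_cohort(co)
  idx <- match(ph$cohort$patient_id, co$truth$patient_id)

  # the reference creatinine is recovered exactly (generator constructs it
  # with the same min(baseline, first admission) rule)
  expect_equal(ph$cohort$reference_creatinine, co$truth$reference[idx],
               tolerance = 1e-12)

  # severe-start classes are staged 3 at onset; every included patient's
  # trajectory reproduces the class mean exactly
  cls <- co$truth$true_class[idx]
  expect_true(all(ph$cohort$first_aki_stage[cls == 8] == 3L))
  expect_true(all(ph$cohort$max_aki_stage >= ph$cohort$first_aki_stage))
  for (pid in ph$cohort$patient_id[seq_len(10)]) {
    tr <- ph$trajectories[ph$trajectories$patient_id == pid, ]
    g <- co$truth$true_class[co$truth$patient_id == pid]
    mu <- drop(traj_basis_for_test(tr$t_hours) %*% cfg$class_mean_params[, g])
    expect_equal(tr$pct, mu, tolerance = 1e-9)
  }
})
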