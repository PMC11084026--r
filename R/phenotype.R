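#' One patient's clinical timeline
#'
#' Container for a patient's demographics, event streams and covariates. All
#' event times live on a single numeric axis of hours relative to ICU
#' admission (so `icu_admit = 0`, the hospital admission is at a negative
#' time, and prior-year creatinine is thousands of hours negative).
#'
#' @param patient_id identifier.
#' @param age years at admission.
#' @param sex `"M"` or `"F"`.
#' @param race one of `"white"`, `"black"`, `"hispanic"`, `"other"`.
#' @param icu_admit,icu_discharge,hospital_admit,hospital_discharge,death_time
#'   hours relative to ICU admission (`death_time` NA for survivors).
#' @param creatinine data.frame `t_hours`, `value` (mg/dL), in-hospital
#'   measurements (may include pre-ICU times).
#' @param antibiotics numeric vector of intravenous antibiotic start hours.
#' @param cultures numeric vector of culture collection hours.
#' @param sofa data.frame `t_hours`, `score`.
#' @param prior_creatinine data.frame `t_hours`, `value` from the 12 months
#'   before hospital admission, or NULL.
#' @param flags list of logical flags (`eskd`, `kidney_transplant`,
#'   `krt_first96h`, `is_first_icu_stay`).
#' @param covariates named list of adjustment covariates (labs, vasopressor
#'   use, nephrotoxin exposure, comorbidity indicators).
#' @return object of class `patient_timeline`.
#' @export
patient_timeline <- function(patient_id, age, sex, race,
                             icu_admit = 0, icu_discharge = NA_real_,
                             hospital_admit = NA_real_,
                             hospital_discharge = NA_real_,
                             death_time = NA_real_,
                             creatinine = data.frame(t_hours = numeric(),
                                                     value = numeric()),
                             antibiotics = numeric(),
                             cultures = numeric(),
                             sofa = data.frame(t_hours = numeric(),
                                               score = numeric()),
                             prior_creatinine = NULL,
                             flags = list(), covariates = list()) {
  if (nrow(creatinine) && any(creatinine$value <= 0))
    stop("creatinine values must be positive", call. = FALSE)
  if (!is.na(icu_discharge) && icu_discharge < icu_admit)
    stop("icu_admit must precede icu_discharge", call. = FALSE)
  flags$eskd <- isTRUE(flags$eskd)
  flags$kidney_transplant <- isTRUE(flags$kidney_transplant)
  flags$krt_first96h <- isTRUE(flags$krt_first96h)
  flags$is_first_icu_stay <- !isFALSE(flags$is_first_icu_stay)
  structure(list(
    patient_id = patient_id, age = age, sex = sex, race = race,
    icu_admit = icu_admit, icu_discharge = icu_discharge,
    hospital_admit = hospital_admit, hospital_discharge = hospital_discharge,
    death_time = death_time,
    creatinine = creatinine[order(creatinine$t_hours), , drop = FALSE],
    antibiotics = sort(antibiotics), cultures = sort(cultures),
    sofa = sofa[order(sofa$t_hours), , drop = FALSE],
    prior_creatinine = prior_creatinine,
    flags = flags, covariates = covariates
  ), class = "patient_timeline")
}

#' @export
print.patient_timeline <- function(x, ...) {
  cat(sprintf("Patient %s: %s, %d y, %s; %d creatinine draws, %d SOFA scores\n",
              x$patient_id, x$sex, as.integer(x$age), x$race,
              nrow(x$creatinine), nrow(x$sofa)))
  invisible(x)
}

#' Suspected infection time from antibiotic-culture co-occurrence
#'
#' A patient is suspected of infection at the earlier member of a qualifying
#' antibiotic-culture pair: when intravenous antibiotics come first, the
#' culture must be collected within 24 h; when the culture comes first, the
#' antibiotics must start within 72 h. Returns the earliest qualifying time,
#' or `NA` when no pair qualifies.
#'
#' @param antibiotics sorted numeric hours of antibiotic administration.
#' @param cultures sorted numeric hours of culture collection.
#' @param abx_first_window,culture_first_window pairing windows in hours
#'   (defaults 24 and 72).
#' @return suspicion time in hours, or `NA_real_`.
#' @export
detect_suspected_infection <- function(antibiotics, cultures,
                                       abx_first_window = 24,
                                       culture_first_window = 72) {
  if (!length(antibiotics) || !length(cultures)) return(NA_real_)
  best <- Inf
  for (a in antibiotics) {
    ok <- cultures[cultures >= a & cultures - a <= abx_first_window]
    if (length(ok)) best <- min(best, a)
    ok2 <- cultures[cultures < a & a - cultures <= culture_first_window]
    if (length(ok2)) best <- min(best, min(ok2))
  }
  if (is.finite(best)) best else NA_real_
}

#' Alternative suspicion rule for databases without reliable culture data
#'
#' Suspicion is declared at the time of the second distinct antibiotic
#' administration when it falls within `window` hours of the first; a
#' simplification of the multiple-antibiotic rule used for multicentre ICU
#' databases with sparse body-fluid sampling data.
#'
#' @param antibiotics sorted numeric hours.
#' @param window pairing window in hours (default 72).
#' @return suspicion time in hours, or `NA_real_`.
#' @export
detect_suspected_infection_abx2 <- function(antibiotics, window = 72) {
  if (length(antibiotics) < 2L) return(NA_real_)
  for (i in 2:length(antibiotics))
    if (antibiotics[i] - antibiotics[i - 1L] <= window) return(antibiotics[i])
  NA_real_
}

#' Sepsis onset under the Sepsis-3 rule
#'
#' The SOFA time is the first time at which the SOFA score has risen by 2 or
#' more within a trailing 24-h window, taking the pre-ICU score to be zero.
#' An episode is returned only when the SOFA time falls between 24 h before
#' and 12 h after the suspected infection time; the onset is the earlier of
#' the two.
#'
#' @param timeline a `patient_timeline`.
#' @param infection_rule `"abx_culture"` (default) or `"abx2"` for the
#'   multiple-antibiotic variant.
#' @return list of class `sepsis_episode` (`suspicion_time`, `sofa_time`,
#'   `onset_time`) or `NULL`.
#' @export
detect_sepsis_onset <- function(timeline, infection_rule = c("abx_culture", "abx2")) {
  infection_rule <- match.arg(infection_rule)
  susp <- switch(infection_rule,
    abx_culture = detect_suspected_infection(timeline$antibiotics, timeline$cultures),
    abx2 = detect_suspected_infection_abx2(timeline$antibiotics))
  if (is.na(susp)) return(NULL)

  s <- timeline$sofa
  if (!nrow(s)) return(NULL)
  sofa_time <- NA_real_
  for (i in seq_len(nrow(s))) {
    t_i <- s$t_hours[i]
    in_win <- s$t_hours >= t_i - 24 & s$t_hours <= t_i
    base <- min(s$score[in_win])
    if (t_i - 24 < timeline$icu_admit) base <- min(base, 0)  # assumed pre-ICU zero
    if (s$score[i] - base >= 2) { sofa_time <- t_i; break }
  }
  if (is.na(sofa_time)) return(NULL)
  if (sofa_time < susp - 24 || sofa_time > susp + 12) return(NULL)
  structure(list(suspicion_time = susp, sofa_time = sofa_time,
                 onset_time = min(susp, sofa_time)),
            class = "sepsis_episode")
}

#' Baseline creatinine by inverting the MDRD equation at eGFR 75
#'
#' Solves the 4-variable re-expressed MDRD equation
#' `eGFR = 175 * Scr^-1.154 * age^-0.203 * 0.742[female] * 1.212[Black]`
#' for the serum creatinine giving an eGFR of 75 mL/min/1.73 m^2; used to
#' impute a baseline when no prior-year creatinine exists.
#'
#' @param age years (>= 18).
#' @param sex `"M"` or `"F"`.
#' @param race race category; only `"black"` changes the coefficient.
#' @param egfr assumed eGFR (default 75).
#' @return creatinine in mg/dL.
#' @export
mdrd_baseline_creatinine <- function(age, sex, race = "other", egfr = 75) {
  if (is.na(age) || is.na(sex)) stop("age and sex required for MDRD imputation",
                                     call. = FALSE)
  f <- 175 * age^(-0.203)
  if (sex == "F") f <- f * 0.742
  if (race == "black") f <- f * 1.212
  (f / egfr)^(1 / 1.154)
}

#' Reference creatinine for a patient
#'
#' The baseline is the median prior-year creatinine when available, otherwise
#' the MDRD back-calculated value; the reference is the lower of the baseline
#' and the first creatinine of the hospital admission.
#'
#' @param timeline a `patient_timeline`.
#' @return list of class `reference_creatinine` with `baseline`,
#'   `baseline_source`, `first_admission`, `reference`.
#' @export
compute_reference_creatinine <- function(timeline) {
  prior <- timeline$prior_creatinine
  if (!is.null(prior) && nrow(prior)) {
    baseline <- stats::median(prior$value)
    src <- "measured-median"
  } else {
    baseline <- mdrd_baseline_creatinine(timeline$age, timeline$sex, timeline$race)
    src <- "mdrd-imputed"
  }
  ha <- if (is.na(timeline$hospital_admit)) -Inf else timeline$hospital_admit
  adm <- timeline$creatinine[timeline$creatinine$t_hours >= ha, , drop = FALSE]
  if (!nrow(adm)) stop("no admission creatinine available", call. = FALSE)
  first_adm <- adm$value[which.min(adm$t_hours)]
  structure(list(baseline = baseline, baseline_source = src,
                 first_admission = first_adm,
                 reference = min(baseline, first_adm)),
            class = "reference_creatinine")
}

#' KDIGO creatinine stage
#'
#' Stage 3 when the value reaches 3.0 times the reference or 4.0 mg/dL;
#' stage 2 at 2.0 times; stage 1 at 1.5 times or when a 0.3 mg/dL rise within
#' 48 h has been met; stage 0 otherwise. Vectorised over `value`.
#'
#' @param value creatinine, mg/dL.
#' @param reference reference creatinine, mg/dL.
#' @param delta48_met logical, whether the 0.3 mg/dL-in-48-h criterion holds
#'   at this measurement.
#' @return integer stage 0-3.
#' @export
stage_creatinine <- function(value, reference, delta48_met = FALSE) {
  if (any(value <= 0) || any(reference <= 0))
    stop("creatinine and reference must be positive", call. = FALSE)
  ratio <- value / reference
  stage <- integer(length(value))
  stage[ratio >= 1.5 | delta48_met] <- 1L
  stage[ratio >= 2.0] <- 2L
  stage[ratio >= 3.0 | value >= 4.0] <- 3L
  stage
}

#' Detect an AKI episode from the creatinine series
#'
#' AKI onset is the earliest measurement time at which either (a) the current
#' value exceeds the minimum value over the trailing 48 h by at least
#' 0.3 mg/dL, or (b) the current value reaches 1.5 times the reference within
#' 7 days of `window_start`. The stage at onset applies the KDIGO thresholds
#' at the onset measurement; the maximum stage scans the first 96 h after ICU
#' admission.
#'
#' @param timeline a `patient_timeline`.
#' @param ref a `reference_creatinine`.
#' @param window_start hour from which measurements are evaluated and the
#'   7-day ratio clock starts (default 0 = ICU admission; use
#'   `timeline$hospital_admit` to probe for pre-ICU AKI).
#' @return list of class `aki_episode` (`onset_time`, `stage_at_onset`,
#'   `max_stage`, `criterion_triggered`) or `NULL`.
#' @export
detect_aki <- function(timeline, ref, window_start = 0) {
  ha <- if (is.na(timeline$hospital_admit)) -Inf else timeline$hospital_admit
  cr <- timeline$creatinine
  cr <- cr[cr$t_hours >= ha, , drop = FALSE]
  eval_idx <- which(cr$t_hours >= window_start)
  if (!length(eval_idx)) return(NULL)

  delta_met <- function(j) {
    w <- cr$value[cr$t_hours >= cr$t_hours[j] - 48 & cr$t_hours <= cr$t_hours[j]]
    cr$value[j] - min(w) >= 0.3
  }
  onset <- NA_real_; crit <- NA_character_; onset_j <- NA_integer_
  for (j in eval_idx) {
    d <- delta_met(j)
    r <- cr$value[j] >= 1.5 * ref$reference &&
      cr$t_hours[j] - window_start <= 7 * 24
    if (d || r) {
      onset <- cr$t_hours[j]
      crit <- if (d) "delta-48h" else "ratio-7d"
      onset_j <- j
      break
    }
  }
  if (is.na(onset)) return(NULL)

  stage_at_onset <- stage_creatinine(cr$value[onset_j], ref$reference,
                                     delta48_met = delta_met(onset_j))
  in96 <- which(cr$t_hours >= 0 & cr$t_hours <= 96)
  max_stage <- stage_at_onset
  if (length(in96)) {
    stages <- vapply(in96, function(j)
      stage_creatinine(cr$value[j], ref$reference, delta48_met = delta_met(j)),
      integer(1))
    max_stage <- max(max_stage, stages)
  }
  structure(list(onset_time = onset, stage_at_onset = stage_at_onset,
                 max_stage = max_stage, criterion_triggered = crit),
            class = "aki_episode")
}

#' Percent-change creatinine trajectory over the first 96 h
#'
#' One point per creatinine measurement in the window, with
#' `pct = 100 * (creatinine - reference) / reference`; no interpolation.
#'
#' @param timeline a `patient_timeline`.
#' @param ref a `reference_creatinine`.
#' @param window_hours trajectory window (default 96).
#' @return data.frame of class `trajectory_series`: `patient_id`, `t_hours`,
#'   `pct`.
#' @export
build_trajectory <- function(timeline, ref, window_hours = 96) {
  cr <- timeline$creatinine
  cr <- cr[cr$t_hours >= 0 & cr$t_hours <= window_hours, , drop = FALSE]
  if (nrow(cr) < 2L)
    stop(sprintf("patient %s has fewer than 2 creatinine values in [0, %g] h",
                 timeline$patient_id, window_hours), call. = FALSE)
  out <- data.frame(patient_id = timeline$patient_id, t_hours = cr$t_hours,
                    pct = 100 * (cr$value - ref$reference) / ref$reference,
                    stringsAsFactors = FALSE)
  class(out) <- c("trajectory_series", "data.frame")
  out
}

#' Acute kidney disease and composite outcomes
#'
#' AKD at day 7 is continued fulfilment of the 1.5x-reference ratio criterion
#' in a patient alive 7 days after AKI onset, assessed on the first
#' creatinine in days 7-8 after onset (looking forward to day 10 before
#' declaring the outcome indeterminate). The 7-day composite counts deaths
#' before day 7 as events at the death time and AKD as an event at day 7; the
#' discharge composite re-assesses AKD on the last creatinine before hospital
#' discharge, with in-hospital death an event at the death time. Times are in
#' days since AKI onset.
#'
#' @param timeline a `patient_timeline`.
#' @param ref a `reference_creatinine`.
#' @param aki an `aki_episode`.
#' @return list of class `outcome_record`.
#' @export
determine_outcomes <- function(timeline, ref, aki) {
  onset <- aki$onset_time
  death <- timeline$death_time
  dis <- timeline$hospital_discharge
  cr <- timeline$creatinine
  day7 <- onset + 7 * 24

  akd <- NA; indeterminate <- FALSE
  died_before_7 <- !is.na(death) && death < day7
  if (!died_before_7) {
    w <- cr[cr$t_hours >= day7 & cr$t_hours <= day7 + 24, , drop = FALSE]
    if (!nrow(w))
      w <- cr[cr$t_hours > day7 + 24 & cr$t_hours <= onset + 10 * 24, , drop = FALSE]
    if (nrow(w)) {
      akd <- w$value[which.min(w$t_hours)] >= 1.5 * ref$reference
    } else indeterminate <- TRUE
  }

  comp7_event <- NA; comp7_time <- NA_real_
  if (died_before_7) {
    comp7_event <- TRUE; comp7_time <- (death - onset) / 24
  } else if (!indeterminate) {
    comp7_event <- isTRUE(akd); comp7_time <- 7
  }

  death_in_hosp <- !is.na(death)
  compd_event <- NA; compd_time <- NA_real_
  if (death_in_hosp) {
    compd_event <- TRUE; compd_time <- (death - onset) / 24
  } else if (!is.na(dis)) {
    before_dis <- cr[cr$t_hours >= 0 & cr$t_hours <= dis, , drop = FALSE]
    if (nrow(before_dis)) {
      akd_dis <- before_dis$value[which.max(before_dis$t_hours)] >= 1.5 * ref$reference
      compd_event <- akd_dis
      compd_time <- (dis - onset) / 24
    }
  }

  structure(list(patient_id = timeline$patient_id,
                 akd_day7 = akd, akd_indeterminate = indeterminate,
                 death_in_hospital = death_in_hosp,
                 composite7_event = comp7_event, composite7_time = comp7_time,
                 composite_discharge_event = compd_event,
                 composite_discharge_time = compd_time),
            class = "outcome_record")
}

# ordered inclusion/exclusion rules; returns NA when the patient passes,
# otherwise the first failing rule's label
exclusion_reason <- function(timeline, infection_rule = "abx_culture") {
  if (timeline$age < 18) return("age<18")
  sep <- detect_sepsis_onset(timeline, infection_rule)
  if (is.null(sep) || sep$onset_time > 24) return("no_sepsis_24h")
  ref <- compute_reference_creatinine(timeline)
  aki <- detect_aki(timeline, ref, window_start = 0)
  if (is.null(aki) || aki$onset_time > 48) return("no_aki_48h")
  if (timeline$flags$eskd || timeline$flags$kidney_transplant)
    return("eskd_or_transplant")
  if (ref$baseline > 4) return("baseline_gt4")
  ha <- if (is.na(timeline$hospital_admit)) -Inf else timeline$hospital_admit
  pre <- timeline$creatinine[timeline$creatinine$t_hours >= ha &
                               timeline$creatinine$t_hours < 0, , drop = FALSE]
  if (nrow(pre) && any(pre$value >= 1.5 * ref$reference)) return("preicu_aki")
  if (timeline$flags$krt_first96h) return("krt_96h")
  exits <- c(timeline$icu_discharge, timeline$death_time)
  exits <- exits[!is.na(exits)]
  if (length(exits) && min(exits) < 96) return("exit_before_96h")
  if (!timeline$flags$is_first_icu_stay) return("not_first_icu_stay")
  NA_character_
}

#' Apply the cohort inclusion and exclusion rules
#'
#' In order: adult age; sepsis onset within 24 h of ICU admission; AKI onset
#' within 48 h; then the exclusions (ESKD or prior kidney transplant, known
#' baseline creatinine above 4 mg/dL, AKI before ICU admission, kidney
#' replacement therapy in the first 96 h, discharge or death before 96 h) and
#' first-ICU-stay restriction. One reason - the first failing rule - is
#' recorded per excluded patient.
#'
#' @param patients list of `patient_timeline`.
#' @param infection_rule passed to [detect_sepsis_onset()].
#' @return list with `included` (character ids) and `ledger` (data.frame
#'   `patient_id`, `reason`).
#' @export
select_cohort <- function(patients, infection_rule = "abx_culture") {
  reasons <- vapply(patients, exclusion_reason, character(1),
                    infection_rule = infection_rule)
  ids <- vapply(patients, function(p) as.character(p$patient_id), character(1))
  list(included = ids[is.na(reasons)],
       ledger = data.frame(patient_id = ids[!is.na(reasons)],
                           reason = reasons[!is.na(reasons)],
                           stringsAsFactors = FALSE))
}

#' Phenotype a cohort end to end
#'
#' Runs sepsis detection, reference creatinine computation, AKI detection,
#' cohort selection, outcome determination and trajectory construction for
#' every patient, returning the analysis-ready tables.
#'
#' @param patients list of `patient_timeline` (or a `synthetic_cohort`).
#' @param infection_rule passed to [detect_sepsis_onset()].
#' @param window_hours trajectory window (default 96).
#' @return list with `cohort` (one row per included patient: demographics,
#'   reference creatinine, sepsis/AKI fields, outcomes, covariates),
#'   `trajectories` (long data.frame `patient_id`, `t_hours`, `pct`) and
#'   `ledger` (exclusions).
#' @export
phenotype_cohort <- function(patients, infection_rule = "abx_culture",
                             window_hours = 96) {
  if (inherits(patients, "synthetic_cohort")) patients <- patients$patients
  sel <- select_cohort(patients, infection_rule)
  keep <- patients[vapply(patients, function(p)
    as.character(p$patient_id) %in% sel$included, logical(1))]

  rows <- list(); trajs <- list()
  for (p in keep) {
    ref <- compute_reference_creatinine(p)
    sep <- detect_sepsis_onset(p, infection_rule)
    aki <- detect_aki(p, ref, window_start = 0)
    out <- determine_outcomes(p, ref, aki)
    tr <- build_trajectory(p, ref, window_hours)
    trajs[[length(trajs) + 1L]] <- tr
    cv <- p$covariates
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = as.character(p$patient_id),
      age = p$age, sex = p$sex, race = p$race,
      baseline_creatinine = ref$baseline, baseline_source = ref$baseline_source,
      reference_creatinine = ref$reference,
      sepsis_onset_h = sep$onset_time,
      aki_onset_h = aki$onset_time,
      first_aki_stage = aki$stage_at_onset, max_aki_stage = aki$max_stage,
      akd_day7 = out$akd_day7, akd_indeterminate = out$akd_indeterminate,
      death_in_hospital = out$death_in_hospital,
      composite7_event = out$composite7_event,
      composite7_time = out$composite7_time,
      composite_discharge_event = out$composite_discharge_event,
      composite_discharge_time = out$composite_discharge_time,
      sofa_max = if (nrow(p$sofa)) max(p$sofa$score) else NA_real_,
      hemoglobin = cv$hemoglobin %||% NA_real_,
      wbc = cv$wbc %||% NA_real_, lactate = cv$lactate %||% NA_real_,
      albumin = cv$albumin %||% NA_real_,
      vasopressor = cv$vasopressor %||% NA,
      vasopressor_hours = cv$vasopressor_hours %||% NA_real_,
      nephrotoxin = cv$nephrotoxin %||% NA,
      diabetes = cv$diabetes %||% NA, chf = cv$chf %||% NA,
      arrhythmia = cv$arrhythmia %||% NA,
      chronic_lung_disease = cv$chronic_lung_disease %||% NA,
      liver_disease = cv$liver_disease %||% NA,
      stringsAsFactors = FALSE
    )
  }
  cohort <- if (length(rows)) do.call(rbind, rows) else data.frame()
  trajectories <- if (length(trajs)) do.call(rbind, trajs) else
    data.frame(patient_id = character(), t_hours = numeric(), pct = numeric())
  rownames(cohort) <- rownames(trajectories) <- NULL
  list(cohort = cohort, trajectories = trajectories, ledger = sel$ledger)
}
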