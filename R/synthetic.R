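#' Configuration for the synthetic ICU cohort generator
#'
#' Defines the ground truth of a simulated cohort of critically ill patients
#' with sepsis-associated AKI: the latent trajectory classes (mean
#' percent-change curves in serum creatinine over the first 96 h of ICU stay),
#' the between-patient and residual variability, the creatinine sampling rate,
#' the class-dependent outcome model, and the clinical event streams that feed
#' the rule-based phenotyping.
#'
#' @param n_patients number of patients to simulate.
#' @param class_proportions probability vector, one entry per latent class;
#'   must sum to 1 and be strictly positive.
#' @param class_mean_params numeric matrix, one column per class, rows are
#'   polynomial coefficients of the class mean percent-change curve in
#'   normalised time `u = t/96` (so row 1 is the mean percent change at ICU
#'   admission).
#' @param random_intercept_sd SD (percent points) of the patient-level random
#'   intercept shifting the whole trajectory.
#' @param residual_sd SD (percent points) of independent measurement noise.
#' @param measurement_rate expected creatinine draws per 24 h (a Poisson
#'   process over the 96-h window; one draw in hours 0-6 is always added so an
#'   admission value exists).
#' @param outcome_model list with `akd_base_logodds` (log-odds of acute kidney
#'   disease in class 1), `akd_log_or` (per-class log odds ratios vs class 1),
#'   `hazard_base` (baseline death hazard per day), `hazard_mult` (per-class
#'   hazard multipliers), `akd_discharge_agreement` (probability that
#'   discharge AKD status equals day-7 status).
#' @param event_model list of rates/fractions controlling the clinical event
#'   streams: `frac_sepsis`, `frac_prior_creatinine`, `frac_under18`,
#'   `frac_eskd`, `frac_krt`, `frac_preicu_aki`, `frac_baseline_gt4`,
#'   `frac_early_exit`.
#' @param seed integer seed; the generator is fully reproducible given the
#'   config.
#' @return object of class `generator_config`.
#' @seealso [preset_published_classes()] for the calibrated eight-class default.
#' @export
generator_config <- function(n_patients,
                             class_proportions,
                             class_mean_params,
                             random_intercept_sd = 8,
                             residual_sd = 10,
                             measurement_rate = 2,
                             outcome_model = NULL,
                             event_model = NULL,
                             seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1)
    stop_config("n_patients must be a positive count")
  p <- as.numeric(class_proportions)
  if (abs(sum(p) - 1) > 1e-12 || any(p <= 0))
    stop_config("class_proportions must be strictly positive and sum to 1")
  class_mean_params <- as.matrix(class_mean_params)
  G <- length(p)
  if (ncol(class_mean_params) != G)
    stop_config("class_mean_params must have one column per class")
  if (residual_sd < 0) stop_config("residual_sd must be >= 0")
  if (random_intercept_sd < 0) stop_config("random_intercept_sd must be >= 0")
  if (measurement_rate <= 0) stop_config("measurement_rate must be > 0")

  om <- outcome_model %||% list()
  om$akd_base_logodds <- om$akd_base_logodds %||% stats::qlogis(0.06)
  om$akd_log_or <- om$akd_log_or %||% rep(0, G)
  om$hazard_base <- om$hazard_base %||% 0.0036
  om$hazard_mult <- om$hazard_mult %||% rep(1, G)
  om$akd_discharge_agreement <- om$akd_discharge_agreement %||% 0.9
  if (length(om$akd_log_or) != G || length(om$hazard_mult) != G)
    stop_config("outcome_model per-class vectors must have length %d", G)

  em <- event_model %||% list()
  em$frac_sepsis <- em$frac_sepsis %||% 0.95
  em$frac_prior_creatinine <- em$frac_prior_creatinine %||% 0.70
  em$frac_under18 <- em$frac_under18 %||% 0.01
  em$frac_eskd <- em$frac_eskd %||% 0.01
  em$frac_krt <- em$frac_krt %||% 0.01
  em$frac_preicu_aki <- em$frac_preicu_aki %||% 0.02
  em$frac_baseline_gt4 <- em$frac_baseline_gt4 %||% 0.005
  em$frac_early_exit <- em$frac_early_exit %||% 0.04

  structure(list(
    n_patients = as.integer(n_patients),
    class_proportions = p,
    class_mean_params = class_mean_params,
    random_intercept_sd = random_intercept_sd,
    residual_sd = residual_sd,
    measurement_rate = measurement_rate,
    outcome_model = om,
    event_model = em,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  patients: %d   classes: %d   seed: %d\n",
              x$n_patients, length(x$class_proportions), x$seed))
  cat("  class proportions:", paste(format(x$class_proportions, digits = 3),
                                    collapse = " "), "\n")
  cat(sprintf("  random intercept SD %.1f, residual SD %.1f pct points; %.1f draws/24h\n",
              x$random_intercept_sd, x$residual_sd, x$measurement_rate))
  invisible(x)
}

#' Eight-class preset calibrated to the published trajectory phenotypes
#'
#' Returns a [generator_config()] whose eight mean curves reproduce the
#' qualitative creatinine-trajectory phenotypes reported for sepsis-associated
#' AKI: transient AKI with a minor admission nadir and a day 2-3 stage-1 peak
#' (class 1), minor transient AKI peaking on day 1 (class 2), early mild AKI
#' with persistence (class 3) or recovery (class 4), late mild AKI with
#' persistence (class 5) or sustained worsening (class 6), moderate AKI with
#' persistence (class 7), and severe AKI starting in stage-3 territory with a
#' small sustained decline (class 8). Class-specific AKD odds ratios and death
#' hazard multipliers are rank-ordered so that the persistent/severe classes
#' carry the highest risk.
#'
#' Mean curves are cubic polynomials through control points at 0, 32, 64 and
#' 96 h; percent change is relative to the reference creatinine, so +50%,
#' +100% and +200% correspond to the KDIGO stage 1/2/3 ratio thresholds.
#'
#' @param n_patients cohort size (default 2000).
#' @param seed integer seed stored in the config.
#' @return object of class `generator_config` with 8 classes.
#' @export
preset_published_classes <- function(n_patients = 2000, seed = 1L) {
  # control values (percent change) at t = 0, 32, 64, 96 h
  controls <- cbind(
    c(-5,  30,  60,  20),   # 1 transient: nadir, stage-1 peak day 2-3, recovery
    c(-5,  40,  15,   0),   # 2 minor transient: peak day 1, recovery
    c(55,  90,  75,  60),   # 3 early mild, persistence
    c(55,  35,  20,  10),   # 4 early mild, recovery
    c(20,  60,  75,  55),   # 5 late mild, peak day 2, persistence
    c(30,  60, 100, 150),   # 6 late mild, sustained worsening
    c(110, 190, 230, 185),  # 7 moderate, stage 2-3 peak day 2-3, persistence
    c(230, 210, 195, 185)   # 8 severe: stage 3 at admission, small decline
  )
  beta <- apply(controls, 2L, poly_through_controls)
  props <- c(0.235, 0.06, 0.17, 0.08, 0.22, 0.07, 0.10, 0.065)
  # AKD odds ratios vs class 1 and death hazard multipliers, rank-ordered to
  # the published association tables (class 8 highest AKD risk, class 6
  # highest composite risk)
  akd_or <- c(1, 0.99, 3.99, 1.30, 2.52, 7.11, 5.59, 9.02)
  hr_mult <- c(1, 0.99, 2.31, 0.85, 1.92, 4.98, 3.02, 3.38)
  generator_config(
    n_patients = n_patients,
    class_proportions = props,
    class_mean_params = beta,
    random_intercept_sd = 8,
    residual_sd = 10,
    measurement_rate = 2,
    outcome_model = list(
      akd_base_logodds = stats::qlogis(0.06),
      akd_log_or = log(akd_or),
      hazard_base = 0.0036,
      hazard_mult = hr_mult,
      akd_discharge_agreement = 0.9
    ),
    seed = seed
  )
}

#' Evaluate the configured class mean curves
#'
#' @param config a `generator_config`.
#' @param t_hours times (hours since ICU admission) at which to evaluate.
#' @return matrix, rows = times, one column per class, percent change.
#' @export
class_mean_curves <- function(config, t_hours = seq(0, 96, by = 1)) {
  X <- traj_basis(t_hours, nrow(config$class_mean_params) - 1L)
  m <- X %*% config$class_mean_params
  rownames(m) <- t_hours
  colnames(m) <- paste0("class", seq_len(ncol(m)))
  m
}

#' Simulate class-dependent outcomes
#'
#' Draws the acute-kidney-disease (AKD) flag from the configured per-class
#' log-odds and an in-hospital death time from a class-scaled exponential
#' hazard, censored at hospital discharge.
#'
#' @param labels integer vector of true class indices (1..G).
#' @param config a `generator_config`.
#' @param discharge_days hospital discharge times in days since ICU admission;
#'   drawn from the generator's length-of-stay model when `NULL`.
#' @param seed optional seed; when `NULL` the current RNG stream is used (as
#'   when called from [generate_cohort()]).
#' @return data.frame with columns `true_class`, `akd`, `akd_discharge`,
#'   `death_days` (NA when censored before death) and `discharge_days`.
#' @export
simulate_outcomes <- function(labels, config, discharge_days = NULL, seed = NULL) {
  G <- length(config$class_proportions)
  if (any(labels < 1L | labels > G)) stop_config("labels must lie in 1..%d", G)
  draw <- function() {
    n <- length(labels)
    om <- config$outcome_model
    p_akd <- stats::plogis(om$akd_base_logodds + om$akd_log_or[labels])
    akd <- stats::rbinom(n, 1L, p_akd) == 1L
    agree <- stats::rbinom(n, 1L, om$akd_discharge_agreement) == 1L
    akd_dis <- ifelse(agree, akd, !akd)
    rate <- om$hazard_base * om$hazard_mult[labels]
    death <- rep(Inf, n)
    pos <- rate > 0
    death[pos] <- stats::rexp(sum(pos), rate[pos])
    dd <- discharge_days
    if (is.null(dd)) {
      icu_los <- ifelse(stats::runif(n) < config$event_model$frac_early_exit,
                        stats::runif(n, 24, 95),
                        96 + stats::rlnorm(n, log(60), 0.8)) / 24
      dd <- icu_los + stats::rlnorm(n, log(5), 0.7)
    }
    death_days <- ifelse(death < dd, death, NA_real_)
    dd <- ifelse(is.na(death_days), dd, death_days)
    data.frame(true_class = labels, akd = akd, akd_discharge = akd_dis,
               death_days = death_days, discharge_days = dd)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic ICU cohort
#'
#' Simulates `n_patients` timelines whose creatinine series follow a latent
#' mixture of class mean curves (patient random intercept + Gaussian residual
#' on the percent-change scale), together with the demographics, covariates,
#' antibiotic/culture/SOFA event streams and outcome-consistent late
#' creatinine draws that the phenotyping rules consume. Event streams are
#' generated backwards from the intended phenotype: septic patients receive a
#' qualifying antibiotic-culture pair and an early SOFA rise, and a
#' configurable sliver of patients is constructed to trip each exclusion rule
#' (minors, ESKD, kidney replacement therapy, pre-ICU AKI, baseline
#' creatinine above 4 mg/dL, early discharge or death).
#'
#' The truth table records, per patient, the latent class, the reference
#' creatinine used to construct the measurements, the random intercept and the
#' simulated outcomes, so downstream recovery can be scored against the
#' generator.
#'
#' @param config a valid [generator_config()].
#' @return object of class `synthetic_cohort`: list with `patients` (list of
#'   `patient_timeline`), `truth` (data.frame) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  G <- length(config$class_proportions)
  em <- config$event_model
  deg <- nrow(config$class_mean_params) - 1L

  labels <- sample.int(G, n, replace = TRUE, prob = config$class_proportions)

  # demographics
  age <- pmin(pmax(round(stats::rnorm(n, 69, 13)), 18L), 99L)
  under18 <- stats::runif(n) < em$frac_under18
  age[under18] <- sample(10:17, sum(under18), replace = TRUE)
  sex <- ifelse(stats::runif(n) < 0.61, "M", "F")
  race <- sample(c("white", "black", "hispanic", "other"), n, replace = TRUE,
                 prob = c(0.69, 0.09, 0.03, 0.19))

  # reference creatinine truth, constructed with the same
  # min(baseline, first admission) rule the phenotyping applies
  has_prior <- stats::runif(n) < em$frac_prior_creatinine
  base_gt4 <- stats::runif(n) < em$frac_baseline_gt4
  baseline <- stats::rlnorm(n, log(1.0), 0.22)
  baseline[base_gt4] <- stats::runif(sum(base_gt4), 4.2, 6)
  baseline[!has_prior] <- vapply(which(!has_prior), function(i) {
    mdrd_baseline_creatinine(age[i], sex[i], race[i])
  }, numeric(1))
  preicu_aki <- stats::runif(n) < em$frac_preicu_aki
  hosp_admit <- -stats::runif(n, 2, 24)          # hours before ICU admission
  first_adm <- baseline * exp(abs(stats::rnorm(n, 0, 0.06)))
  first_adm[preicu_aki] <- baseline[preicu_aki] * stats::runif(sum(preicu_aki), 1.6, 2.2)
  reference <- pmin(baseline, first_adm)

  # flags
  eskd <- stats::runif(n) < em$frac_eskd
  ktx <- stats::runif(n) < 0.003
  krt <- stats::runif(n) < em$frac_krt
  septic <- stats::runif(n) < em$frac_sepsis

  # stay timing, then outcomes censored at the cohort's own discharge times
  icu_dis_h <- ifelse(stats::runif(n) < em$frac_early_exit,
                      stats::runif(n, 24, 95),
                      96 + stats::rlnorm(n, log(60), 0.8))
  hosp_dis_h <- icu_dis_h + stats::rlnorm(n, log(120), 0.7)
  out <- simulate_outcomes(labels, config, discharge_days = hosp_dis_h / 24)
  death_h <- ifelse(is.na(out$death_days), NA_real_, out$death_days * 24)
  icu_dis_h <- ifelse(!is.na(death_h), pmin(icu_dis_h, death_h), icu_dis_h)
  hosp_dis_h <- ifelse(!is.na(death_h), death_h, hosp_dis_h)

  b_i <- stats::rnorm(n, 0, config$random_intercept_sd)

  # covariate labs (some with missingness for the imputation stage)
  hemoglobin <- round(stats::rnorm(n, 8.6, 1.5), 1)
  wbc <- round(stats::rlnorm(n, log(15.4), 0.35), 1)
  lactate <- round(stats::rlnorm(n, log(2.4), 0.45), 1)
  albumin <- round(stats::rnorm(n, 2.9, 0.5), 1)
  wbc[stats::runif(n) < 0.05] <- NA
  lactate[stats::runif(n) < 0.15] <- NA
  albumin[stats::runif(n) < 0.50] <- NA     # exceeds the 40% filter
  vaso <- stats::runif(n) < 0.62
  vaso_hours <- ifelse(vaso, round(stats::rlnorm(n, log(21), 0.9), 1), 0)
  nephrotoxin <- stats::runif(n) < 0.34
  diabetes <- stats::runif(n) < 0.23
  chf <- stats::runif(n) < 0.23
  arrhythmia <- stats::runif(n) < 0.18
  lung <- stats::runif(n) < 0.15
  liver <- stats::runif(n) < 0.08

  ids <- sprintf("P%05d", seq_len(n))
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    end_h <- min(hosp_dis_h[i], death_h[i], na.rm = TRUE)

    # ICU creatinine sampling: guaranteed admission draw + Poisson schedule
    t0 <- stats::runif(1, 0, 6)
    k <- stats::rpois(1, config$measurement_rate / 24 * 96)
    tm <- sort(unique(c(t0, stats::runif(k, 0, 96))))
    keep <- tm <= end_h
    if (sum(keep) < 2L) keep[seq_len(min(2L, length(tm)))] <- TRUE
    tm <- tm[keep]
    if (length(tm) < 2L) tm <- sort(c(tm, stats::runif(1, 24, 96)))
    mu <- drop(traj_basis(tm, deg) %*% config$class_mean_params[, labels[i]])
    pct <- pmax(mu + b_i[i] + stats::rnorm(length(tm), 0, config$residual_sd), -95)
    cr <- data.frame(t_hours = tm, value = reference[i] * (1 + pct / 100))

    # pre-ICU: first hospital admission creatinine
    cr <- rbind(data.frame(t_hours = hosp_admit[i], value = first_adm[i]), cr)

    # post-96h draws consistent with the drawn AKD flags
    late <- c(173, 197, 221)
    late <- late[late < end_h]
    if (length(late)) {
      ratio <- if (out$akd[i]) stats::runif(length(late), 1.6, 2.4)
               else stats::runif(length(late), 0.85, 1.40)
      cr <- rbind(cr, data.frame(t_hours = late, value = reference[i] * ratio))
    }
    t_dis <- hosp_dis_h[i] - 12
    if (is.na(death_h[i]) && t_dis > 233) {
      ratio <- if (out$akd_discharge[i]) stats::runif(1, 1.6, 2.4)
               else stats::runif(1, 0.85, 1.40)
      cr <- rbind(cr, data.frame(t_hours = t_dis, value = reference[i] * ratio))
    }
    cr$value <- pmax(cr$value, 0.05)

    # prior-year creatinine: odd count with median exactly at the baseline
    prior <- NULL
    if (has_prior[i]) {
      eps <- abs(stats::rnorm(sample(1:2, 1), 0, 0.08))
      vals <- baseline[i] * c(1, exp(eps), exp(-eps))
      pt <- sort(stats::runif(length(vals), hosp_admit[i] - 8760, hosp_admit[i] - 24))
      prior <- data.frame(t_hours = pt, value = sample(vals))
    }

    # event streams: antibiotics / cultures / SOFA
    if (septic[i]) {
      if (stats::runif(1) < 0.7) {
        abx1 <- stats::runif(1, 0.5, 6); cult <- abx1 + stats::runif(1, 1, 20)
      } else {
        cult <- stats::runif(1, 0.5, 4); abx1 <- cult + stats::runif(1, 1, 48)
      }
      abx <- c(abx1, abx1 + stats::runif(2, 6, 48))
      sofa_t <- c(1, seq(12, 96, by = 12))
      s1 <- sample(2:8, 1, prob = 8:2)
      sofa_s <- pmax(0, c(s1, s1 + cumsum(sample(-2:2, 8, replace = TRUE))))
    } else {
      cult <- stats::runif(1, 1, 5)
      abx <- if (stats::runif(1) < 0.5) numeric(0) else cult + stats::runif(1, 75, 90)
      sofa_t <- c(1, seq(12, 96, by = 12))
      sofa_s <- sample(0:1, 9, replace = TRUE)
    }
    keep_s <- sofa_t <= end_h | seq_along(sofa_t) == 1L
    sofa <- data.frame(t_hours = sofa_t[keep_s], score = as.numeric(sofa_s[keep_s]))

    patients[[i]] <- patient_timeline(
      patient_id = ids[i], age = age[i], sex = sex[i], race = race[i],
      icu_admit = 0, icu_discharge = icu_dis_h[i],
      hospital_admit = hosp_admit[i], hospital_discharge = hosp_dis_h[i],
      death_time = death_h[i],
      creatinine = cr[order(cr$t_hours), , drop = FALSE],
      antibiotics = sort(abx), cultures = sort(cult), sofa = sofa,
      prior_creatinine = prior,
      flags = list(eskd = eskd[i], kidney_transplant = ktx[i],
                   krt_first96h = krt[i], is_first_icu_stay = TRUE),
      covariates = list(
        hemoglobin = hemoglobin[i], wbc = wbc[i], lactate = lactate[i],
        albumin = albumin[i], vasopressor = vaso[i],
        vasopressor_hours = vaso_hours[i], nephrotoxin = nephrotoxin[i],
        diabetes = diabetes[i], chf = chf[i], arrhythmia = arrhythmia[i],
        chronic_lung_disease = lung[i], liver_disease = liver[i]
      )
    )
  }

  truth <- data.frame(
    patient_id = ids, true_class = labels, reference = reference,
    baseline = baseline, random_intercept = b_i,
    akd = out$akd, akd_discharge = out$akd_discharge,
    death_days = out$death_days, discharge_days = hosp_dis_h / 24,
    stringsAsFactors = FALSE
  )

  structure(list(patients = patients, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ICU cohort: %d patients, %d latent classes (seed %d)\n",
              length(x$patients), length(x$config$class_proportions),
              x$config$seed))
  cat("  true class frequencies:",
      paste(table(factor(x$truth$true_class,
                         levels = seq_along(x$config$class_proportions))),
            collapse = " "), "\n")
  invisible(x)
}
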