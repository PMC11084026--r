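# CSV interchange: five long-format tables mirroring a relational ICU
# extract. Times are numeric hours relative to ICU admission.

cohort_schema <- list(
  schema = "akitraj-cohort-1",
  tables = list(
    patients = c("patient_id", "age", "sex", "race", "icu_admit",
                 "icu_discharge", "hospital_admit", "hospital_discharge",
                 "death_time", "eskd", "kidney_transplant", "krt_first96h",
                 "is_first_icu_stay", "hemoglobin", "wbc", "lactate",
                 "albumin", "vasopressor", "vasopressor_hours", "nephrotoxin",
                 "diabetes", "chf", "arrhythmia", "chronic_lung_disease",
                 "liver_disease"),
    creatinine = c("patient_id", "t_hours", "creatinine"),
    medications = c("patient_id", "t_hours", "medication"),
    cultures = c("patient_id", "t_hours"),
    sofa = c("patient_id", "t_hours", "sofa")
  )
)

#' Write a cohort to the long-format CSV tables
#'
#' Writes `patients.csv`, `creatinine.csv` (prior-year, pre-ICU and ICU
#' measurements on one time axis), `medications.csv` (intravenous
#' antibiotics), `cultures.csv` and `sofa.csv`, plus a versioned
#' `schema.json`. For a `synthetic_cohort` a `truth.json` sidecar with the
#' generator's labels and outcomes is written as well (for testing only - the
#' phenotyping never reads it).
#'
#' @param cohort a `synthetic_cohort` or plain list of `patient_timeline`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  patients <- if (inherits(cohort, "synthetic_cohort")) cohort$patients else cohort

  num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  prow <- lapply(patients, function(p) {
    cv <- p$covariates
    data.frame(patient_id = as.character(p$patient_id), age = p$age,
               sex = p$sex, race = p$race, icu_admit = p$icu_admit,
               icu_discharge = num(p$icu_discharge),
               hospital_admit = num(p$hospital_admit),
               hospital_discharge = num(p$hospital_discharge),
               death_time = num(p$death_time),
               eskd = p$flags$eskd, kidney_transplant = p$flags$kidney_transplant,
               krt_first96h = p$flags$krt_first96h,
               is_first_icu_stay = p$flags$is_first_icu_stay,
               hemoglobin = num(cv$hemoglobin), wbc = num(cv$wbc),
               lactate = num(cv$lactate), albumin = num(cv$albumin),
               vasopressor = isTRUE(cv$vasopressor),
               vasopressor_hours = num(cv$vasopressor_hours),
               nephrotoxin = isTRUE(cv$nephrotoxin),
               diabetes = isTRUE(cv$diabetes), chf = isTRUE(cv$chf),
               arrhythmia = isTRUE(cv$arrhythmia),
               chronic_lung_disease = isTRUE(cv$chronic_lung_disease),
               liver_disease = isTRUE(cv$liver_disease),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, prow), file.path(dir, "patients.csv"),
                   row.names = FALSE)

  cr <- do.call(rbind, lapply(patients, function(p) {
    main <- data.frame(patient_id = as.character(p$patient_id),
                       t_hours = p$creatinine$t_hours,
                       creatinine = p$creatinine$value)
    if (!is.null(p$prior_creatinine) && nrow(p$prior_creatinine))
      main <- rbind(data.frame(patient_id = as.character(p$patient_id),
                               t_hours = p$prior_creatinine$t_hours,
                               creatinine = p$prior_creatinine$value), main)
    main
  }))
  utils::write.csv(cr, file.path(dir, "creatinine.csv"), row.names = FALSE)

  med <- do.call(rbind, lapply(patients, function(p) {
    if (!length(p$antibiotics)) return(NULL)
    data.frame(patient_id = as.character(p$patient_id),
               t_hours = p$antibiotics, medication = "iv_antibiotic")
  }))
  utils::write.csv(med %||% data.frame(patient_id = character(),
                                       t_hours = numeric(),
                                       medication = character()),
                   file.path(dir, "medications.csv"), row.names = FALSE)

  cul <- do.call(rbind, lapply(patients, function(p) {
    if (!length(p$cultures)) return(NULL)
    data.frame(patient_id = as.character(p$patient_id), t_hours = p$cultures)
  }))
  utils::write.csv(cul %||% data.frame(patient_id = character(),
                                       t_hours = numeric()),
                   file.path(dir, "cultures.csv"), row.names = FALSE)

  sf <- do.call(rbind, lapply(patients, function(p) {
    if (!nrow(p$sofa)) return(NULL)
    data.frame(patient_id = as.character(p$patient_id),
               t_hours = p$sofa$t_hours, sofa = p$sofa$score)
  }))
  utils::write.csv(sf %||% data.frame(patient_id = character(),
                                      t_hours = numeric(), sofa = numeric()),
                   file.path(dir, "sofa.csv"), row.names = FALSE)

  jsonlite::write_json(cohort_schema, file.path(dir, "schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (inherits(cohort, "synthetic_cohort"))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         dataframe = "columns", digits = NA, na = "null")
  invisible(dir)
}

#' Read a cohort from the long-format CSV tables
#'
#' Inverse of [write_cohort()]: rebuilds one `patient_timeline` per row of
#' `patients.csv`. Creatinine rows earlier than the patient's hospital
#' admission are classified as prior-year baseline measurements.
#'
#' @param dir directory containing the five tables.
#' @return list of `patient_timeline`.
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  pat <- rd("patients.csv"); cr <- rd("creatinine.csv")
  med <- rd("medications.csv"); cul <- rd("cultures.csv"); sf <- rd("sofa.csv")

  cr_by <- split(cr, cr$patient_id)
  med_by <- split(med$t_hours, med$patient_id)
  cul_by <- split(cul$t_hours, cul$patient_id)
  sf_by <- split(sf, sf$patient_id)

  lapply(seq_len(nrow(pat)), function(i) {
    id <- as.character(pat$patient_id[i])
    crx <- cr_by[[id]]
    ha <- pat$hospital_admit[i]
    if (is.null(crx)) crx <- data.frame(t_hours = numeric(), creatinine = numeric())
    is_prior <- !is.na(ha) & crx$t_hours < ha
    sfx <- sf_by[[id]]
    patient_timeline(
      patient_id = id, age = pat$age[i], sex = pat$sex[i], race = pat$race[i],
      icu_admit = pat$icu_admit[i], icu_discharge = pat$icu_discharge[i],
      hospital_admit = ha, hospital_discharge = pat$hospital_discharge[i],
      death_time = pat$death_time[i],
      creatinine = data.frame(t_hours = crx$t_hours[!is_prior],
                              value = crx$creatinine[!is_prior]),
      antibiotics = med_by[[id]] %||% numeric(),
      cultures = cul_by[[id]] %||% numeric(),
      sofa = if (is.null(sfx)) data.frame(t_hours = numeric(), score = numeric())
             else data.frame(t_hours = sfx$t_hours, score = sfx$sofa),
      prior_creatinine = if (any(is_prior))
        data.frame(t_hours = crx$t_hours[is_prior],
                   value = crx$creatinine[is_prior]) else NULL,
      flags = list(eskd = pat$eskd[i], kidney_transplant = pat$kidney_transplant[i],
                   krt_first96h = pat$krt_first96h[i],
                   is_first_icu_stay = pat$is_first_icu_stay[i]),
      covariates = list(
        hemoglobin = pat$hemoglobin[i], wbc = pat$wbc[i],
        lactate = pat$lactate[i], albumin = pat$albumin[i],
        vasopressor = pat$vasopressor[i],
        vasopressor_hours = pat$vasopressor_hours[i],
        nephrotoxin = pat$nephrotoxin[i], diabetes = pat$diabetes[i],
        chf = pat$chf[i], arrhythmia = pat$arrhythmia[i],
        chronic_lung_disease = pat$chronic_lung_disease[i],
        liver_disease = pat$liver_disease[i]
      )
    )
  })
}
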