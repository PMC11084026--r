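#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the input (a generator
#' preset or a directory of CSV tables), the trajectory and AKI detection
#' windows, the class-count sweep, the imputation settings and the seed.
#'
#' @param preset `"published8"` (the calibrated eight-class generator) or `NULL`
#'   when `input_dir` is given.
#' @param input_dir directory with the five CSV tables (overrides `preset`).
#' @param n_patients cohort size when simulating (default 2000).
#' @param trajectory_window_hours trajectory window (default 96).
#' @param aki_window_hours AKI inclusion window after ICU admission
#'   (default 48).
#' @param g_range class counts to try (default 2:10).
#' @param n_starts EM starts per class count (default 5).
#' @param max_iter,tol EM controls.
#' @param m_imputations completed tables for the association stage.
#' @param adjusted also fit adjusted models (default TRUE).
#' @param seed integer seed recorded in every output.
#' @param outdir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "published8", input_dir = NULL,
                            n_patients = 2000, trajectory_window_hours = 96,
                            aki_window_hours = 48, g_range = 2:10,
                            n_starts = 5L, max_iter = 300L, tol = 1e-7,
                            m_imputations = 5L, adjusted = TRUE,
                            seed = 1L, outdir = "akitraj-run") {
  if (trajectory_window_hours <= 0 || aki_window_hours <= 0)
    stop_config("windows must be positive")
  if (!length(g_range)) stop_config("g_range must be non-empty")
  if (is.null(input_dir) && !identical(preset, "published8"))
    stop_config("unknown preset: %s", preset %||% "<null>")
  structure(list(preset = preset, input_dir = input_dir,
                 n_patients = n_patients,
                 trajectory_window_hours = trajectory_window_hours,
                 aki_window_hours = aki_window_hours,
                 g_range = as.integer(g_range), n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter), tol = tol,
                 m_imputations = as.integer(m_imputations),
                 adjusted = isTRUE(adjusted),
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the end-to-end analysis
#'
#' Executes, in order: cohort simulation (or CSV ingest), phenotyping,
#' trajectory construction, class-count selection by BIC, posterior class
#' assignment, and the class-versus-outcome association stage; every stage
#' writes its outputs under `config$outdir` and the run closes with a
#' manifest (`manifest.json`) holding the config snapshot, package version,
#' consort-style stage counts and md5 checksums of all outputs. A second run
#' with an identical config reproduces identical outputs; wall-clock timings
#' go to `run.log`, not the manifest.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (class `run_manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  t_start <- Sys.time()
  stage <- "simulate"
  manifest <- list(config = unclass(config),
                   package_version = as.character(utils::packageVersion("akitraj")),
                   counts = list(), outputs = list())

  result <- tryCatch({
    # -- simulate / ingest ------------------------------------------------
    data_dir <- config$input_dir
    if (is.null(data_dir)) {
      log_line(logf, "stage simulate: generating '", config$preset,
               "' cohort, n = ", config$n_patients)
      gen <- preset_published_classes(config$n_patients, seed = config$seed)
      cohort <- generate_cohort(gen)
      data_dir <- file.path(config$outdir, "data")
      write_cohort(cohort, data_dir)
      patients <- cohort$patients
    } else {
      log_line(logf, "stage simulate: reading tables from ", data_dir)
      patients <- read_cohort(data_dir)
    }
    manifest$counts$n_input <- length(patients)

    # -- phenotype --------------------------------------------------------
    stage <- "phenotype"
    log_line(logf, "stage phenotype: applying sepsis/AKI rules")
    ph <- phenotype_cohort(patients,
                           window_hours = config$trajectory_window_hours)
    ok48 <- ph$cohort$aki_onset_h <= config$aki_window_hours
    ph$cohort <- ph$cohort[ok48, , drop = FALSE]
    ph$trajectories <- ph$trajectories[
      ph$trajectories$patient_id %in% ph$cohort$patient_id, , drop = FALSE]
    utils::write.csv(ph$cohort, file.path(config$outdir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(ph$trajectories,
                     file.path(config$outdir, "trajectories.csv"),
                     row.names = FALSE)
    utils::write.csv(ph$ledger, file.path(config$outdir, "exclusions.csv"),
                     row.names = FALSE)
    manifest$counts$n_included <- nrow(ph$cohort)
    manifest$counts$n_excluded <- nrow(ph$ledger)
    manifest$counts$exclusions <- as.list(table(ph$ledger$reason))

    # -- fit --------------------------------------------------------------
    stage <- "fit"
    log_line(logf, "stage fit: LCMM sweep over G = ",
             paste(range(config$g_range), collapse = ".."))
    sel <- select_model(ph$trajectories, lcmm_spec(G = 2L),
                        G_range = config$g_range, n_starts = config$n_starts,
                        tol = config$tol, max_iter = config$max_iter,
                        seed = config$seed + 1L)
    utils::write.csv(sel$bic_table, file.path(config$outdir, "bic_table.csv"),
                     row.names = FALSE)
    write_lcmm_fit(sel$best_fit, file.path(config$outdir, "model.json"))
    asg <- assign_classes(sel$best_fit)
    utils::write.csv(asg$assignments,
                     file.path(config$outdir, "assignments.csv"),
                     row.names = FALSE)
    utils::write.csv(asg$discrimination, file.path(config$outdir, "mpcmp.csv"),
                     row.names = FALSE)
    utils::write.csv(marginal_trajectories(sel$best_fit),
                     file.path(config$outdir, "class_means.csv"),
                     row.names = FALSE)
    manifest$counts$selected_G <- sel$best_fit$spec$G
    manifest$counts$class_sizes <- as.list(stats::setNames(
      asg$discrimination$n, paste0("class", asg$discrimination$class)))

    # -- associate --------------------------------------------------------
    stage <- "associate"
    log_line(logf, "stage associate: outcome models")
    tab <- merge(ph$cohort, asg$assignments, by = "patient_id")
    flt <- filter_missingness(tab)
    imp <- impute_pmm(flt$table, m = config$m_imputations,
                      seed = config$seed + 2L)
    res <- list(fit_logistic_akd(imp, adjusted = FALSE))
    if (config$adjusted) res <- c(res, list(fit_logistic_akd(imp, adjusted = TRUE)))
    for (oc in c("composite7", "composite_discharge")) {
      res <- c(res, list(fit_cox_composite(imp, oc, adjusted = FALSE)))
      if (config$adjusted)
        res <- c(res, list(fit_cox_composite(imp, oc, adjusted = TRUE)))
    }
    assoc <- do.call(rbind, lapply(res, function(r)
      cbind(outcome = attr(r, "outcome"), effect = attr(r, "effect"),
            adjusted = attr(r, "adjusted"), as.data.frame(r))))
    utils::write.csv(assoc, file.path(config$outdir, "associations.csv"),
                     row.names = FALSE)
    km <- rbind(cbind(outcome = "composite7", km_curves(tab, "composite7")),
                cbind(outcome = "composite_discharge",
                      km_curves(tab, "composite_discharge")))
    utils::write.csv(km, file.path(config$outdir, "km_curves.csv"),
                     row.names = FALSE)
    manifest$counts$dropped_covariates <- flt$dropped
    manifest$counts$n_akd <- sum(tab$akd_day7, na.rm = TRUE)
    manifest$counts$n_death <- sum(tab$death_in_hospital, na.rm = TRUE)
    TRUE
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  # -- manifest -----------------------------------------------------------
  outs <- setdiff(list.files(config$outdir, recursive = TRUE),
                  c("manifest.json", "run.log"))
  manifest$outputs <- as.list(tools::md5sum(file.path(config$outdir, outs)))
  names(manifest$outputs) <- outs
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  log_line(logf, sprintf("done in %.1f s",
                         as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  invisible(structure(manifest, class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  input %d -> included %d (excluded %d); selected G = %s\n",
              x$counts$n_input %||% NA, x$counts$n_included %||% NA,
              x$counts$n_excluded %||% NA,
              format(x$counts$selected_G %||% NA)))
  invisible(x)
}

fmt_table <- function(df, digits = 3) {
  df <- as.data.frame(df)
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  header <- paste("|", paste(names(df), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
  rows <- apply(df, 1L, function(r)
    paste("|", paste(trimws(r), collapse = " | "), "|"))
  paste(c(header, sep, rows), collapse = "\n")
}

#' Write the human-readable run report
#'
#' Summarises a completed run as markdown: consort counts, the BIC table,
#' per-class discrimination (MPCMP), class-mean trajectory coordinates,
#' outcome frequencies (events / cohort size, rounded to integer percent)
#' and the association tables. Re-running on unchanged outputs is
#' byte-identical. Sections whose stage output is missing are marked
#' unavailable.
#'
#' @param outdir the pipeline output directory.
#' @param file report path (default `<outdir>/report.md`).
#' @return the report path, invisibly.
#' @export
write_report <- function(outdir, file = file.path(outdir, "report.md")) {
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                             simplifyVector = TRUE)
  rd <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  lines <- c("# Creatinine trajectory classification report", "",
             sprintf("Seed %s; package version %s.",
                     man$config$seed, man$package_version), "")

  lines <- c(lines, "## Cohort selection", "",
             sprintf("%d patients in; %d included, %d excluded.",
                     man$counts$n_input, man$counts$n_included,
                     man$counts$n_excluded), "")
  ex <- rd("exclusions.csv")
  if (!is.null(ex) && nrow(ex)) {
    tb <- as.data.frame(table(ex$reason), stringsAsFactors = FALSE)
    names(tb) <- c("reason", "n")
    lines <- c(lines, fmt_table(tb), "")
  }

  bic <- rd("bic_table.csv")
  lines <- c(lines, "## Class-count selection (BIC)", "")
  lines <- c(lines, if (is.null(bic)) "_unavailable_" else
    c(fmt_table(bic), "", sprintf("Selected G = %s.", man$counts$selected_G)), "")

  mp <- rd("mpcmp.csv")
  lines <- c(lines, "## Class discrimination (MPCMP)", "",
             if (is.null(mp)) "_unavailable_" else fmt_table(mp), "")

  cm <- rd("class_means.csv")
  if (!is.null(cm)) {
    grid <- cm[cm$t_hours %in% seq(0, 96, by = 24), ]
    wide <- stats::reshape(grid, idvar = "t_hours", timevar = "class",
                           direction = "wide")
    names(wide) <- sub("^pct\\.", "class", names(wide))
    lines <- c(lines, "## Class mean trajectories (percent change)", "",
               fmt_table(wide), "")
  }

  co <- rd("cohort.csv")
  if (!is.null(co)) {
    n <- nrow(co)
    evt <- function(x) sum(x, na.rm = TRUE)
    tb <- data.frame(
      outcome = c("AKD day 7", "in-hospital death", "composite day 7",
                  "composite discharge"),
      events = c(evt(co$akd_day7), evt(co$death_in_hospital),
                 evt(co$composite7_event), evt(co$composite_discharge_event)),
      stringsAsFactors = FALSE)
    tb$percent <- percent_rounded(tb$events, n)
    lines <- c(lines, "## Outcome frequencies", "",
               sprintf("Cohort size %d.", n), "", fmt_table(tb), "")
  }

  as_tab <- rd("associations.csv")
  lines <- c(lines, "## Class-outcome associations (vs class 1)", "",
             if (is.null(as_tab)) "_unavailable_" else fmt_table(as_tab), "")

  writeLines(lines, file)
  invisible(file)
}
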