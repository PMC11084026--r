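# identifier, class and outcome columns: never imputed, never dropped
analysis_protected_cols <- function() {
  c("patient_id", "assigned_class", "true_class", "max_posterior",
    "akd_day7", "akd_indeterminate", "death_in_hospital",
    "composite7_event", "composite7_time",
    "composite_discharge_event", "composite_discharge_time")
}

#' Drop covariates with excessive missingness
#'
#' Removes covariate columns whose fraction of missing values strictly
#' exceeds the threshold. Identifier, class and outcome columns are never
#' dropped.
#'
#' @param table analysis data.frame.
#' @param threshold maximum tolerated missing fraction (default 0.40; a
#'   column exactly at the threshold is kept).
#' @param protect extra column names to keep regardless of missingness.
#' @return list with `table` (reduced) and `dropped` (character).
#' @export
filter_missingness <- function(table, threshold = 0.40, protect = character()) {
  always <- c(analysis_protected_cols(), protect)
  frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  drop <- names(frac)[frac > threshold & !(names(frac) %in% always)]
  list(table = table[, setdiff(names(table), drop), drop = FALSE],
       dropped = drop)
}

# one PMM draw for a single column given current completed predictors
pmm_impute_column <- function(y, pred, miss, k_donors) {
  obs <- which(!miss)
  for (j in which(miss)) {
    d <- abs(pred[obs] - pred[j])
    donors <- obs[order(d)[seq_len(min(k_donors, length(obs)))]]
    y[j] <- y[donors[sample.int(length(donors), 1L)]]
  }
  y
}

#' Multiple imputation by chained predictive mean matching
#'
#' Chained-equations imputation for numeric covariates: each incomplete
#' column is regressed on the other covariates, every missing case is matched
#' to one of the `k_donors` observed cases with the nearest predicted mean,
#' and the donor's observed value is copied. Imputed values are therefore
#' always members of the observed support. `m` independent completions are
#' produced; with no missing values all completions equal the input.
#'
#' @param table analysis data.frame (missingness confined to numeric
#'   covariates; identifier/outcome columns are passed through).
#' @param m number of completed tables (default 5).
#' @param k_donors donor pool size (default 5). Columns with fewer observed
#'   values than `k_donors` fall back to mean imputation with a warning.
#' @param sweeps chained-equation passes per completion (default 5).
#' @param seed optional seed.
#' @return list of `m` completed data.frames, class `pmm_imputations`.
#' @export
impute_pmm <- function(table, m = 5L, k_donors = 5L, sweeps = 5L, seed = NULL) {
  run <- function() impute_pmm_impl(table, m, k_donors, sweeps)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out, class = "pmm_imputations")
}

impute_pmm_impl <- function(table, m, k_donors, sweeps) {
  prot <- names(table) %in% analysis_protected_cols()
  num <- vapply(table, is.numeric, logical(1)) & !prot
  has_na <- vapply(table, anyNA, logical(1)) & !prot
  targets <- names(table)[num & has_na]
  if (any(has_na & !num))
    warning("non-numeric columns with missing values are left untouched: ",
            paste(names(table)[has_na & !num], collapse = ", "))
  if (!length(targets)) return(replicate(m, table, simplify = FALSE))

  # numeric predictors (complete or imputation targets)
  predictors <- names(table)[num]
  miss <- lapply(targets, function(v) is.na(table[[v]]))
  names(miss) <- targets

  # columns with too few observed values cannot be matched; mean-impute them
  fallback <- targets[vapply(targets, function(v) sum(!miss[[v]]) < k_donors,
                             logical(1))]
  if (length(fallback))
    warning("columns with fewer than ", k_donors,
            " observed values are mean-imputed: ",
            paste(fallback, collapse = ", "))
  targets <- setdiff(targets, fallback)

  lapply(seq_len(m), function(rep) {
    tab <- table
    for (v in fallback) tab[[v]][miss[[v]]] <- mean(table[[v]], na.rm = TRUE)
    # initialise with column means
    for (v in targets) tab[[v]][miss[[v]]] <- mean(tab[[v]], na.rm = TRUE)
    for (s in seq_len(sweeps)) {
      for (v in targets) {
        others <- setdiff(predictors, v)
        Xm <- cbind(1, as.matrix(tab[, others, drop = FALSE]))
        obs <- !miss[[v]]
        fit <- stats::lm.fit(Xm[obs, , drop = FALSE], table[[v]][obs])
        keep <- !is.na(fit$coefficients)
        pred <- drop(Xm[, keep, drop = FALSE] %*% fit$coefficients[keep])
        tab[[v]] <- pmm_impute_column(ifelse(miss[[v]], NA, table[[v]]),
                                      pred, miss[[v]], k_donors)
      }
    }
    tab
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Total variance is the within-imputation variance plus `(1 + 1/m)` times
#' the between-imputation variance; inference uses a t reference with the
#' classical degrees of freedom. With a single table (or zero
#' between-imputation variance) pooling collapses to the single-table
#' analysis.
#'
#' @param est matrix of coefficient estimates, one row per imputation.
#' @param se matrix of standard errors, same shape.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame `estimate`, `se`, `df`, `ci_low`, `ci_high`, `p` on the
#'   coefficient scale.
#' @export
pool_rubin <- function(est, se, conf_level = 0.95) {
  est <- rbind(est); se <- rbind(se)
  m <- nrow(est)
  qbar <- colMeans(est)
  W <- colMeans(se^2)
  B <- if (m > 1L) apply(est, 2L, stats::var) else rep(0, ncol(est))
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0 & m > 1L,
               (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  a <- 1 - (1 - conf_level) / 2
  tq <- ifelse(is.finite(df), stats::qt(a, df), stats::qnorm(a))
  se_t <- sqrt(Tv)
  p <- 2 * stats::pt(-abs(qbar / se_t), ifelse(is.finite(df), df, 1e9))
  data.frame(estimate = qbar, se = se_t, df = df,
             ci_low = qbar - tq * se_t, ci_high = qbar + tq * se_t, p = p)
}

# default adjustment set: the quoted covariate list, restricted to columns
# present (laboratory covariates = those surviving the missingness filter)
default_adjustment <- function(table) {
  intersect(c("age", "sex", "race", "diabetes", "chf", "arrhythmia",
              "chronic_lung_disease", "liver_disease", "hemoglobin", "wbc",
              "lactate", "albumin", "baseline_creatinine", "sofa_max",
              "first_aki_stage", "max_aki_stage"),
            names(table))
}

as_table_list <- function(tables) {
  if (is.data.frame(tables)) list(tables)
  else if (inherits(tables, "pmm_imputations") || is.list(tables)) tables
  else stop_config("tables must be a data.frame or a list of data.frames")
}

class_terms <- function(tab) {
  G <- max(tab$assigned_class)
  factor(tab$assigned_class, levels = seq_len(G))
}

extract_class_effects <- function(pooled, coefs, G, prefix = "cls") {
  rows <- paste0(prefix, 2:G)
  idx <- match(rows, coefs)
  data.frame(class = 2:G,
             estimate = exp(pooled$estimate[idx]),
             ci_low = exp(pooled$ci_low[idx]),
             ci_high = exp(pooled$ci_high[idx]),
             p = pooled$p[idx])
}

#' Logistic regression of acute kidney disease on trajectory class
#'
#' Fits `akd_day7 ~ class (+ adjustment covariates)` with class 1 as the
#' reference, on each completed table, pooling coefficients by Rubin's rules
#' before exponentiation. Patients with indeterminate AKD status are dropped
#' from the denominator. Effects whose pooled coefficient magnitude exceeds
#' 10 on the log scale (or is inestimable) are flagged as non-estimable,
#' which is how complete separation surfaces.
#'
#' @param tables a data.frame or list of completed data.frames (from
#'   [impute_pmm()]); each needs `assigned_class` and `akd_day7`.
#' @param adjusted add the adjustment covariate set.
#' @param covariates adjustment covariates (default: the standard set
#'   intersected with available columns).
#' @return object of class `association_result`: data.frame with one row per
#'   non-reference class (`estimate` = odds ratio, `ci_low`, `ci_high`, `p`,
#'   `non_estimable`) plus attributes `outcome`, `adjusted`, `m`.
#' @export
fit_logistic_akd <- function(tables, adjusted = FALSE, covariates = NULL) {
  tables <- as_table_list(tables)
  m <- length(tables)
  ests <- NULL; ses <- NULL; cn <- NULL
  for (tab in tables) {
    tab <- tab[!is.na(tab$akd_day7), , drop = FALSE]
    if (!any(tab$akd_day7) || all(tab$akd_day7))
      stop_config("need at least one event and one non-event")
    G <- max(tab$assigned_class)
    df <- data.frame(y = as.integer(tab$akd_day7), cls = class_terms(tab))
    rhs <- "cls"
    if (adjusted) {
      covariates <- covariates %||% default_adjustment(tab)
      df <- cbind(df, tab[, covariates, drop = FALSE])
      rhs <- paste(c("cls", covariates), collapse = " + ")
    }
    fit <- stats::glm(stats::as.formula(paste("y ~", rhs)), data = df,
                      family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    sm <- summary(fit)$coefficients
    cn <- rownames(sm)
    ests <- rbind(ests, sm[, 1L]); ses <- rbind(ses, sm[, 2L])
  }
  pooled <- pool_rubin(ests, ses)
  out <- extract_class_effects(pooled, cn, G)
  out$non_estimable <- !is.finite(out$estimate) | abs(log(out$estimate)) > 10
  structure(out, class = c("association_result", "data.frame"),
            outcome = "akd_day7", adjusted = adjusted, m = m,
            effect = "OR", n = nrow(tables[[1L]]))
}

#' Cox regression of a composite outcome on trajectory class
#'
#' Proportional-hazards model (Efron ties) for the composite of AKD or
#' death, versus class 1, with optional adjustment and Rubin pooling across
#' completed tables.
#'
#' @param tables a data.frame or list of completed data.frames with the
#'   composite event/time columns.
#' @param outcome `"composite7"` or `"composite_discharge"`.
#' @param adjusted,covariates as in [fit_logistic_akd()].
#' @return an `association_result` with hazard ratios.
#' @export
fit_cox_composite <- function(tables,
                              outcome = c("composite7", "composite_discharge"),
                              adjusted = FALSE, covariates = NULL) {
  outcome <- match.arg(outcome)
  tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
  tables <- as_table_list(tables)
  m <- length(tables)
  ests <- NULL; ses <- NULL; cn <- NULL
  for (tab in tables) {
    tab <- tab[!is.na(tab[[ecol]]) & !is.na(tab[[tcol]]), , drop = FALSE]
    if (!any(tab[[ecol]])) stop_config("no events; cannot fit a Cox model")
    G <- max(tab$assigned_class)
    df <- data.frame(time = pmax(tab[[tcol]], 1e-8),
                     event = as.integer(tab[[ecol]]), cls = class_terms(tab))
    rhs <- "cls"
    if (adjusted) {
      covariates <- covariates %||% default_adjustment(tab)
      df <- cbind(df, tab[, covariates, drop = FALSE])
      rhs <- paste(c("cls", covariates), collapse = " + ")
    }
    fit <- survival::coxph(
      stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
      data = df, ties = "efron",
      control = survival::coxph.control(eps = 1e-11, toler.chol = 1e-13,
                                        iter.max = 50))
    sm <- summary(fit)$coefficients
    cn <- rownames(sm)
    ests <- rbind(ests, sm[, "coef"]); ses <- rbind(ses, sm[, "se(coef)"])
  }
  pooled <- pool_rubin(ests, ses)
  out <- extract_class_effects(pooled, cn, G)
  out$non_estimable <- !is.finite(out$estimate) | is.na(out$estimate) |
    abs(log(pmax(out$estimate, 1e-12))) > 10
  structure(out, class = c("association_result", "data.frame"),
            outcome = outcome, adjusted = adjusted, m = m,
            effect = "HR", n = nrow(tables[[1L]]))
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s of %s vs class 1 (%s, m = %d)\n",
              attr(x, "effect"), attr(x, "outcome"),
              if (attr(x, "adjusted")) "adjusted" else "unadjusted",
              attr(x, "m")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Kaplan-Meier curves per trajectory class
#'
#' Product-limit survival estimates of a composite outcome, stratified by
#' assigned class.
#'
#' @param table analysis data.frame.
#' @param outcome `"composite7"` or `"composite_discharge"`.
#' @return data.frame `class`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_curves <- function(table, outcome = c("composite7", "composite_discharge")) {
  outcome <- match.arg(outcome)
  tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
  tab <- table[!is.na(table[[ecol]]) & !is.na(table[[tcol]]), , drop = FALSE]
  sf <- survival::survfit(
    survival::Surv(pmax(tab[[tcol]], 0), as.integer(tab[[ecol]])) ~ cls,
    data = data.frame(cls = class_terms(tab)))
  if (is.null(sf$strata)) {
    data.frame(class = 1L, time = sf$time, surv = sf$surv,
               n_risk = sf$n.risk, n_event = sf$n.event)
  } else {
    cls <- as.integer(sub("^cls=", "", rep(names(sf$strata), sf$strata)))
    data.frame(class = cls, time = sf$time, surv = sf$surv,
               n_risk = sf$n.risk, n_event = sf$n.event)
  }
}
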