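#' Specification of a latent class mixed model
#'
#' The model for subject i in latent class g is
#' `y_ij = x(t_ij)' beta_g + z(t_ij)' b_i + e_ij`, with `x` a polynomial of
#' normalised time `u = t / t_scale`, `b_i` Gaussian random effects with
#' covariance `D` shared across classes, `e_ij ~ N(0, sigma2)` and class
#' membership probabilities `pi_g = softmax(xi)`.
#'
#' @param G number of latent classes (>= 1).
#' @param fixed_degree polynomial degree of the class-specific fixed effects
#'   (default 3: cubic, the lowest degree that produces the observed
#'   peak-and-recover shapes).
#' @param random_structure `"intercept"` (default) or `"intercept_slope"`.
#' @param t_scale hours mapped to one unit of model time (default 96).
#' @return object of class `lcmm_spec`.
#' @export
lcmm_spec <- function(G, fixed_degree = 3L,
                      random_structure = c("intercept", "intercept_slope"),
                      t_scale = 96) {
  random_structure <- match.arg(random_structure)
  if (G < 1L) stop_config("G must be >= 1")
  if (fixed_degree < 1L) stop_config("fixed_degree must be >= 1")
  structure(list(G = as.integer(G), fixed_degree = as.integer(fixed_degree),
                 random_structure = random_structure, t_scale = t_scale),
            class = "lcmm_spec")
}

# long data -> per-subject index structures
prep_lcmm_data <- function(data, spec) {
  need <- c("patient_id", "t_hours", "pct")
  if (!all(need %in% names(data)))
    stop_config("trajectory data must have columns %s", paste(need, collapse = ", "))
  data <- data[!is.na(data$pct) & !is.na(data$t_hours), , drop = FALSE]
  data <- data[order(data$patient_id, data$t_hours), , drop = FALSE]
  ids <- unique(as.character(data$patient_id))
  idx <- match(as.character(data$patient_id), ids)
  X <- traj_basis(data$t_hours, spec$fixed_degree, spec$t_scale)
  q <- if (spec$random_structure == "intercept") 1L else 2L
  Z <- X[, seq_len(q), drop = FALSE]
  list(y = data$pct, X = X, Z = Z, idx = idx, ids = ids,
       ni = tabulate(idx, nbins = length(ids)), n = length(ids), q = q)
}

# component log-densities log N(y_i; X_i beta_g, Z_i D Z_i' + sigma2 I),
# n_subjects x G. Random-intercept models use the closed-form Woodbury
# identities so the E-step is vectorised over subjects.
component_logdens <- function(prep, beta, D, sigma2) {
  G <- ncol(beta)
  n <- prep$n
  out <- matrix(NA_real_, n, G)
  if (prep$q == 1L) {
    sb2 <- D[1, 1]
    a <- sb2 / (sigma2 + prep$ni * sb2)
    logdet <- (prep$ni - 1) * log(sigma2) + log(sigma2 + prep$ni * sb2)
    for (g in seq_len(G)) {
      r <- prep$y - drop(prep$X %*% beta[, g])
      S1 <- rowsum(r, prep$idx, reorder = FALSE)[, 1L]
      S2 <- rowsum(r * r, prep$idx, reorder = FALSE)[, 1L]
      quad <- (S2 - a * S1^2) / sigma2
      out[, g] <- -0.5 * (prep$ni * log(2 * pi) + logdet + quad)
    }
  } else {
    rows <- split(seq_along(prep$idx), prep$idx)
    for (i in seq_len(n)) {
      ri <- rows[[i]]
      Zi <- prep$Z[ri, , drop = FALSE]
      V <- Zi %*% D %*% t(Zi) + diag(sigma2, length(ri))
      ch <- tryCatch(chol(V), error = function(e)
        stop_config("marginal covariance not positive definite"))
      logdet <- 2 * sum(log(diag(ch)))
      for (g in seq_len(G)) {
        r <- prep$y[ri] - drop(prep$X[ri, , drop = FALSE] %*% beta[, g])
        z <- backsolve(ch, r, transpose = TRUE)
        out[i, g] <- -0.5 * (length(ri) * log(2 * pi) + logdet + sum(z^2))
      }
    }
  }
  out
}

#' Observed-data log-likelihood of a latent class mixed model
#'
#' Evaluates `sum_i log sum_g pi_g N(y_i; X_i beta_g, Z_i D Z_i' + sigma2 I)`
#' for given parameters, without fitting.
#'
#' @param params list with `beta` (matrix, one column per class), `re_cov`
#'   (random-effect covariance `D`), `sigma2` (residual variance) and `xi`
#'   (class-membership logits, last entry 0).
#' @param data long trajectory data (`patient_id`, `t_hours`, `pct`).
#' @param spec an [lcmm_spec()].
#' @return scalar log-likelihood.
#' @export
lcmm_loglik <- function(params, data, spec) {
  prep <- prep_lcmm_data(data, spec)
  beta <- as.matrix(params$beta)
  D <- as.matrix(params$re_cov)
  if (params$sigma2 <= 0) stop_config("sigma2 must be positive")
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop_config("random-effect covariance must be positive semi-definite")
  logf <- component_logdens(prep, beta, D, params$sigma2)
  lpi <- params$xi - logsumexp_rows(matrix(params$xi, nrow = 1))[1]
  sum(logsumexp_rows(sweep(logf, 2L, lpi, `+`)))
}

# one EM pass; returns updated parameters and the loglik of the *incoming*
# parameters (computed from the same E-step, so the trace is exact)
em_step <- function(prep, beta, D, sigma2, lpi) {
  G <- ncol(beta)
  logf <- component_logdens(prep, beta, D, sigma2)
  lw <- sweep(logf, 2L, lpi, `+`)
  lse <- logsumexp_rows(lw)
  loglik <- sum(lse)
  w <- exp(lw - lse)

  if (prep$q == 1L) {
    sb2 <- D[1, 1]
    a <- sb2 / (sigma2 + prep$ni * sb2)
    Ci <- a * sigma2
    S1 <- matrix(0, prep$n, G)
    for (g in seq_len(G)) {
      r <- prep$y - drop(prep$X %*% beta[, g])
      S1[, g] <- rowsum(r, prep$idx, reorder = FALSE)[, 1L]
    }
    m <- a * S1                       # posterior mean random intercept
    beta_new <- beta
    ss <- 0
    for (g in seq_len(G)) {
      wobs <- w[prep$idx, g]
      yt <- prep$y - m[prep$idx, g]
      A <- crossprod(prep$X, prep$X * wobs)
      b <- crossprod(prep$X, wobs * yt)
      beta_new[, g] <- solve(A + diag(1e-10, ncol(A)), b)
      r <- prep$y - drop(prep$X %*% beta_new[, g]) - m[prep$idx, g]
      ss <- ss + sum(wobs * r * r) + sum(w[, g] * prep$ni * Ci)
    }
    sigma2_new <- max(ss / sum(prep$ni), 1e-10)
    sb2_new <- max(sum(w * (m^2 + Ci)) / prep$n, 0)
    D_new <- matrix(sb2_new, 1, 1)
  } else {
    rows <- split(seq_along(prep$idx), prep$idx)
    q <- prep$q
    m <- array(0, c(prep$n, G, q))
    Csum <- matrix(0, q, q)
    Clist <- vector("list", prep$n)
    for (i in seq_len(prep$n)) {
      ri <- rows[[i]]
      Zi <- prep$Z[ri, , drop = FALSE]
      V <- Zi %*% D %*% t(Zi) + diag(sigma2, length(ri))
      Vinv <- chol2inv(chol(V))
      K <- D %*% t(Zi) %*% Vinv
      Clist[[i]] <- D - K %*% Zi %*% D
      for (g in seq_len(G)) {
        r <- prep$y[ri] - drop(prep$X[ri, , drop = FALSE] %*% beta[, g])
        m[i, g, ] <- drop(K %*% r)
      }
    }
    beta_new <- beta
    ss <- 0
    for (g in seq_len(G)) {
      wobs <- w[prep$idx, g]
      zb <- rowSums(prep$Z * m[prep$idx, g, , drop = TRUE])
      if (q == 1L) zb <- prep$Z[, 1] * m[prep$idx, g, 1]
      yt <- prep$y - zb
      A <- crossprod(prep$X, prep$X * wobs)
      b <- crossprod(prep$X, wobs * yt)
      beta_new[, g] <- solve(A + diag(1e-10, ncol(A)), b)
      r <- prep$y - drop(prep$X %*% beta_new[, g]) - zb
      trterm <- vapply(seq_len(prep$n), function(i) {
        Zi <- prep$Z[rows[[i]], , drop = FALSE]
        sum(diag(Zi %*% Clist[[i]] %*% t(Zi)))
      }, numeric(1))
      ss <- ss + sum(wobs * r * r) + sum(w[, g] * trterm)
    }
    sigma2_new <- max(ss / sum(prep$ni), 1e-10)
    D_new <- matrix(0, q, q)
    for (i in seq_len(prep$n)) {
      for (g in seq_len(G)) {
        mi <- m[i, g, ]
        D_new <- D_new + w[i, g] * (tcrossprod(mi) + Clist[[i]])
      }
    }
    D_new <- D_new / prep$n
  }

  pi_new <- pmax(colMeans(w), 1e-12)
  pi_new <- pi_new / sum(pi_new)
  list(beta = beta_new, D = D_new, sigma2 = sigma2_new,
       lpi = log(pi_new), loglik = loglik, w = w)
}

# initial parameter set for one start. Start 1 splits subjects into rank
# groups of their mean level; start 2 clusters subject means by kmeans; the
# remaining starts perturb a single-class least-squares fit (the classic
# grid-search initialisation for latent-class mixed models).
init_params <- function(prep, G, start_index, beta0, v0) {
  grp <- NULL
  means <- rowsum(prep$y, prep$idx, reorder = FALSE)[, 1L] / prep$ni
  if (start_index == 1L) {
    grp <- as.integer(cut(rank(means, ties.method = "first"),
                          breaks = G, labels = FALSE))
  } else if (start_index == 2L && prep$n > G) {
    km <- tryCatch(stats::kmeans(means, centers = G, nstart = 10, iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km)) grp <- km$cluster
  }
  if (!is.null(grp)) {
    beta <- matrix(0, ncol(prep$X), G)
    for (g in seq_len(G)) {
      wobs <- as.numeric(grp[prep$idx] == g) + 1e-3
      A <- crossprod(prep$X, prep$X * wobs)
      beta[, g] <- solve(A + diag(1e-8, ncol(A)),
                         crossprod(prep$X, wobs * prep$y))
    }
    lpi <- log(pmax(tabulate(grp, G) / prep$n, 1e-8))
  } else {
    # perturbed single-class fit: same shape, shifted and tilted at random
    tau <- sqrt(v0)
    beta <- beta0 %*% t(rep(1, G)) +
      matrix(stats::rnorm(length(beta0) * G, 0, tau / 2), ncol = G)
    beta[1L, ] <- beta0[1L] + stats::rnorm(G, 0, tau)
    lpi <- rep(-log(G), G)
  }
  list(beta = beta, D = diag(v0 / 4, prep$q), sigma2 = v0 / 2, lpi = lpi)
}

run_em <- function(prep, par, tol, max_iter, trace = numeric(0)) {
  beta <- par$beta; D <- par$D; sigma2 <- par$sigma2; lpi <- par$lpi
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- em_step(prep, beta, D, sigma2, lpi)
    if (any(apply(st$w, 2L, max) < 1e-6))
      return(list(empty_class = TRUE, trace = trace))
    trace <- c(trace, st$loglik)
    k <- length(trace)
    if (k > 1L) {
      rel <- abs(trace[k] - trace[k - 1L]) /
        (abs(trace[k - 1L]) + .Machine$double.eps)
      if (rel < tol) {
        beta <- st$beta; D <- st$D; sigma2 <- st$sigma2; lpi <- st$lpi
        converged <- TRUE
        break
      }
    }
    beta <- st$beta; D <- st$D; sigma2 <- st$sigma2; lpi <- st$lpi
  }
  # E-step at the final parameters
  logf <- component_logdens(prep, beta, D, sigma2)
  lw <- sweep(logf, 2L, lpi - logsumexp_rows(matrix(lpi, 1))[1], `+`)
  lse <- logsumexp_rows(lw)
  list(beta = beta, D = D, sigma2 = sigma2, lpi = lpi,
       loglik = sum(lse), w = exp(lw - lse), trace = trace,
       converged = converged, empty_class = FALSE)
}

#' Fit a latent class mixed model by EM
#'
#' Expectation-maximisation for the mixture of linear mixed models: the
#' E-step computes posterior class memberships, the M-step solves weighted
#' least squares for each class's fixed effects and closed-form updates for
#' the shared random-effect covariance, residual variance and membership
#' logits. Because the mixture likelihood is multimodal, the fit uses the
#' grid-search strategy common for latent-class mixed models: `n_starts`
#' initialisations (a deterministic rank split of subjects by mean percent
#' change, a kmeans split, and random perturbations of the single-class
#' least-squares fit) each run for a short EM burn-in, after which the best
#' interim solution is refined to convergence. Classes are relabelled in
#' increasing order of their mean trajectory level at t = 0 so labels are
#' stable across runs.
#'
#' @param data long trajectory data (`patient_id`, `t_hours`, `pct`).
#' @param spec an [lcmm_spec()].
#' @param n_starts number of initialisations (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per start (default 500).
#' @param seed optional seed for the random starts.
#' @return object of class `lcmm_fit`: `spec`, `beta`, `re_cov`, `sigma2`,
#'   `xi` (last class 0), `loglik`, `n_params`, `bic`, `posterior` (subjects
#'   by classes, rows sum to 1), `converged`, `loglik_trace`, `ids`.
#' @export
fit_lcmm <- function(data, spec, n_starts = 10L, tol = 1e-8, max_iter = 500L,
                     seed = NULL) {
  run <- function() fit_lcmm_impl(data, spec, n_starts, tol, max_iter)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

fit_lcmm_impl <- function(data, spec, n_starts, tol, max_iter) {
  prep <- prep_lcmm_data(data, spec)
  G <- spec$G
  if (prep$n < G * (spec$fixed_degree + 1L))
    stop_config("need at least %d subjects to fit %d classes",
                G * (spec$fixed_degree + 1L), G)

  # single-class least-squares fit anchoring the perturbation starts
  beta0 <- solve(crossprod(prep$X) + diag(1e-8, ncol(prep$X)),
                 crossprod(prep$X, prep$y))
  v0 <- max(stats::var(prep$y - drop(prep$X %*% beta0)), 1)

  # grid-search strategy: short EM burn-in from every start, then refine the
  # best interim solution to convergence
  burn <- min(50L, max_iter)
  best <- NULL
  attempts <- 0L
  s <- 1L
  while (s <= n_starts && attempts < 3L * n_starts) {
    attempts <- attempts + 1L
    par <- init_params(prep, G, s, beta0, v0)
    fit <- run_em(prep, par, tol, burn)
    if (isTRUE(fit$empty_class)) next  # restart with a fresh random draw
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    s <- s + 1L
  }
  if (is.null(best)) {
    warning("every EM start collapsed a class; falling back to the rank-split start")
    best <- run_em(prep, init_params(prep, G, 1L, beta0, v0), tol, max_iter)
  } else if (!best$converged && max_iter > burn) {
    more <- run_em(prep, best[c("beta", "D", "sigma2", "lpi")], tol,
                   max_iter - burn, trace = best$trace)
    if (!isTRUE(more$empty_class)) best <- more
  }
  if (!best$converged)
    warning("EM did not converge in ", max_iter, " iterations; results are the best found")

  # stable labels: classes ordered by mean trajectory level at t = 0
  ord <- order(best$beta[1L, ])
  beta <- best$beta[, ord, drop = FALSE]
  lpi <- best$lpi[ord]
  posterior <- best$w[, ord, drop = FALSE]
  rownames(posterior) <- prep$ids
  colnames(posterior) <- paste0("class", seq_len(G))
  xi <- lpi - lpi[G]

  q <- prep$q
  n_params <- G * (spec$fixed_degree + 1L) + q * (q + 1L) / 2L + 1L + (G - 1L)
  bic <- -2 * best$loglik + n_params * log(prep$n)

  structure(list(spec = spec, beta = beta, re_cov = best$D,
                 sigma2 = best$sigma2, xi = xi, loglik = best$loglik,
                 n_params = n_params, bic = bic, posterior = posterior,
                 converged = best$converged, loglik_trace = best$trace,
                 ids = prep$ids, n_subjects = prep$n),
            class = "lcmm_fit")
}

#' @export
print.lcmm_fit <- function(x, ...) {
  cat(sprintf("Latent class mixed model: G = %d, degree %d, %s random effects\n",
              x$spec$G, x$spec$fixed_degree, x$spec$random_structure))
  cat(sprintf("  %d subjects; loglik %.2f; BIC %.2f; %sconverged\n",
              x$n_subjects, x$loglik, x$bic, if (x$converged) "" else "NOT "))
  cat("  class proportions:",
      paste(format(exp(x$xi) / sum(exp(x$xi)), digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Select the number of classes by BIC
#'
#' Fits the model for every class count in `G_range` and returns the fit with
#' the lowest Bayesian Information Criterion together with the full fit
#' table. A class count whose fit fails is recorded with missing BIC and
#' skipped.
#'
#' @param data long trajectory data.
#' @param spec_template an [lcmm_spec()] whose `G` is overridden.
#' @param G_range integer vector of class counts (default 2:10).
#' @param n_starts,tol,max_iter passed to [fit_lcmm()].
#' @param seed optional seed (one stream for the whole sweep).
#' @return list with `best_fit` (an `lcmm_fit`) and `bic_table` (data.frame
#'   `G`, `loglik`, `n_params`, `bic`, `converged`).
#' @export
select_model <- function(data, spec_template, G_range = 2:10, n_starts = 10L,
                         tol = 1e-8, max_iter = 500L, seed = NULL) {
  if (!length(G_range)) stop_config("G_range must be non-empty")
  fits <- vector("list", length(G_range))
  tab <- data.frame(G = G_range, loglik = NA_real_, n_params = NA_integer_,
                    bic = NA_real_, converged = NA)
  for (k in seq_along(G_range)) {
    sp <- spec_template
    sp$G <- as.integer(G_range[k])
    # each class count gets its own derived seed so the sweep result does
    # not depend on the order the counts are tried
    one <- function() tryCatch(fit_lcmm_impl(data, sp, n_starts, tol, max_iter),
                               error = function(e) NULL)
    f <- if (is.null(seed)) one() else
      withr::with_seed(seed + 101L * sp$G, one())
    if (is.null(f)) next
    fits[[k]] <- f
    tab$loglik[k] <- f$loglik
    tab$n_params[k] <- f$n_params
    tab$bic[k] <- f$bic
    tab$converged[k] <- f$converged
  }
  if (all(is.na(tab$bic))) stop_config("no class count could be fitted")
  list(best_fit = fits[[which.min(tab$bic)]], bic_table = tab)
}

#' Posterior class assignments and discrimination report
#'
#' Assigns each subject to the class with the highest posterior membership
#' probability (ties to the lowest class index) and summarises discrimination
#' by the mean posterior class membership probability (MPCMP): the mean of
#' the maximum posterior over the members assigned to each class.
#'
#' @param fit an `lcmm_fit` (or anything with a `posterior` matrix).
#' @return list with `assignments` (data.frame `patient_id`,
#'   `assigned_class`, `max_posterior`) and `discrimination` (data.frame
#'   `class`, `n`, `mpcmp`).
#' @export
assign_classes <- function(fit) {
  w <- fit$posterior
  assigned <- max.col(w, ties.method = "first")
  mp <- w[cbind(seq_len(nrow(w)), assigned)]
  assignments <- data.frame(
    patient_id = rownames(w) %||% as.character(seq_len(nrow(w))),
    assigned_class = assigned, max_posterior = mp, stringsAsFactors = FALSE)
  G <- ncol(w)
  disc <- data.frame(
    class = seq_len(G),
    n = vapply(seq_len(G), function(g) sum(assigned == g), integer(1)),
    mpcmp = vapply(seq_len(G), function(g)
      if (any(assigned == g)) mean(mp[assigned == g]) else NA_real_, numeric(1)))
  list(assignments = assignments, discrimination = disc)
}

#' Apply a trained model to an external cohort
#'
#' Computes posterior class memberships for new subjects with all parameters
#' frozen at their trained values (no re-fitting), then assigns classes as in
#' [assign_classes()]. Applying a fit to its own training data reproduces the
#' training assignments exactly.
#'
#' @param fit a trained `lcmm_fit`.
#' @param new_data long trajectory data on the same time scale.
#' @return list with `assignments`, `discrimination` and `posterior`.
#' @export
apply_lcmm <- function(fit, new_data) {
  keep <- !is.na(new_data$pct) & !is.na(new_data$t_hours)
  if (any(!keep)) {
    warning(sum(!keep), " trajectory rows with missing values skipped")
    new_data <- new_data[keep, , drop = FALSE]
  }
  prep <- prep_lcmm_data(new_data, fit$spec)
  logf <- component_logdens(prep, fit$beta, fit$re_cov, fit$sigma2)
  lpi <- fit$xi - logsumexp_rows(matrix(fit$xi, 1))[1]
  lw <- sweep(logf, 2L, lpi, `+`)
  w <- exp(lw - logsumexp_rows(lw))
  rownames(w) <- prep$ids
  colnames(w) <- paste0("class", seq_len(ncol(w)))
  res <- assign_classes(list(posterior = w))
  c(res, list(posterior = w))
}

#' Marginal class-mean trajectories
#'
#' Fixed-effects mean percent-change curve for each class on a time grid
#' (random effects have mean zero, so the marginal mean is `x(t)' beta_g`).
#'
#' @param fit an `lcmm_fit`.
#' @param time_grid hours since ICU admission (default 0..96 by 2).
#' @return data.frame `class`, `t_hours`, `pct`.
#' @export
marginal_trajectories <- function(fit, time_grid = seq(0, 96, by = 2)) {
  X <- traj_basis(time_grid, fit$spec$fixed_degree, fit$spec$t_scale)
  m <- X %*% fit$beta
  data.frame(class = rep(seq_len(ncol(m)), each = length(time_grid)),
             t_hours = rep(time_grid, ncol(m)), pct = as.vector(m))
}

#' Serialise a trained model to JSON (and back)
#'
#' The JSON document carries a schema version, the model specification and
#' all estimated parameters, so a model trained on one cohort can be shipped
#' and re-applied to another with [apply_lcmm()].
#'
#' @param fit an `lcmm_fit`.
#' @param path file path.
#' @return `write_lcmm_fit` returns `path` invisibly; `read_lcmm_fit` returns
#'   an `lcmm_fit` (without posteriors, which belong to the training data).
#' @export
write_lcmm_fit <- function(fit, path) {
  doc <- list(schema = "akitraj-lcmm-1",
              spec = fit$spec[c("G", "fixed_degree", "random_structure", "t_scale")],
              beta = fit$beta, re_cov = fit$re_cov, sigma2 = fit$sigma2,
              xi = fit$xi, loglik = fit$loglik, n_params = fit$n_params,
              bic = fit$bic, n_subjects = fit$n_subjects,
              converged = fit$converged)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lcmm_fit
#' @export
read_lcmm_fit <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "akitraj-lcmm-1"))
    stop_config("unrecognised model schema: %s", doc$schema %||% "<missing>")
  sp <- lcmm_spec(doc$spec$G, doc$spec$fixed_degree, doc$spec$random_structure,
                  doc$spec$t_scale)
  structure(list(spec = sp, beta = as.matrix(doc$beta),
                 re_cov = as.matrix(doc$re_cov), sigma2 = doc$sigma2,
                 xi = as.numeric(doc$xi), loglik = doc$loglik,
                 n_params = doc$n_params, bic = doc$bic, posterior = NULL,
                 converged = doc$converged, n_subjects = doc$n_subjects),
            class = "lcmm_fit")
}
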