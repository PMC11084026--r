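# Independent oracles used across the suite. These deliberately take the
# naive route (dense covariance matrices, probability-scale sums, explicit
# product limits) so they share no code path with the package.

# multivariate normal log-density via determinant() and solve()
dmvnorm_log_naive <- function(y, mu, V) {
  k <- length(y)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  r <- y - mu
  -0.5 * (k * log(2 * pi) + ld + drop(t(r) %*% solve(V) %*% r))
}

# brute-force LCMM marginal log-likelihood: per subject, build the full
# covariance Z D Z' + sigma2 I and sum the component densities
lcmm_loglik_naive <- function(params, data, spec) {
  u <- data$t_hours / spec$t_scale
  X <- outer(u, 0:spec$fixed_degree, `^`)
  q <- if (spec$random_structure == "intercept") 1L else 2L
  Z <- X[, seq_len(q), drop = FALSE]
  pi_g <- exp(params$xi) / sum(exp(params$xi))
  total <- 0
  for (id in unique(data$patient_id)) {
    rows <- which(data$patient_id == id)
    Zi <- Z[rows, , drop = FALSE]
    V <- Zi %*% as.matrix(params$re_cov) %*% t(Zi) +
      diag(params$sigma2, length(rows))
    dens <- 0
    for (g in seq_along(pi_g)) {
      mu <- drop(X[rows, , drop = FALSE] %*% params$beta[, g])
      dens <- dens + pi_g[g] * exp(dmvnorm_log_naive(data$pct[rows], mu, V))
    }
    total <- total + log(dens)
  }
  total
}

traj_basis_for_test <- function(t) outer(t / 96, 0:3, `^`)

# explicit Kaplan-Meier product limit
km_naive <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (k in seq_along(tt)) {
    at_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = tt, surv = surv)
}

# scalar bisection on the monotone MDRD curve
mdrd_bisect <- function(age, sex, race = "other", egfr = 75) {
  f <- function(scr) {
    v <- 175 * scr^(-1.154) * age^(-0.203)
    if (sex == "F") v <- v * 0.742
    if (race == "black") v <- v * 1.212
    v - egfr
  }
  lo <- 0.05; hi <- 20
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# hand-built timeline with sane defaults for rule-level tests
make_timeline <- function(patient_id = "T1", age = 60, sex = "M",
                          race = "white",
                          creatinine = data.frame(t_hours = c(2, 24, 48, 72),
                                                  value = c(1, 1, 1, 1)),
                          antibiotics = 2, cultures = 4,
                          sofa = data.frame(t_hours = c(1, 24, 48),
                                            score = c(3, 3, 3)),
                          prior = data.frame(t_hours = c(-4000, -3000, -2000),
                                             value = c(0.9, 1.0, 1.1)),
                          icu_discharge = 200, hospital_admit = -12,
                          hospital_discharge = 400, death_time = NA_real_,
                          flags = list(), first_admission_value = NULL) {
  if (!is.null(first_admission_value))
    creatinine <- rbind(data.frame(t_hours = hospital_admit,
                                   value = first_admission_value), creatinine)
  patient_timeline(patient_id = patient_id, age = age, sex = sex, race = race,
                   icu_admit = 0, icu_discharge = icu_discharge,
                   hospital_admit = hospital_admit,
                   hospital_discharge = hospital_discharge,
                   death_time = death_time, creatinine = creatinine,
                   antibiotics = antibiotics, cultures = cultures,
                   sofa = sofa, prior_creatinine = prior, flags = flags)
}

# small long-format trajectory simulator used by the LCMM tests (independent
# of generate_cohort): class means given as coefficient matrix in u = t/96
sim_trajectories <- function(n, beta, pi_g, sigma_b, sigma, n_obs = 6,
                             seed = 1) {
  withr::with_seed(seed, {
    G <- ncol(beta)
    cls <- sample.int(G, n, replace = TRUE, prob = pi_g)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      t <- sort(runif(n_obs, 0, 96))
      X <- outer(t / 96, 0:(nrow(beta) - 1L), `^`)
      pct <- drop(X %*% beta[, cls[i]]) + rnorm(1, 0, sigma_b) +
        rnorm(n_obs, 0, sigma)
      out[[i]] <- data.frame(patient_id = sprintf("S%04d", i), t_hours = t,
                             pct = pct)
    }
    list(data = do.call(rbind, out), labels = cls)
  })
}

# best-permutation matching of estimated class labels to truth
best_permutation <- function(beta_hat, beta_true) {
  G <- ncol(beta_true)
  perms <- matrix(unlist(combinat_perms(seq_len(G))), ncol = G, byrow = TRUE)
  best <- NULL; best_err <- Inf
  for (r in seq_len(nrow(perms))) {
    err <- sum((beta_hat[, perms[r, ]] - beta_true)^2)
    if (err < best_err) { best_err <- err; best <- perms[r, ] }
  }
  best
}

combinat_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}
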