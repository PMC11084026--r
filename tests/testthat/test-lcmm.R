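random_params <- function(G, degree = 2, q = 1, seed) {
  withr::with_seed(seed, {
    list(beta = matrix(rnorm((degree + 1) * G, 0, 20), degree + 1, G),
         re_cov = if (q == 1) matrix(runif(1, 4, 50), 1, 1) else {
           A <- matrix(rnorm(4), 2, 2); crossprod(A) + diag(2) * 2
         },
         sigma2 = runif(1, 25, 150),
         xi = c(rnorm(G - 1), 0))
  })
}

test_that("log-likelihood matches the brute-force dense-covariance oracle", {
  sim <- sim_trajectories(3, matrix(c(0, 50, 0, 120, -40, 10), 3, 2),
                          c(0.5, 0.5), sigma_b = 8, sigma = 10, seed = 4)
  for (s in 1:4) {
    par <- random_params(G = 2, degree = 2, seed = s)
    spec <- lcmm_spec(2, fixed_degree = 2)
    expect_equal(lcmm_loglik(par, sim$data, spec),
                 lcmm_loglik_naive(par, sim$data, spec), tolerance = 1e-8)
  }
  # intercept + slope random structure against the same oracle
  par2 <- random_params(G = 2, degree = 2, q = 2, seed = 9)
  spec2 <- lcmm_spec(2, fixed_degree = 2, random_structure = "intercept_slope")
  expect_equal(lcmm_loglik(par2, sim$data, spec2),
               lcmm_loglik_naive(par2, sim$data, spec2), tolerance = 1e-8)
})

test_that("single-component limits: G=1 and duplicated components agree", {
  sim <- sim_trajectories(6, matrix(c(10, 30, -20), 3, 1), 1,
                          sigma_b = 6, sigma = 8, seed = 5)
  p1 <- random_params(G = 1, degree = 2, seed = 2)
  p1$xi <- 0
  ll1 <- lcmm_loglik(p1, sim$data, lcmm_spec(1, fixed_degree = 2))
  expect_equal(ll1, lcmm_loglik_naive(p1, sim$data, lcmm_spec(1, fixed_degree = 2)),
               tolerance = 1e-8)
  # two identical components: loglik equals the G=1 value whatever xi is
  p2 <- list(beta = cbind(p1$beta, p1$beta), re_cov = p1$re_cov,
             sigma2 = p1$sigma2, xi = c(1.7, 0))
  expect_equal(lcmm_loglik(p2, sim$data, lcmm_spec(2, fixed_degree = 2)), ll1,
               tolerance = 1e-10)
  # and the likelihood is invariant to permuting class labels
  p3 <- random_params(G = 2, degree = 2, seed = 3)
  p3_perm <- list(beta = p3$beta[, 2:1], re_cov = p3$re_cov,
                  sigma2 = p3$sigma2, xi = p3$xi[2:1] - p3$xi[1])
  expect_equal(lcmm_loglik(p3, sim$data, lcmm_spec(2, fixed_degree = 2)),
               lcmm_loglik_naive(p3_perm, sim$data, lcmm_spec(2, fixed_degree = 2)),
               tolerance = 1e-8)
})

two_class_truth <- function() {
  # linear + quadratic class means, well separated
  list(beta = matrix(c(0, 80, -40, 60, -30, 40), 3, 2),
       pi = c(0.55, 0.45))
}

test_that("EM is monotone, posteriors are proper, BIC identity holds", {
  tr <- two_class_truth()
  sim <- sim_trajectories(120, tr$beta, tr$pi, sigma_b = 5, sigma = 10,
                          seed = 6)
  fit <- fit_lcmm(sim$data, lcmm_spec(2, fixed_degree = 2), n_starts = 3,
                  seed = 7)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_equal(unname(rowSums(fit$posterior)), rep(1, fit$n_subjects),
               tolerance = 1e-8)
  expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n_subjects))
  # the reported loglik agrees with an independent evaluation at the
  # returned parameters
  expect_equal(fit$loglik,
               lcmm_loglik_naive(list(beta = fit$beta, re_cov = fit$re_cov,
                                      sigma2 = fit$sigma2, xi = fit$xi),
                                 sim$data, fit$spec),
               tolerance = 1e-6)
})

test_that("noise-free two-class data is recovered essentially exactly", {
  tr <- two_class_truth()
  sim <- sim_trajectories(60, tr$beta, tr$pi, sigma_b = 0, sigma = 0.01,
                          seed = 8)
  # near-zero noise keeps sharpening the likelihood, so the relative-change
  # stopping rule may hit the iteration cap; the solution is still exact
  fit <- suppressWarnings(
    fit_lcmm(sim$data, lcmm_spec(2, fixed_degree = 2), n_starts = 3, seed = 9))
  perm <- best_permutation(fit$beta, tr$beta)
  expect_equal(unname(fit$beta[, perm]), tr$beta, tolerance = 1e-3)
  expect_true(all(apply(fit$posterior, 1, max) > 0.999))
  # marginal curves equal the generator means on a grid
  mt <- marginal_trajectories(fit, seq(0, 96, by = 8))
  for (g in 1:2) {
    mu_hat <- mt$pct[mt$class == which(perm == g)]
    mu <- drop(outer(seq(0, 96, by = 8) / 96, 0:2, `^`) %*% tr$beta[, g])
    expect_equal(mu_hat, mu, tolerance = 1e-3)
  }
})

test_that("two-class simulation recovers coefficients within 2 MC SE", {
  tr <- two_class_truth()
  R <- 8
  est <- array(NA_real_, c(R, 3, 2))
  for (r in seq_len(R)) {
    sim <- sim_trajectories(300, tr$beta, tr$pi, sigma_b = 5, sigma = 10,
                            seed = 100 + r)
    fit <- fit_lcmm(sim$data, lcmm_spec(2, fixed_degree = 2), n_starts = 3,
                    tol = 1e-8, seed = 200 + r)
    perm <- best_permutation(fit$beta, tr$beta)
    est[r, , ] <- fit$beta[, perm]
  }
  mean_hat <- apply(est, c(2, 3), mean)
  se_hat <- apply(est, c(2, 3), stats::sd) / sqrt(R)
  z <- (mean_hat - tr$beta) / se_hat
  # joint Monte-Carlo consistency at the 95% level (6 coefficients)
  expect_lte(sum(z^2), stats::qchisq(0.95, length(z)))
  expect_lt(max(abs(z)), 3)
})

test_that("class assignment, tie-breaks and MPCMP arithmetic", {
  fake <- list(posterior = matrix(c(0.9, 0.8, 0.3, 0.1, 0.2, 0.7), 3, 2,
                                  dimnames = list(c("a", "b", "c"), NULL)))
  res <- assign_classes(fake)
  expect_equal(res$assignments$assigned_class, c(1, 1, 2))
  expect_equal(res$discrimination$mpcmp, c(0.85, 0.70))
  expect_equal(res$discrimination$n, c(2L, 1L))

  # uniform posteriors: everyone goes to class 1 by the lowest-index rule
  unif <- list(posterior = matrix(0.25, 5, 4))
  res2 <- assign_classes(unif)
  expect_true(all(res2$assignments$assigned_class == 1))
  expect_equal(res2$discrimination$mpcmp[1], 0.25)
  expect_true(all(is.na(res2$discrimination$mpcmp[2:4])))
})

test_that("model selection: BIC arithmetic and the one-class limit", {
  expect_equal(-2 * (-100) + 5 * log(50), 219.5601, tolerance = 1e-4)

  # data from a single class: the smallest G in range wins
  sim <- sim_trajectories(120, matrix(c(10, 40, -20), 3, 1), 1,
                          sigma_b = 6, sigma = 10, seed = 11)
  sel <- select_model(sim$data, lcmm_spec(2, fixed_degree = 2),
                      G_range = c(4, 2, 3), n_starts = 2, max_iter = 200,
                      seed = 12)
  expect_equal(sel$best_fit$spec$G, 2L)
  expect_equal(nrow(sel$bic_table), 3L)
  expect_equal(sel$bic_table$G, c(4, 2, 3))   # tried in the order given
  expect_error(select_model(sim$data, lcmm_spec(2), G_range = integer()),
               "non-empty")
})

test_that("a trained model applies to external data with frozen parameters", {
  tr <- two_class_truth()
  sim <- sim_trajectories(150, tr$beta, tr$pi, sigma_b = 5, sigma = 10,
                          seed = 13)
  fit <- fit_lcmm(sim$data, lcmm_spec(2, fixed_degree = 2), n_starts = 3,
                  seed = 14)
  asg_train <- assign_classes(fit)

  # idempotence on the training data
  res <- apply_lcmm(fit, sim$data)
  expect_equal(res$assignments$assigned_class,
               asg_train$assignments$assigned_class)
  expect_equal(res$posterior, fit$posterior, tolerance = 1e-10)

  # a subject sitting on a class mean is assigned there with certainty
  t <- seq(4, 92, length.out = 8)
  probe <- data.frame(patient_id = "probe", t_hours = t,
                      pct = drop(outer(t / 96, 0:2, `^`) %*% tr$beta[, 2]) +
                        rnorm(8, 0, 0.1))
  res2 <- apply_lcmm(fit, probe)
  expect_gt(res2$assignments$max_posterior, 0.99)

  # held-out accuracy is close to training accuracy
  sim2 <- sim_trajectories(150, tr$beta, tr$pi, sigma_b = 5, sigma = 10,
                           seed = 15)
  res3 <- apply_lcmm(fit, sim2$data)
  acc <- function(assigned, truth) {
    max(mean(assigned == truth), mean(assigned == 3 - truth))
  }
  a_train <- acc(asg_train$assignments$assigned_class, sim$labels)
  a_new <- acc(res3$assignments$assigned_class, sim2$labels)
  expect_lte(abs(a_train - a_new), 0.05)

  # serialisation round-trips and reproduces the application
  path <- withr::local_tempfile(fileext = ".json")
  write_lcmm_fit(fit, path)
  fit2 <- read_lcmm_fit(path)
  res4 <- apply_lcmm(fit2, sim2$data)
  expect_equal(res4$assignments$assigned_class,
               res3$assignments$assigned_class)
})

test_that("marginal trajectories are the fixed-effect polynomials", {
  fake <- structure(list(spec = lcmm_spec(2, fixed_degree = 1),
                         beta = matrix(c(0, 10, 5, -10), 2, 2)),
                    class = "lcmm_fit")
  mt <- marginal_trajectories(fake, c(0, 48, 96))
  expect_equal(mt$pct[mt$class == 1], c(0, 5, 10))   # line through origin
  expect_equal(mt$pct[mt$class == 2], c(5, 0, -5))
})
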