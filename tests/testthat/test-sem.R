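test_that("implied moments follow the path-tracing formulas", {
  # no genetic paths: only rho links the two birth weights
  p0 <- sem_params(0, 0, 0.5, 1, 1, 0.3)
  V0 <- implied_moments(p0)$cov
  expect_equal(V0["bw", "snp"], 0)
  expect_equal(V0["bw_o", "snp"], 0)
  expect_equal(V0["bw", "bw_o"], 0.3)

  # hand-derived values for m = 0.1, f = 0.2, phi = 0.5
  p1 <- sem_params(0.1, 0.2, 0.5, 1, 1, 0.2)
  V1 <- implied_moments(p1)$cov
  expect_equal(V1["snp", "snp"], 0.5)
  expect_equal(V1["bw", "snp"], 0.125)
  expect_equal(V1["bw_o", "snp"], 0.100)
  expect_equal(V1["bw", "bw"], 1.035)
  expect_equal(V1["bw_o", "bw_o"], 1.035)
  expect_equal(V1["bw", "bw_o"], 0.225)

  # symmetry when m = f
  ps <- sem_params(0.07, 0.07, 0.4, 1, 1, 0)
  Vs <- implied_moments(ps)$cov
  expect_equal(Vs["bw", "snp"], 1.5 * 0.07 * 0.4)
  expect_equal(Vs["bw", "snp"], Vs["bw_o", "snp"])

  expect_error(sem_params(0, 0, -1, 1, 1, 0), "positive")
  expect_error(sem_params(0, 0, 0.5, 1, 1, 1.5), "Cauchy-Schwarz")
})

test_that("FIML log-likelihood equals the per-record density oracle", {
  p <- sem_params(0.08, 0.04, 0.42, 0.9, 1.1, 0.25, mu = c(0.6, 0.1, -0.2))

  # a single complete record exactly at the implied mean
  mom <- implied_moments(p)
  one <- tibble::tibble(g_self = mom$mean["snp"], bw_own = mom$mean["bw"],
                        bw_offspring = mom$mean["bw_o"])
  expect_equal(fiml_loglik(p, one),
               -0.5 * log((2 * pi)^3 * det(mom$cov)), tolerance = 1e-12)

  # duplicating a dataset exactly doubles the log-likelihood
  co <- simulate_cohort(sim_config(n = 400, eaf = 0.3, m = 0.08, f = 0.04,
                                   seed = 50))
  ll <- fiml_loglik(p, co)
  expect_equal(fiml_loglik(p, dplyr::bind_rows(co, co)), 2 * ll,
               tolerance = 1e-8)

  # random parameter/data configurations match the brute-force oracle
  set.seed(51)
  for (i in 1:5) {
    pr <- sem_params(rnorm(1, 0, 0.1), rnorm(1, 0, 0.1), runif(1, 0.2, 0.6),
                     runif(1, 0.5, 1.5), runif(1, 0.5, 1.5), runif(1, -0.2, 0.4),
                     mu = rnorm(3, 0, 0.3))
    coi <- simulate_cohort(sim_config(n = 200, eaf = runif(1, 0.2, 0.8),
                                      seed = 51 + i))
    expect_equal(fiml_loglik(pr, coi), brute_force_loglik(pr, coi),
                 tolerance = 1e-10)
  }
})

test_that("closed-form inversion is exact on forward-mapped moments", {
  V <- implied_moments(sem_params(0.1, 0.2, 0.5, 1, 1, 0.2))$cov
  mf <- closed_form_mf(V)
  expect_equal(unname(mf["m"]), 0.1, tolerance = 1e-14)
  expect_equal(unname(mf["f"]), 0.2, tolerance = 1e-14)

  # equal genotype covariances give m = f = 2c / (3 phi)
  Vsym <- V
  Vsym[1, 2] <- Vsym[2, 1] <- Vsym[1, 3] <- Vsym[3, 1] <- 0.12
  mfs <- closed_form_mf(Vsym)
  expect_equal(unname(mfs["m"]), unname(mfs["f"]))
  expect_equal(unname(mfs["m"]), 2 * (0.12 / 0.5) / 3)

  Vnull <- V
  Vnull[1, 2] <- Vnull[2, 1] <- Vnull[1, 3] <- Vnull[3, 1] <- 0
  expect_equal(unname(closed_form_mf(Vnull)), c(0, 0))
  expect_error(closed_form_mf(matrix(0, 3, 3)), "positive")
})

test_that("complete-data fits are saturated: moments and (m, f) reproduced", {
  co <- make_complete_cohort(5000, seed = 52)
  fit <- fit_sem(co)
  expect_true(fit$converged)
  S_ml <- cov(cbind(co$g_self, co$bw_own, co$bw_offspring)) *
    (nrow(co) - 1) / nrow(co)
  mf <- closed_form_mf(S_ml)
  expect_equal(unname(fit$estimates["m"]), unname(mf["m"]), tolerance = 1e-4)
  expect_equal(unname(fit$estimates["f"]), unname(mf["f"]), tolerance = 1e-4)
  est <- fit$estimates
  imp <- implied_moments(sem_params(est["m"], est["f"], est["phi"],
                                    est["sigma2"], est["sigma2_o"], est["rho"],
                                    est[c("mu_snp", "mu_bw", "mu_bwo")]))
  expect_lt(max(abs(imp$cov - S_ml)), 1e-6)
  expect_lt(max(abs(imp$mean - colMeans(cbind(co$g_self, co$bw_own,
                                              co$bw_offspring)))), 1e-6)
})

test_that("estimates are scale-equivariant with invariant Wald z", {
  co <- simulate_cohort(sim_config(n = 8000, m = 0.2, f = 0.15, seed = 53))
  fit1 <- fit_sem(co)
  co2 <- dplyr::mutate(co, bw_own = 2 * bw_own, bw_offspring = 2 * bw_offspring)
  fit2 <- fit_sem(co2)
  expect_equal(unname(fit2$estimates["m"]), 2 * unname(fit1$estimates["m"]),
               tolerance = 1e-3)
  expect_equal(unname(fit2$estimates["f"]), 2 * unname(fit1$estimates["f"]),
               tolerance = 1e-3)
  expect_equal(fit2$wald$statistic, fit1$wald$statistic, tolerance = 1e-2)
})

test_that("standard errors shrink as records move into the complete pattern", {
  cfg_split <- sim_config(n = 20000, m = 0.05, f = 0.03,
                          pattern_fractions = c(0.45, 0.45, 0.1), seed = 54)
  cfg_both <- sim_config(n = 20000, m = 0.05, f = 0.03,
                         pattern_fractions = c(0.1, 0.1, 0.8), seed = 54)
  se_split <- fit_sem(simulate_cohort(cfg_split))$se
  se_both <- fit_sem(simulate_cohort(cfg_both))$se
  expect_lt(se_both[["m"]], se_split[["m"]])
  expect_lt(se_both[["f"]], se_split[["f"]])
})

test_that("unidentified pattern configurations error, naming the gap", {
  co <- simulate_cohort(sim_config(n = 500, pattern_fractions = c(1, 0, 0),
                                   seed = 55))
  expect_error(fit_sem(co), "offspring birth weight")
  co2 <- simulate_cohort(sim_config(n = 500, pattern_fractions = c(0, 1, 0),
                                    seed = 55))
  expect_error(fit_sem(co2), "own birth weight")
})

test_that("fixing phi constrains the genotype variance", {
  co <- make_complete_cohort(4000, eaf = 0.3, seed = 56)
  fit <- fit_sem(co, fix_phi = 2 * 0.3 * 0.7)
  expect_equal(unname(fit$estimates["phi"]), 0.42, tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("SEM and pair conditional regression agree on complete trios", {
  co <- make_complete_cohort(50000, m = 0.05, f = 0.03, seed = 57)
  fit <- fit_sem(co)
  pairs <- tibble::tibble(g_mother = co$g_self, g_child = co$g_offspring,
                          bw_z = co$bw_offspring)
  cond <- conditional_regression(pairs, covariates = NULL)
  for (i in 1:2) {
    delta <- abs(fit$wald$estimate[i] - cond$beta[i])
    expect_lt(delta, 3 * sqrt(fit$wald$std.error[i]^2 + cond$se[i]^2))
  }
})

test_that("the 2-df test is null at identical fits and powered at strong effects", {
  co <- make_complete_cohort(50000, m = 0.2, f = 0.2, seed = 58)
  fit <- fit_sem(co)
  res <- lrt_2df(fit)
  expect_gte(res$statistic, 0)
  expect_equal(res$df, 2L)
  expect_lt(res$p, 1e-8)

  # a null-truth dataset gives a small statistic
  co0 <- make_complete_cohort(2000, m = 0, f = 0, seed = 59)
  res0 <- lrt_2df(fit_sem(co0))
  expect_lt(res0$statistic, qchisq(0.999, 2))
})

test_that("tidy, glance and autoplot expose the fit", {
  co <- simulate_cohort(sim_config(n = 3000, m = 0.2, f = 0.1, seed = 60))
  fit <- fit_sem(co)
  td <- tidy(fit)
  expect_setequal(td$term, c("m", "f", "phi", "sigma2", "sigma2_o", "rho",
                             "mu_snp", "mu_bw", "mu_bwo"))
  expect_true(all(td$conf.low < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, 3000)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "Maternal-fetal")
})
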