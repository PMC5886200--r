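#' Parameters of the maternal-fetal birth-weight SEM
#'
#' The model has three observed variables — the genotyped woman's allele
#' count (SNP), her own birth weight (BW) and her first child's birth weight
#' (BW_O) — and two latent genotypes: her mother's (G_G) and her child's
#' (G_O), each connected to SNP by a fixed Mendelian path of 0.5. The free
#' parameters are the maternal path `m` (G_G -> BW, SNP -> BW_O), the fetal
#' path `f` (SNP -> BW, G_O -> BW_O), the genotype variance `phi`, the
#' residual variances `sigma2` and `sigma2_o`, the residual covariance `rho`
#' and the three means.
#'
#' @param m,f Maternal and fetal path coefficients (SD units per allele).
#' @param phi Genotype variance (positive); `2 * eaf * (1 - eaf)` under HWE.
#' @param sigma2,sigma2_o Residual variances of BW and BW_O (positive).
#' @param rho Residual covariance, `rho^2 <= sigma2 * sigma2_o`.
#' @param mu Length-3 means of (SNP, BW, BW_O).
#' @return A list of class `matfet_sem_params`.
#' @export
sem_params <- function(m, f, phi, sigma2, sigma2_o, rho, mu = c(0, 0, 0)) {
  if (phi <= 0) abort("`phi` must be positive.")
  if (sigma2 <= 0 || sigma2_o <= 0) abort("Residual variances must be positive.")
  if (rho^2 > sigma2 * sigma2_o) {
    abort("`rho` violates Cauchy-Schwarz: rho^2 must not exceed sigma2 * sigma2_o.")
  }
  if (length(mu) != 3) abort("`mu` must have length 3 (SNP, BW, BW_O).")
  structure(list(m = m, f = f, phi = phi, sigma2 = sigma2, sigma2_o = sigma2_o,
                 rho = rho, mu = as.numeric(mu)),
            class = "matfet_sem_params")
}

#' Model-implied moments of (SNP, BW, BW_O)
#'
#' Path-tracing results for the model of [sem_params()]:
#' `var(SNP) = phi`, `cov(BW, SNP) = (0.5 m + f) phi`,
#' `cov(BW_O, SNP) = (m + 0.5 f) phi`,
#' `var(BW) = (m^2 + f^2 + m f) phi + sigma2` (and `sigma2_o` for BW_O),
#' `cov(BW, BW_O) = (0.5 m^2 + 1.25 m f + 0.5 f^2) phi + rho`.
#' These were re-derived by hand and confirmed against a large-n Monte-Carlo
#' simulation from [simulate_cohort()] before being relied on.
#'
#' @param params A [sem_params()].
#' @return List with `mean` (length 3) and `cov` (3x3, dimnames
#'   `snp`/`bw`/`bw_o`). Errors if the implied covariance is not positive
#'   definite.
#' @export
#' @examples
#' implied_moments(sem_params(0.1, 0.2, 0.5, 1, 1, 0.2))$cov
implied_moments <- function(params) {
  V <- implied_cov(params)
  if (inherits(tryCatch(chol(V), error = identity), "error")) {
    abort("Implied covariance matrix is not positive definite.")
  }
  list(mean = setNames(params$mu, c("snp", "bw", "bw_o")), cov = V)
}

implied_cov <- function(p) {
  gvar <- (p$m^2 + p$f^2 + p$m * p$f) * p$phi
  V <- matrix(c(
    p$phi, (0.5 * p$m + p$f) * p$phi, (p$m + 0.5 * p$f) * p$phi,
    (0.5 * p$m + p$f) * p$phi, gvar + p$sigma2,
    (0.5 * p$m^2 + 1.25 * p$m * p$f + 0.5 * p$f^2) * p$phi + p$rho,
    (p$m + 0.5 * p$f) * p$phi,
    (0.5 * p$m^2 + 1.25 * p$m * p$f + 0.5 * p$f^2) * p$phi + p$rho,
    gvar + p$sigma2_o), 3, 3)
  dimnames(V) <- list(c("snp", "bw", "bw_o"), c("snp", "bw", "bw_o"))
  V
}

# Per-pattern sufficient statistics: n, mean vector and centred scatter for
# each observed-variable block. FIML only ever needs these, so the likelihood
# costs the same at n = 100 or n = 100 000.
pattern_stats <- function(data, snp_col = "g_self") {
  stopifnot(snp_col %in% names(data),
            all(c("bw_own", "bw_offspring") %in% names(data)))
  x <- cbind(snp = data[[snp_col]], bw = data$bw_own, bw_o = data$bw_offspring)
  x <- x[!is.na(x[, "snp"]), , drop = FALSE]
  has_bw <- !is.na(x[, "bw"])
  has_bwo <- !is.na(x[, "bw_o"])
  blocks <- list(
    OWN_ONLY = list(idx = c(1L, 2L), rows = has_bw & !has_bwo),
    OFFSPRING_ONLY = list(idx = c(1L, 3L), rows = !has_bw & has_bwo),
    BOTH = list(idx = 1:3, rows = has_bw & has_bwo)
  )
  purrr::map(blocks, function(b) {
    xb <- x[b$rows, b$idx, drop = FALSE]
    n <- nrow(xb)
    if (n == 0) return(list(idx = b$idx, n = 0L))
    xbar <- colMeans(xb)
    xc <- sweep(xb, 2, xbar)
    list(idx = b$idx, n = n, xbar = xbar, S = crossprod(xc))
  })
}

# Log-likelihood from sufficient statistics; -Inf when a marginal implied
# covariance is not PD (optimizer-safe).
fiml_ll_stats <- function(p, stats) {
  V <- implied_cov(p)
  mu <- p$mu
  ll <- 0
  for (b in stats) {
    if (b$n == 0) next
    Vk <- V[b$idx, b$idx, drop = FALSE]
    R <- tryCatch(chol(Vk), error = identity)
    if (inherits(R, "error")) return(-Inf)
    k <- length(b$idx)
    logdet <- 2 * sum(log(diag(R)))
    Vinv <- chol2inv(R)
    d <- b$xbar - mu[b$idx]
    ll <- ll - 0.5 * b$n * (k * log(2 * pi) + logdet) -
      0.5 * (sum(Vinv * b$S) + b$n * drop(t(d) %*% Vinv %*% d))
  }
  ll
}

#' Full-information maximum-likelihood log-likelihood
#'
#' Sums, over the three missingness patterns, the multivariate-normal
#' log-density of each record under the marginal (mean, covariance) of its
#' observed variables, so differently incomplete records all contribute.
#' When only complete records are present this equals the complete-data
#' log-likelihood.
#'
#' @param params A [sem_params()].
#' @param data Cohort tibble with the SNP column plus `bw_own` and
#'   `bw_offspring` (patterns inferred from missingness).
#' @param snp_col Name of the genotype column.
#' @return Scalar log-likelihood (`-Inf` if a marginal covariance is not
#'   positive definite).
#' @export
fiml_loglik <- function(params, data, snp_col = "g_self") {
  stopifnot(inherits(params, "matfet_sem_params"))
  fiml_ll_stats(params, pattern_stats(data, snp_col))
}

#' Method-of-moments inversion for (m, f)
#'
#' Closed-form inversion of the implied-covariance equations: with
#' `phi = var(SNP)`, `a = cov(BW, SNP) / phi` and `b = cov(BW_O, SNP) / phi`,
#' `f = (4a - 2b) / 3` and `m = (4b - 2a) / 3`. On complete data the model is
#' just-identified, so this is an exact oracle for [fit_sem()].
#'
#' @param sample_cov 3x3 covariance matrix of (SNP, BW, BW_O), in that order.
#' @return Named vector `c(m =, f =)`.
#' @export
#' @examples
#' V <- implied_moments(sem_params(0.1, 0.2, 0.5, 1, 1, 0.2))$cov
#' closed_form_mf(V)  # recovers m = 0.1, f = 0.2
closed_form_mf <- function(sample_cov) {
  phi <- sample_cov[1, 1]
  if (phi <= 0) abort("Genotype variance must be positive.")
  a <- sample_cov[1, 2] / phi
  b <- sample_cov[1, 3] / phi
  c(m = (4 * b - 2 * a) / 3, f = (4 * a - 2 * b) / 3)
}

# Working parameterization: theta = (m, f, log phi, log sigma2, log sigma2_o,
# atanh residual correlation, mu_snp, mu_bw, mu_bwo). Positivity and
# Cauchy-Schwarz hold by construction, so quasi-Newton runs unconstrained.
theta_names <- c("m", "f", "lphi", "ls2", "ls2o", "z", "mu_snp", "mu_bw", "mu_bwo")

theta_to_params <- function(theta) {
  s2 <- exp(theta[["ls2"]])
  s2o <- exp(theta[["ls2o"]])
  list(m = theta[["m"]], f = theta[["f"]], phi = exp(theta[["lphi"]]),
       sigma2 = s2, sigma2_o = s2o,
       rho = tanh(theta[["z"]]) * sqrt(s2 * s2o),
       mu = c(theta[["mu_snp"]], theta[["mu_bw"]], theta[["mu_bwo"]]))
}

natural_vec <- function(theta) {
  p <- theta_to_params(theta)
  c(m = p$m, f = p$f, phi = p$phi, sigma2 = p$sigma2, sigma2_o = p$sigma2_o,
    rho = p$rho, mu_snp = p$mu[1], mu_bw = p$mu[2], mu_bwo = p$mu[3])
}

# Data-driven starting values from pattern-pooled moments.
start_theta <- function(stats) {
  pool <- function(blocks, var1, var2) {
    # pooled covariance of two variables over blocks observing both
    num <- 0; den <- 0; ok <- FALSE
    for (b in blocks) {
      pos1 <- match(var1, b$idx); pos2 <- match(var2, b$idx)
      if (b$n >= 2 && !is.na(pos1) && !is.na(pos2)) {
        num <- num + b$S[pos1, pos2]
        den <- den + (b$n - 1)
        ok <- TRUE
      }
    }
    if (ok) num / den else NA_real_
  }
  pool_mean <- function(blocks, var) {
    num <- 0; den <- 0
    for (b in blocks) {
      pos <- match(var, b$idx)
      if (b$n >= 1 && !is.na(pos)) {
        num <- num + b$n * b$xbar[pos]
        den <- den + b$n
      }
    }
    if (den > 0) num / den else 0
  }
  phi <- max(pool(stats, 1, 1), 1e-4)
  v_bw <- pool(stats, 2, 2)
  v_bwo <- pool(stats, 3, 3)
  a <- pool(stats, 1, 2) / phi
  b <- pool(stats, 1, 3) / phi
  m0 <- (4 * b - 2 * a) / 3
  f0 <- (4 * a - 2 * b) / 3
  gvar <- (m0^2 + f0^2 + m0 * f0) * phi
  s2 <- max(v_bw - gvar, 0.05 * v_bw)
  s2o <- max(v_bwo - gvar, 0.05 * v_bwo)
  c_bwo <- pool(stats, 2, 3)
  r0 <- 0
  if (is.finite(c_bwo)) {
    rho0 <- c_bwo - (0.5 * m0^2 + 1.25 * m0 * f0 + 0.5 * f0^2) * phi
    r0 <- max(min(rho0 / sqrt(s2 * s2o), 0.9), -0.9)
  }
  setNames(c(m0, f0, log(phi), log(s2), log(s2o), atanh(r0),
             pool_mean(stats, 1), pool_mean(stats, 2), pool_mean(stats, 3)),
           theta_names)
}

num_gradient <- function(fn, theta, step = 1e-5) {
  vapply(seq_along(theta), function(i) {
    h <- step * max(1, abs(theta[i]))
    tp <- tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, numeric(1))
}

num_hessian <- function(fn, theta, step = 1e-5) {
  k <- length(theta)
  h <- step * pmax(1, abs(theta))
  H <- matrix(0, k, k)
  f0 <- fn(theta)
  for (i in seq_len(k)) {
    tp <- tm <- theta
    tp[i] <- tp[i] + h[i]; tm[i] <- tm[i] - h[i]
    H[i, i] <- (fn(tp) - 2 * f0 + fn(tm)) / h[i]^2
    for (j in seq_len(i - 1)) {
      tpp <- tpm <- tmp <- tmm <- theta
      tpp[c(i, j)] <- tpp[c(i, j)] + h[c(i, j)]
      tmm[c(i, j)] <- tmm[c(i, j)] - h[c(i, j)]
      tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
      tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
      H[i, j] <- H[j, i] <- (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

num_jacobian <- function(fn, theta, step = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(0, length(f0), length(theta))
  for (i in seq_along(theta)) {
    h <- step * max(1, abs(theta[i]))
    tp <- tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    J[, i] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  rownames(J) <- names(f0)
  J
}

fit_sem_stats <- function(stats, fixed = list(), n_restarts = 2) {
  free <- setdiff(theta_names, names(fixed))
  assemble <- function(th_free) {
    full <- setNames(numeric(length(theta_names)), theta_names)
    full[free] <- th_free
    for (nm in names(fixed)) full[nm] <- fixed[[nm]]
    full
  }
  negll <- function(th_free) {
    ll <- fiml_ll_stats(theta_to_params(assemble(th_free)), stats)
    if (!is.finite(ll)) 1e12 else -ll
  }
  th0_full <- start_theta(stats)
  th0 <- th0_full[free]
  best <- NULL
  for (attempt in 0:n_restarts) {
    start <- if (attempt == 0) th0 else th0 + rnorm(length(th0), 0, 0.1)
    opt <- optim(start, negll, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
    g <- num_gradient(negll, best$par)
    tol <- 1e-6 * max(1, abs(best$value))
    if (best$convergence == 0 && max(abs(g)) < tol) break
  }
  g <- num_gradient(negll, best$par)
  grad_ok <- max(abs(g)) < 1e-6 * max(1, abs(best$value))
  H <- num_hessian(negll, best$par)
  Hpd <- !inherits(tryCatch(chol(H), error = identity), "error")
  vcov_w <- if (Hpd) chol2inv(chol(H)) else matrix(NA_real_, length(free), length(free))
  theta_hat <- assemble(best$par)
  J_full <- num_jacobian(natural_vec, theta_hat)
  J <- J_full[, match(free, theta_names), drop = FALSE]
  vcov_nat <- J %*% vcov_w %*% t(J)
  dimnames(vcov_nat) <- list(rownames(J_full), rownames(J_full))
  list(theta = theta_hat, estimates = natural_vec(theta_hat),
       vcov = vcov_nat, vcov_working = vcov_w, free = free,
       loglik = -best$value,
       converged = best$convergence == 0 && grad_ok && Hpd,
       grad_max = max(abs(g)))
}

#' Fit the maternal-fetal SEM by full-information maximum likelihood
#'
#' Maximizes [fiml_loglik()] by quasi-Newton (BFGS) on an unconstrained
#' working scale (log variances, atanh-scaled residual correlation) from
#' data-driven starting values, with up to two random restarts if the first
#' pass fails the convergence check (small gradient and positive-definite
#' observed information). Standard errors come from the inverse numerical
#' observed information, mapped to the natural scale by the delta method;
#' Wald z statistics for `m` and `f` use the normal reference.
#'
#' @param data Cohort tibble with the SNP column plus `bw_own` and
#'   `bw_offspring`; missingness patterns are inferred. Records observing
#'   neither birth weight are dropped. At least one record must observe own
#'   birth weight and at least one the offspring's, otherwise the two paths
#'   are not separable and an error names the missing pattern.
#' @param snp_col Name of the genotype column.
#' @param fix_phi Optional fixed value for the genotype variance (e.g.
#'   `2 * p * (1 - p)`); `NULL` (default) estimates it freely.
#' @return Object of class `matfet_sem`: estimates, vcov, `loglik`,
#'   `converged`, `n_by_pattern`, and a `wald` tibble for the maternal and
#'   fetal paths. Non-convergence is flagged, never silent.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 2000, m = 0.3, f = 0.2, seed = 1))
#' fit <- fit_sem(cohort)
#' tidy(fit)
fit_sem <- function(data, snp_col = "g_self", fix_phi = NULL) {
  stats <- pattern_stats(data, snp_col)
  n_bw <- stats$OWN_ONLY$n + stats$BOTH$n
  n_bwo <- stats$OFFSPRING_ONLY$n + stats$BOTH$n
  if (n_bw == 0) {
    abort("No record observes own birth weight (patterns OWN_ONLY/BOTH empty); maternal and fetal paths are not identified.")
  }
  if (n_bwo == 0) {
    abort("No record observes offspring birth weight (patterns OFFSPRING_ONLY/BOTH empty); maternal and fetal paths are not identified.")
  }
  fixed <- list()
  if (!is.null(fix_phi)) {
    if (fix_phi <= 0) abort("`fix_phi` must be positive.")
    fixed$lphi <- log(fix_phi)
  }
  fit <- fit_sem_stats(stats, fixed = fixed)
  est <- fit$estimates
  se <- sqrt(pmax(diag(fit$vcov), 0))
  wald <- tibble::tibble(
    term = c("maternal", "fetal"),
    estimate = est[c("m", "f")],
    std.error = se[c("m", "f")],
    statistic = est[c("m", "f")] / se[c("m", "f")],
    p.value = 2 * pnorm(-abs(est[c("m", "f")] / se[c("m", "f")]))
  )
  structure(
    list(estimates = est, se = se, vcov = fit$vcov, loglik = fit$loglik,
         converged = fit$converged, grad_max = fit$grad_max,
         n_by_pattern = purrr::map_int(stats, "n"),
         wald = wald, stats = stats, fixed = fixed, snp_col = snp_col),
    class = "matfet_sem"
  )
}

#' 2-df likelihood-ratio test for any SNP effect on birth weight
#'
#' Refits the SEM with both the maternal and fetal paths constrained to zero
#' and compares twice the log-likelihood difference to chi-square with 2
#' degrees of freedom — the joint test that the SNP affects birth weight
#' through either route.
#'
#' @param full A fitted [fit_sem()] object (its data enter through the
#'   stored sufficient statistics).
#' @return List with `statistic`, `df = 2`, `p`, and the null fit's
#'   log-likelihood.
#' @export
lrt_2df <- function(full) {
  stopifnot(inherits(full, "matfet_sem"))
  null_fit <- fit_sem_stats(full$stats, fixed = c(list(m = 0, f = 0), full$fixed))
  stat <- 2 * (full$loglik - null_fit$loglik)
  if (stat < -1e-6 * max(1, abs(full$loglik))) {
    abort("Null log-likelihood exceeds the full model's: optimizer failure.")
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = 2L, p = pchisq(stat, 2, lower.tail = FALSE),
       loglik_null = null_fit$loglik)
}

#' Export SEM path estimates as study-effect rows
#'
#' Formats the fitted maternal- and fetal-conditional estimates in the
#' study-effect schema used by the meta-analysis stage, so SEM results can
#' be combined with mother-child-pair results via [combine_sem_pairs()].
#'
#' @param fit A [fit_sem()] object.
#' @param snp_id,effect_allele,other_allele,eaf Variant annotation.
#' @return Two-row tibble tagged `maternal_conditional` /
#'   `fetal_conditional`.
#' @export
sem_study_effects <- function(fit, snp_id = NA_character_,
                              effect_allele = NA_character_,
                              other_allele = NA_character_, eaf = NA_real_) {
  stopifnot(inherits(fit, "matfet_sem"))
  tibble::tibble(
    study_id = "sem",
    snp_id = snp_id,
    term = c("maternal_conditional", "fetal_conditional"),
    effect_allele = effect_allele, other_allele = other_allele, eaf = eaf,
    beta = fit$wald$estimate, se = fit$wald$std.error, p = fit$wald$p.value,
    n = sum(fit$n_by_pattern)
  )
}

#' @export
print.matfet_sem <- function(x, ...) {
  cat("Maternal-fetal birth-weight SEM (FIML)\n")
  cat(sprintf("  n = %d (own-only %d, offspring-only %d, both %d)\n",
              sum(x$n_by_pattern), x$n_by_pattern[["OWN_ONLY"]],
              x$n_by_pattern[["OFFSPRING_ONLY"]], x$n_by_pattern[["BOTH"]]))
  cat(sprintf("  log-likelihood %.3f, converged: %s\n", x$loglik, x$converged))
  w <- x$wald
  for (i in seq_len(nrow(w))) {
    cat(sprintf("  %-9s %8.4f (SE %.4f), z = %6.2f, p = %.3g\n",
                w$term[i], w$estimate[i], w$std.error[i], w$statistic[i],
                w$p.value[i]))
  }
  invisible(x)
}
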