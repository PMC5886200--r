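# Shared fixture builders and independent oracles.

# Complete-data cohort (every record observes both birth weights).
make_complete_cohort <- function(n, eaf = 0.3, m = 0.05, f = 0.03,
                                 sigma2 = 1, sigma2_o = 1, rho = 0.2, seed = 1) {
  simulate_cohort(sim_config(n = n, eaf = eaf, m = m, f = f, sigma2 = sigma2,
                             sigma2_o = sigma2_o, rho = rho,
                             pattern_fractions = c(0, 0, 1), seed = seed))
}

# Independent FIML oracle: per-record multivariate-normal log-density via an
# explicit quadratic form with solve(), no sufficient statistics.
brute_force_loglik <- function(params, data, snp_col = "g_self") {
  V <- implied_moments(params)$cov
  mu <- implied_moments(params)$mean
  x <- cbind(data[[snp_col]], data$bw_own, data$bw_offspring)
  x <- x[!is.na(x[, 1]), , drop = FALSE]
  ll <- 0
  for (i in seq_len(nrow(x))) {
    obs <- which(!is.na(x[i, ]))
    Vk <- V[obs, obs, drop = FALSE]
    d <- x[i, obs] - mu[obs]
    ll <- ll - 0.5 * (length(obs) * log(2 * pi) + log(det(Vk)) +
                        drop(t(d) %*% solve(Vk, d)))
  }
  ll
}

# Independent exact-HWE oracle: enumerate the conditional distribution of the
# heterozygote count with exact binomial coefficients, normalized explicitly.
hwe_exact_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  nr <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  hets <- seq.int(nr %% 2, min(nr, 2 * n - nr), by = 2)
  pr <- vapply(hets, function(h) {
    choose(n, (nr - h) / 2) * choose(n - (nr - h) / 2, h) * 2^h
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

# Sample skewness and excess kurtosis.
sample_skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3
sample_ex_kurtosis <- function(x) mean((x - mean(x))^4) / sd(x)^4 - 3
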