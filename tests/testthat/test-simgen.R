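test_that("sim_config validates its invariants", {
  expect_error(sim_config(eaf = 1.2), "eaf")
  expect_error(sim_config(sigma2 = 0), "positive")
  expect_error(sim_config(rho = 1.5), "Cauchy-Schwarz")
  expect_error(sim_config(pattern_fractions = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("Mendelian transmission matches enumeration of allele draws", {
  set.seed(42)
  expect_true(all(mendelian_transmit(rep(2, 100), rep(2, 100)) == 2))
  expect_true(all(mendelian_transmit(rep(0, 100), rep(0, 100)) == 0))
  # het x het: {0: 1/4, 1: 1/2, 2: 1/4} from the 4 equiprobable allele pairs
  kids <- mendelian_transmit(rep(1L, 40000), rep(1L, 40000))
  expect_gt(chisq.test(table(factor(kids, 0:2)),
                       p = c(0.25, 0.5, 0.25))$p.value, 0.001)
  expect_error(mendelian_transmit(3, 1), "allele counts")
})

test_that("genotype chain has HWE variance and the 0.5 / 0.25 correlations", {
  for (eaf in c(0.1, 0.3, 0.5, 0.8)) {
    g <- simulate_cohort(sim_config(n = 60000, eaf = eaf, seed = 100 + eaf * 10))
    expect_equal(cor(g$g_self, g$g_offspring), 0.5, tolerance = 0.05)
    expect_equal(cor(g$g_grandmother, g$g_offspring), 0.25, tolerance = 0.1)
    expect_equal(var(g$g_self), 2 * eaf * (1 - eaf), tolerance = 0.05)
    # transmitted variance split: R^2 of child on mother -> 0.25
    expect_equal(summary(lm(g_offspring ~ g_self, data = g))$r.squared,
                 0.25, tolerance = 0.02)
  }
})

test_that("monomorphic input propagates and conditional child distribution is Mendelian", {
  g0 <- simulate_cohort(sim_config(n = 500, eaf = 0, seed = 5))
  expect_true(all(g0$g_grandmother == 0 & g0$g_self == 0 & g0$g_offspring == 0))
  # at eaf 0.5 with a random-mating partner, offspring of a het mother are
  # {0: 1/4, 1: 1/2, 2: 1/4} by enumeration over partner HWE genotypes
  set.seed(6)
  g <- simulate_genotypes(sim_config(n = 200000, eaf = 0.5))
  kid <- g$g_offspring[g$g_self == 1]
  expect_gt(chisq.test(table(factor(kid, 0:2)),
                       p = c(0.25, 0.5, 0.25))$p.value, 0.001)
})

test_that("phenotype moments match the path-model values", {
  cfg <- sim_config(n = 500000, eaf = 0.5, m = 0.1, f = 0.2, rho = 0.2,
                    pattern_fractions = c(0, 0, 1), seed = 9)
  co <- simulate_cohort(cfg)
  expect_equal(cov(co$bw_own, co$g_self), 0.125, tolerance = 0.01)
  expect_equal(cov(co$bw_offspring, co$g_self), 0.100, tolerance = 0.01)
  expect_equal(cov(co$bw_own, co$bw_offspring), 0.225, tolerance = 0.01)
  expect_equal(var(co$bw_own), 1.035, tolerance = 0.015)
  expect_equal(var(co$bw_own), var(co$bw_offspring), tolerance = 0.015)
  # moment consistency with the model, all entries at once
  imp <- implied_moments(sem_params(0.1, 0.2, var(co$g_self), 1, 1, 0.2))
  S <- cov(cbind(co$g_self, co$bw_own, co$bw_offspring))
  expect_true(max(abs(S - imp$cov)) < 0.02)
})

test_that("no genetic paths means no genotype-phenotype covariance", {
  co <- simulate_cohort(sim_config(n = 100000, m = 0, f = 0, rho = 0,
                                   pattern_fractions = c(0, 0, 1), seed = 10))
  expect_lt(abs(cov(co$bw_own, co$g_self)), 3 / sqrt(nrow(co)))
})

test_that("missingness patterns follow the configured multinomial", {
  fr <- c(0.42, 0.27, 0.31)
  co <- simulate_cohort(sim_config(n = 78674, pattern_fractions = fr, seed = 11))
  counts <- table(co$pattern)
  exp_counts <- 78674 * fr
  # 99% multinomial bounds per cell
  bound <- 2.576 * sqrt(78674 * fr * (1 - fr))
  expect_true(all(abs(as.numeric(counts) - exp_counts) < bound))
  expect_true(all(is.na(co$bw_offspring[co$pattern == "OWN_ONLY"])))
  expect_true(all(is.na(co$bw_own[co$pattern == "OFFSPRING_ONLY"])))

  all_own <- simulate_cohort(sim_config(n = 200, pattern_fractions = c(1, 0, 0),
                                        seed = 12))
  expect_true(all(all_own$pattern == "OWN_ONLY"))
  complete <- simulate_cohort(sim_config(n = 200, pattern_fractions = c(0, 0, 1),
                                         seed = 12))
  expect_true(all(stats::complete.cases(complete)))
})

test_that("a fixed seed reproduces the cohort bit-for-bit", {
  cfg <- sim_config(n = 3000, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("dosage noise stays within [0, 2] and is off by default", {
  co <- simulate_cohort(sim_config(n = 500, seed = 2))
  expect_false("dosage_self" %in% names(co))
  cod <- simulate_cohort(sim_config(n = 500, dosage_noise_sd = 0.2, seed = 2))
  expect_true(all(cod$dosage_self >= 0 & cod$dosage_self <= 2))
})

test_that("reporting artifacts are recovered or caught exactly by the filters", {
  co <- simulate_cohort(sim_config(n = 4000, pattern_fractions = c(0, 0, 1),
                                   seed = 14))
  co <- co[abs(co$bw_offspring) <= 2, ]  # keep base weights inside 2.5-4.5 kg
  set.seed(15)
  clean <- add_reporting_artifacts(co)
  res <- filter_offspring_bw(clean)
  expect_equal(nrow(res$kept), nrow(clean))  # round trip, nothing removed
  expect_equal(res$kept$bw_kg, clean$kg_true, tolerance = 1e-12)

  set.seed(16)
  dirty <- add_reporting_artifacts(co, n_out_of_range = 17, n_discrepant = 9,
                                   frac_repeat = 0.1)
  res <- filter_offspring_bw(dirty)
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(dirty))
  expect_equal(sum(res$excluded$reason == "RANGE"), 17)
  expect_equal(sum(res$excluded$reason == "REPEAT_DISCREPANCY"), 9)
  expect_setequal(res$excluded$id, dirty$id[dirty$artifact != "NONE"])
})
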