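#' Configuration for a synthetic three-generation cohort
#'
#' Bundles and validates the generative parameters of the simulator: a single
#' biallelic SNP segregating at Hardy-Weinberg equilibrium, Mendelian
#' transmission across grandmother -> mother -> child with random-mating
#' partners, and birth-weight phenotypes generated from the path model
#' `BW = m * G_G + f * SNP + e` and `BW_O = m * SNP + f * G_O + e_O`
#' with bivariate-normal residuals.
#'
#' @param n Number of genotyped women (one trio each).
#' @param eaf Effect allele frequency in `[0, 1]`.
#' @param m Maternal effect: SD units of offspring birth weight per maternal
#'   allele, acting through the intrauterine environment.
#' @param f Fetal effect: SD units of own birth weight per own allele.
#' @param sigma2,sigma2_o Residual variances of own and offspring birth weight.
#' @param rho Residual covariance between the two birth weights (absorbs
#'   shared polygenic and environmental sources).
#' @param pattern_fractions Length-3 numeric (own-only, offspring-only, both)
#'   summing to 1: the planned-missingness mix.
#' @param dosage_noise_sd Optional SD of Gaussian noise added to hard calls to
#'   mimic imputed dosages (clamped to `[0, 2]`); 0 disables.
#' @param seed Integer RNG seed honoured by [simulate_cohort()].
#'
#' @return A list of class `matfet_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n = 1000, eaf = 0.3, m = 0.05, f = 0.03, seed = 1)
sim_config <- function(n = 10000, eaf = 0.3, m = 0.05, f = 0.03,
                       sigma2 = 1, sigma2_o = 1, rho = 0.2,
                       pattern_fractions = c(own_only = 0.42,
                                             offspring_only = 0.27,
                                             both = 0.31),
                       dosage_noise_sd = 0, seed = NULL) {
  if (n < 1) abort("`n` must be a positive count.")
  if (eaf < 0 || eaf > 1) abort("`eaf` must lie in [0, 1].")
  if (sigma2 <= 0 || sigma2_o <= 0) {
    abort("Residual variances `sigma2` and `sigma2_o` must be positive.")
  }
  if (abs(rho) > sqrt(sigma2 * sigma2_o)) {
    abort("`rho` violates Cauchy-Schwarz: residual covariance matrix is not PSD.")
  }
  pf <- as.numeric(pattern_fractions)
  if (length(pf) != 3 || any(pf < 0) || abs(sum(pf) - 1) > 1e-12) {
    abort("`pattern_fractions` must be 3 non-negative proportions summing to 1.")
  }
  structure(
    list(n = as.integer(n), eaf = eaf, m = m, f = f,
         sigma2 = sigma2, sigma2_o = sigma2_o, rho = rho,
         pattern_fractions = setNames(pf, c("own_only", "offspring_only", "both")),
         dosage_noise_sd = dosage_noise_sd,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "matfet_sim_config"
  )
}

#' Mendelian transmission of one biallelic genotype
#'
#' Each parent passes one allele drawn uniformly from their two; the child
#' genotype is the sum. Vectorised over parents.
#'
#' @param g_mother,g_father Integer allele counts in `{0, 1, 2}` (recycled to
#'   a common length).
#' @return Integer vector of child allele counts.
#' @export
#' @examples
#' mendelian_transmit(2, 2)  # always 2
mendelian_transmit <- function(g_mother, g_father) {
  if (!all(g_mother %in% 0:2) || !all(g_father %in% 0:2)) {
    abort("Parental genotypes must be allele counts in {0, 1, 2}.")
  }
  nn <- max(length(g_mother), length(g_father))
  g_mother <- rep_len(g_mother, nn)
  g_father <- rep_len(g_father, nn)
  rbinom(nn, 1L, g_mother / 2) + rbinom(nn, 1L, g_father / 2)
}

#' Simulate three-generation genotypes under HWE and random mating
#'
#' Grandmother and all partners are independent Hardy-Weinberg draws at
#' `eaf`; the woman's genotype is a Mendelian transmission from grandmother
#' and a random grandfather, and her child's from her and a random partner.
#'
#' @param config A [sim_config()].
#' @return Tibble with `id`, `g_grandmother`, `g_self`, `g_offspring` (and
#'   `dosage_self` when dosage noise is enabled).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "matfet_sim_config"))
  n <- config$n
  p <- config$eaf
  g_gm <- rbinom(n, 2L, p)
  g_gf <- rbinom(n, 2L, p)
  g_self <- mendelian_transmit(g_gm, g_gf)
  g_partner <- rbinom(n, 2L, p)
  g_off <- mendelian_transmit(g_self, g_partner)
  out <- tibble::tibble(id = seq_len(n),
                        g_grandmother = g_gm,
                        g_self = g_self,
                        g_offspring = g_off)
  if (config$dosage_noise_sd > 0) {
    out$dosage_self <- pmin(pmax(g_self + rnorm(n, 0, config$dosage_noise_sd), 0), 2)
  }
  out
}

#' Simulate birth-weight phenotypes from the path model
#'
#' Draws residual pairs from the bivariate normal with variances
#' `(sigma2, sigma2_o)` and covariance `rho`, then forms
#' `bw_own = m * g_grandmother + f * g_self + e` and
#' `bw_offspring = m * g_self + f * g_offspring + e_o`. The sample moment
#' matrix of `(g_self, bw_own, bw_offspring)` converges to
#' [implied_moments()] of the same parameters.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return `genotypes` with `bw_own` and `bw_offspring` columns added.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "matfet_sim_config"))
  n <- nrow(genotypes)
  s2 <- config$sigma2
  s2o <- config$sigma2_o
  rho <- config$rho
  cond_var <- s2o - rho^2 / s2
  if (cond_var < 0) abort("Residual covariance matrix is not positive semi-definite.")
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  e1 <- sqrt(s2) * z1
  e2 <- (rho / s2) * e1 + sqrt(cond_var) * z2
  genotypes |>
    dplyr::mutate(
      bw_own = config$m * .data$g_grandmother + config$f * .data$g_self + e1,
      bw_offspring = config$m * .data$g_self + config$f * .data$g_offspring + e2
    )
}

#' Assign missingness patterns completely at random
#'
#' Each record is assigned one of the three reporting patterns by a
#' multinomial draw with the configured fractions; the birth weight a
#' pattern does not observe is set to `NA`. Assignment is independent of
#' genotype and phenotype (missing completely at random), which is the
#' condition under which full-information maximum likelihood is valid.
#'
#' @param records Cohort tibble with `bw_own` and `bw_offspring`.
#' @param config The [sim_config()] supplying `pattern_fractions`.
#' @return `records` with a `pattern` column in
#'   `{OWN_ONLY, OFFSPRING_ONLY, BOTH}` and masked phenotypes.
#' @export
apply_missingness <- function(records, config) {
  stopifnot(inherits(config, "matfet_sim_config"))
  lv <- c("OWN_ONLY", "OFFSPRING_ONLY", "BOTH")
  pat <- sample(lv, nrow(records), replace = TRUE, prob = config$pattern_fractions)
  records |>
    dplyr::mutate(
      pattern = factor(pat, levels = lv),
      bw_own = ifelse(pat == "OFFSPRING_ONLY", NA_real_, .data$bw_own),
      bw_offspring = ifelse(pat == "OWN_ONLY", NA_real_, .data$bw_offspring)
    )
}

#' Simulate a complete patterned cohort
#'
#' Runs [simulate_genotypes()], [simulate_phenotypes()] and
#' [apply_missingness()] under the config's seed. With a fixed seed the
#' table is bit-for-bit reproducible.
#'
#' @param config A [sim_config()].
#' @return Patterned cohort tibble.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 500, seed = 7))
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "matfet_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  simulate_genotypes(config) |>
    simulate_phenotypes(config) |>
    apply_missingness(config)
}

#' Turn offspring birth weights into raw pound-denominated reports
#'
#' Emulates questionnaire reporting so the cleaning filters have something
#' to remove: birth weight on the z scale is mapped to kilograms
#' (`mean_kg + sd_kg * z`), reported in pounds (`kg / 0.45`), and a
#' configurable set of artifacts is injected. `n_out_of_range` records get a
#' true weight below 2.5 kg; `n_discrepant` records get a second report
#' offset by `discrepancy_lb` pounds; a further `frac_repeat` get a benign
#' identical second report. The ground-truth id and kilogram value are
#' retained so tests can verify exactly which records a filter removed.
#'
#' @param records Cohort tibble with non-missing `bw_offspring`.
#' @param n_out_of_range,n_discrepant Counts of injected violations.
#' @param frac_repeat Fraction given an identical repeat report.
#' @param discrepancy_lb Offset of the discrepant second report (>= 1 lb
#'   triggers the repeat-report exclusion).
#' @param mean_kg,sd_kg Affine map from z units to kilograms (1 SD of birth
#'   weight is taken as 484 g).
#' @return Tibble `id`, `report_1`, `report_2` (pounds), `multiple_birth`,
#'   `kg_true`, `artifact`.
#' @export
add_reporting_artifacts <- function(records, n_out_of_range = 0, n_discrepant = 0,
                                    frac_repeat = 0, discrepancy_lb = 1,
                                    mean_kg = 3.5, sd_kg = 0.484) {
  rec <- dplyr::filter(records, !is.na(.data$bw_offspring))
  n <- nrow(rec)
  if (n_out_of_range + n_discrepant > n) {
    abort("More injected artifacts than available records.")
  }
  kg <- mean_kg + sd_kg * rec$bw_offspring
  artifact <- rep("NONE", n)
  idx <- sample.int(n, n_out_of_range + n_discrepant)
  oor <- idx[seq_len(n_out_of_range)]
  dis <- idx[setdiff(seq_along(idx), seq_len(n_out_of_range))]
  kg[oor] <- runif(length(oor), 1.0, 2.4)
  artifact[oor] <- "OUT_OF_RANGE"
  report_1 <- kg / 0.45
  report_2 <- rep(NA_real_, n)
  report_2[dis] <- report_1[dis] + discrepancy_lb
  artifact[dis] <- "DISCREPANT"
  if (frac_repeat > 0) {
    ben <- which(artifact == "NONE" & runif(n) < frac_repeat)
    report_2[ben] <- report_1[ben]
  }
  tibble::tibble(id = rec$id, report_1 = report_1, report_2 = report_2,
                 multiple_birth = FALSE, kg_true = kg, artifact = artifact)
}
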