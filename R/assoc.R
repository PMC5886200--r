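#' Additive association of a birth-weight z-score with genotype
#'
#' Ordinary least-squares regression of the phenotype on allele dosage with
#' an intercept and optional covariates (an additive genetic model). The
#' slope on dosage is the per-allele effect in phenotype SD units; its
#' standard error comes from the residual variance and the two-sided p-value
#' from the t distribution. Dosages may be fractional in `[0, 2]`; the
#' effect allele frequency is `mean(dosage) / 2`.
#'
#' @param data Data frame holding the analysis columns.
#' @param genotype Name of the dosage column.
#' @param phenotype Name of the phenotype column.
#' @param covariates Character vector of covariate column names (covariates
#'   absent from `data` are dropped with a message, mirroring cohorts where
#'   e.g. gestational duration was not collected).
#' @param snp_id,effect_allele,other_allele Annotation carried into the
#'   result.
#' @return One-row tibble: `snp_id`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `p`, `n`, `status` (`"OK"` or `"MONOMORPHIC"`, the latter
#'   with `NA` estimates).
#' @export
#' @examples
#' d <- data.frame(g = rbinom(500, 2, 0.3), bw = rnorm(500))
#' additive_assoc(d, "g", "bw")
additive_assoc <- function(data, genotype = "g_self", phenotype = "bw_z",
                           covariates = character(),
                           snp_id = NA_character_, effect_allele = NA_character_,
                           other_allele = NA_character_) {
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    rlang::inform(paste0("Covariate(s) not in data, analysed without: ",
                         paste(missing_cov, collapse = ", ")))
    covariates <- intersect(covariates, names(data))
  }
  cols <- c(genotype, phenotype, covariates)
  stopifnot(all(cols %in% names(data)))
  d <- data[complete.cases(data[cols]), cols, drop = FALSE]
  g <- d[[genotype]]
  n <- nrow(d)
  skeleton <- tibble::tibble(snp_id = snp_id, effect_allele = effect_allele,
                             other_allele = other_allele,
                             eaf = mean(g) / 2, beta = NA_real_, se = NA_real_,
                             p = NA_real_, n = n, status = "OK")
  if (var(g) == 0) {
    skeleton$status <- "MONOMORPHIC"
    return(skeleton)
  }
  if (n <= length(covariates) + 2) abort("Too few complete records for the regression.")
  X <- cbind(1, g, as.matrix(d[covariates]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("Design matrix is rank deficient.")
  beta_hat <- qr.coef(qrX, d[[phenotype]])
  res <- qr.resid(qrX, d[[phenotype]])
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * chol2inv(chol(crossprod(X)))[2, 2])
  skeleton$beta <- unname(beta_hat[2])
  skeleton$se <- se
  skeleton$p <- if (se == 0) 0 else 2 * pt(-abs(beta_hat[2] / se), df)
  skeleton
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (the standard exact HWE test).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major homozygote, heterozygote,
#'   minor homozygote); non-negative, total > 0.
#' @return Exact p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact(1, 0, 1)  # 1/3
hwe_exact <- function(n_aa, n_ab, n_bb) {
  if (any(c(n_aa, n_ab, n_bb) < 0)) abort("Genotype counts must be non-negative.")
  n <- n_aa + n_ab + n_bb
  if (n == 0) abort("Total genotype count must be positive.")
  n_rare <- min(2 * n_aa + n_ab, 2 * n_bb + n_ab)
  hets <- seq.int(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # log P(h | allele counts) up to a constant
  logp <- h_logprob(hets, n, n_rare)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_ab, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

h_logprob <- function(h, n, n_rare) {
  h * log(2) - lgamma(h + 1) - lgamma((n_rare - h) / 2 + 1) -
    lgamma((2 * n - n_rare - h) / 2 + 1)
}

#' Variant-level quality-control filters
#'
#' Applies the per-profile exclusion rules used before meta-analysis:
#'
#' * `"autosomal-meta"`: MAF < 0.01, or imputation quality below the
#'   dialect's threshold — PLINK `info` < 0.8, MACH/Beagle `r2hat` < 0.3,
#'   SNPTEST `proper_info` < 0.4 (strict inequalities; boundary values kept).
#' * `"x-chromosome"`: HWE p < 1e-6, MAF < 0.01, or missing rate > 0.015.
#' * `"followup"`: HWE p < 0.0028 (Bonferroni 0.05/18) for directly
#'   genotyped variants; imputed variants instead require quality > 0.8.
#'
#' Rows are conserved: kept + excluded = input.
#'
#' @param qc Tibble with `snp_id`, `eaf`, and per profile some of
#'   `quality_metric`, `dialect` (`PLINK_INFO`, `MACH_R2HAT`,
#'   `SNPTEST_PROPER_INFO`), `hwe_p`, `missing_rate`, `genotyped` (logical).
#'   Quality metrics slightly above 1 are clamped to 1.
#' @param profile One of the three profile names.
#' @return List with `kept` and `excluded` (`snp_id`, `reason`).
#' @export
filter_variants <- function(qc, profile = c("autosomal-meta", "x-chromosome",
                                            "followup")) {
  profile <- match.arg(profile)
  maf <- pmin(qc$eaf, 1 - qc$eaf)
  reason <- rep("NONE", nrow(qc))
  quality_fail <- function(q) {
    if (!all(q$dialect %in% c("PLINK_INFO", "MACH_R2HAT", "SNPTEST_PROPER_INFO"))) {
      abort("Unknown imputation-quality dialect.")
    }
    qual <- pmin(q$quality_metric, 1)
    thr <- c(PLINK_INFO = 0.8, MACH_R2HAT = 0.3, SNPTEST_PROPER_INFO = 0.4)
    qual < thr[q$dialect]
  }
  if (profile == "autosomal-meta") {
    reason[quality_fail(qc)] <- "LOW_QUALITY"
    reason[maf < 0.01] <- "LOW_MAF"
  } else if (profile == "x-chromosome") {
    reason[qc$missing_rate > 0.015] <- "MISSING_RATE"
    reason[qc$hwe_p < 1e-6] <- "HWE"
    reason[maf < 0.01] <- "LOW_MAF"
  } else {
    genotyped <- if ("genotyped" %in% names(qc)) qc$genotyped else rep(TRUE, nrow(qc))
    imputed_fail <- !genotyped & !(pmin(qc$quality_metric, 1) > 0.8)
    reason[imputed_fail] <- "LOW_QUALITY"
    reason[genotyped & qc$hwe_p < 0.0028] <- "HWE"
  }
  bad <- which(reason != "NONE")
  list(kept = qc[reason == "NONE", , drop = FALSE],
       excluded = tibble::tibble(snp_id = qc$snp_id[bad],
                                 reason = reason[bad]))
}

#' Genomic control
#'
#' Computes the inflation factor `lambda` as the median association
#' chi-square divided by the median of the 1-df chi-square distribution
#' (0.4549364), and divides the statistics by `lambda` when it exceeds 1.
#' Deflation is never applied: for `lambda <= 1` statistics are returned
#' unchanged (lambda is still reported).
#'
#' @param chisq_stats Non-negative 1-df chi-square statistics.
#' @return List with `lambda` and `adjusted`.
#' @export
genomic_control <- function(chisq_stats) {
  if (length(chisq_stats) == 0) abort("Need at least one chi-square statistic.")
  if (any(chisq_stats < 0, na.rm = TRUE)) abort("Chi-square statistics must be non-negative.")
  lambda <- median(chisq_stats, na.rm = TRUE) / qchisq(0.5, df = 1)
  list(lambda = lambda,
       adjusted = if (lambda > 1) chisq_stats / lambda else chisq_stats)
}
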