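#' Convert pounds to kilograms
#'
#' Uses the factor 0.45 kg per pound, the convention adopted for
#' questionnaire birth-weight reports.
#'
#' @param x Weight in pounds (non-negative).
#' @return Weight in kilograms, `0.45 * x` exactly.
#' @export
#' @examples
#' pounds_to_kg(7)  # 3.15
pounds_to_kg <- function(x) {
  if (any(x < 0, na.rm = TRUE)) abort("Weights in pounds must be non-negative.")
  0.45 * x
}

#' Filter offspring birth-weight reports
#'
#' Applies the offspring birth-weight exclusions: records flagged as multiple
#' births are removed; records with two reports differing by at least 1 lb
#' (0.45 kg) are removed; records whose derived weight falls below 2.5 kg or
#' above 4.5 kg are removed. The boundaries 2.5 and 4.5 kg themselves are
#' kept (the rule is strict `<`/`>`), and the 1 lb repeat-report rule is
#' inclusive. The filter is idempotent and conserves rows: every input row
#' appears in exactly one of `kept` and `excluded`.
#'
#' @param reports Tibble with `id`, `report_1` and optionally `report_2`
#'   (pounds), and optionally a logical `multiple_birth` flag. A pre-derived
#'   `bw_kg` column is honoured; otherwise `bw_kg = pounds_to_kg(report_1)`.
#' @return List with `kept` (input rows plus `bw_kg`) and `excluded`
#'   (`id`, `reason`, `value`); reasons are `MULTIPLE_BIRTH`,
#'   `REPEAT_DISCREPANCY`, `RANGE`.
#' @export
filter_offspring_bw <- function(reports) {
  rep2 <- if ("report_2" %in% names(reports)) reports$report_2 else NA_real_
  multi <- if ("multiple_birth" %in% names(reports)) {
    isTRUE_v(reports$multiple_birth)
  } else rep(FALSE, nrow(reports))
  bw_kg <- if ("bw_kg" %in% names(reports)) {
    reports$bw_kg
  } else pounds_to_kg(reports$report_1)
  # inclusive >= 1 lb, with an epsilon so reports differing by exactly 1 lb
  # are caught despite floating-point representation
  discrepant <- !is.na(rep2) & abs(reports$report_1 - rep2) >= 1 - 1e-9
  out_of_range <- bw_kg < 2.5 | bw_kg > 4.5
  reason <- dplyr::case_when(
    multi ~ "MULTIPLE_BIRTH",
    discrepant ~ "REPEAT_DISCREPANCY",
    out_of_range ~ "RANGE",
    .default = "NONE"
  )
  reports$bw_kg <- bw_kg
  bad <- which(reason != "NONE")
  list(
    kept = reports[reason == "NONE", , drop = FALSE],
    excluded = tibble::tibble(id = reports$id[bad],
                              reason = reason[bad],
                              value = bw_kg[bad])
  )
}

isTRUE_v <- function(x) !is.na(x) & x

#' Standardize to a z-score
#'
#' Centres and scales to sample mean 0 and sample SD 1 (n - 1 denominator).
#' Missing values are propagated and ignored in the moments.
#'
#' @param values Numeric vector with at least 2 non-missing values.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort("Need at least 2 non-missing values to z-score.")
  s <- sd(values[ok])
  if (s == 0) abort("Cannot z-score a constant vector (zero variance).")
  (values - mean(values[ok])) / s
}

#' Residualize a phenotype on covariates, then z-score
#'
#' Ordinary least-squares residuals of the phenotype on an intercept plus the
#' supplied covariates, re-standardized to a z-score. Used to adjust birth
#' weight for sex, principal components and genotyping batch before analysis.
#'
#' @param pheno Numeric phenotype vector.
#' @param covariates Data frame or matrix of covariates (may be `NULL` or
#'   zero-column for intercept-only, in which case the result is
#'   `zscore(pheno)`).
#' @return Residualized, z-scored phenotype; rows with missing phenotype or
#'   covariates return `NA`.
#' @export
adjust_covariates <- function(pheno, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) return(zscore(pheno))
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  Xi <- cbind(`(Intercept)` = 1, X)
  ok <- !is.na(pheno) & complete.cases(X)
  qrX <- qr(Xi[ok, , drop = FALSE])
  if (qrX$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(Xi))]]
    abort(paste0("Covariate matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  res <- rep(NA_real_, length(pheno))
  res[ok] <- qr.resid(qrX, pheno[ok])
  if (sd(res[ok]) <= 1e-10 * sd(pheno[ok])) {
    abort("Residuals have (numerically) zero variance: phenotype is linear in the covariates.")
  }
  zscore(res)
}

#' Rank-based inverse-normal transformation
#'
#' Maps values to normal quantiles of their offset ranks,
#' `qnorm((r - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by default
#' (so the denominator is `n + 1/4`). Ties share the average rank; order is
#' preserved; the result is invariant to any monotone transform of the input.
#'
#' @param values Numeric vector with at least 2 distinct non-missing values.
#' @param offset Rank offset constant; 3/8 (Blom) by default.
#' @return Transformed vector with missing values propagated.
#' @export
inverse_normal <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  if (length(unique(values[ok])) < 2) {
    abort("Inverse-normal transform needs at least 2 distinct values.")
  }
  n <- sum(ok)
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Prepare blood-pressure measurements
#'
#' Averages the two readings (a single valid reading is used as-is and
#' logged), adds the antihypertensive-medication offset (+15 mmHg systolic,
#' +10 mmHg diastolic) for medicated individuals, excludes records whose two
#' readings differ by more than `4.56 * trait_sd` mmHg, and finally excludes
#' adjusted values more than 4.56 SD from the analysis sample's own mean.
#' The trait SDs default to 19.7 mmHg (systolic) and 13.1 mmHg (diastolic).
#'
#' @param records Tibble with `id`, `reading_1`, `reading_2`, `on_medication`.
#' @param trait `"sbp"` or `"dbp"` (sets the SD and medication offset).
#' @param trait_sd Override for the trait SD in mmHg.
#' @return List with `kept` (adds `adjusted`, `single_reading`) and
#'   `excluded` (`id`, `reason`, `value`); reasons are `READING_DISCREPANCY`,
#'   `OUTLIER`, `NO_READING`.
#' @export
prep_blood_pressure <- function(records, trait = c("sbp", "dbp"), trait_sd = NULL) {
  trait <- match.arg(trait)
  sd_mmhg <- trait_sd %||% switch(trait, sbp = 19.7, dbp = 13.1)
  med_offset <- switch(trait, sbp = 15, dbp = 10)
  r1 <- records$reading_1
  r2 <- records$reading_2
  n_valid <- (!is.na(r1)) + (!is.na(r2))
  mean_reading <- dplyr::case_when(
    n_valid == 2 ~ (r1 + r2) / 2,
    !is.na(r1) ~ r1,
    !is.na(r2) ~ r2,
    .default = NA_real_
  )
  adjusted <- mean_reading + ifelse(isTRUE_v(records$on_medication), med_offset, 0)
  discrepant <- n_valid == 2 & abs(r1 - r2) > 4.56 * sd_mmhg
  reason <- dplyr::case_when(
    n_valid == 0 ~ "NO_READING",
    discrepant ~ "READING_DISCREPANCY",
    .default = "NONE"
  )
  centre <- mean(adjusted[reason == "NONE"])
  outlier <- reason == "NONE" & abs(adjusted - centre) > 4.56 * sd_mmhg
  reason[outlier] <- "OUTLIER"
  kept <- records[reason == "NONE", , drop = FALSE]
  kept$adjusted <- adjusted[reason == "NONE"]
  kept$single_reading <- n_valid[reason == "NONE"] == 1
  bad <- which(reason != "NONE")
  list(
    kept = kept,
    excluded = tibble::tibble(id = records$id[bad],
                              reason = reason[bad],
                              value = adjusted[bad])
  )
}
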