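#' Conditional regression in mother-child pairs
#'
#' One OLS fit of the offspring birth-weight z-score on maternal and fetal
#' genotype jointly (plus sex and gestational duration where available): the
#' maternal-dosage coefficient is the maternal effect conditional on fetal
#' genotype, and the fetal-dosage coefficient the fetal effect conditional
#' on maternal genotype. Because maternal and fetal genotypes correlate at
#' about 0.5, unconditional single-genotype regressions are biased towards
#' `m + 0.5 f` and `f + 0.5 m`; the joint fit separates the two.
#'
#' @param pairs Tibble with `g_mother`, `g_child` (dosages in `[0, 2]`),
#'   `bw_z`, and optionally `sex` and `gestational_duration`. Covariates
#'   listed in `covariates` but absent from the data are dropped with a
#'   message (some cohorts lack gestational duration).
#' @param covariates Covariate column names to adjust for when present.
#' @return Two-row tibble (term `maternal_conditional` /
#'   `fetal_conditional`) with `beta`, `se`, `p`, `n`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 2000, m = 0.3, f = 0.2, seed = 1))
#' pairs <- data.frame(g_mother = cohort$g_self, g_child = cohort$g_offspring,
#'                     bw_z = cohort$bw_offspring)
#' conditional_regression(pairs[complete.cases(pairs), ], covariates = NULL)
conditional_regression <- function(pairs,
                                   covariates = c("sex", "gestational_duration")) {
  requested <- covariates %||% character()
  covariates <- intersect(requested, names(pairs))
  if (length(setdiff(requested, covariates))) {
    rlang::inform(paste0("Covariate(s) not in data, analysed without: ",
                         paste(setdiff(requested, covariates), collapse = ", ")))
  }
  cols <- c("g_mother", "g_child", "bw_z", covariates)
  stopifnot(all(c("g_mother", "g_child", "bw_z") %in% names(pairs)))
  d <- pairs[complete.cases(pairs[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n <= length(covariates) + 3) abort("Too few complete pairs for the joint regression.")
  r_mc <- cor(d$g_mother, d$g_child)
  if (!is.finite(r_mc) || abs(r_mc) > 0.99) {
    abort("Maternal and fetal genotypes are (near-)collinear; conditional effects are not separable.")
  }
  X <- cbind(1, g_mother = d$g_mother, g_child = d$g_child,
             as.matrix(d[covariates]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) abort("Design matrix is rank deficient.")
  beta_hat <- qr.coef(qrX, d$bw_z)
  res <- qr.resid(qrX, d$bw_z)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv)[2:3])
  est <- unname(beta_hat[2:3])
  tibble::tibble(
    term = c("maternal_conditional", "fetal_conditional"),
    beta = est, se = se,
    p = 2 * pt(-abs(est / se), df),
    n = n
  )
}

#' Meta-analyse per-study conditional pair estimates
#'
#' Delegates to [ivw_meta()] separately for the maternal-conditional and
#' fetal-conditional coefficients across studies.
#'
#' @param per_study_results List of [conditional_regression()] outputs (or
#'   one tibble with a `study_id` column).
#' @return Two-row tibble of pooled `matfet_meta` results keyed by `term`.
#' @export
pair_meta <- function(per_study_results) {
  combined <- if (is.data.frame(per_study_results)) {
    tibble::as_tibble(per_study_results)
  } else {
    dplyr::bind_rows(per_study_results, .id = "study_id")
  }
  combined |>
    dplyr::mutate(term = factor(.data$term, levels = unique(.data$term))) |>
    dplyr::group_by(.data$term) |>
    dplyr::group_modify(~ ivw_meta(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(term = as.character(.data$term))
}
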