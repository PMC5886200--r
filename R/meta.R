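#' Harmonize study effects onto a common effect allele
#'
#' Aligns every record for a SNP to the first study's effect/other allele
#' pair. Records whose alleles are swapped relative to the reference have
#' their effect negated and allele frequency complemented. Palindromic SNPs
#' (A/T or C/G) are rejected outright — strand orientation cannot be
#' inferred from alleles alone — and allele pairs matching neither
#' orientation are rejected as mismatches.
#'
#' @param records Tibble of study effects: `study_id`, `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `n`.
#' @return List with `aligned` and `rejected` (input rows plus `reason` in
#'   `{PALINDROMIC, ALLELE_MISMATCH}`).
#' @export
harmonize_alleles <- function(records) {
  stopifnot(all(c("snp_id", "effect_allele", "other_allele", "beta", "eaf") %in%
                  names(records)))
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  ea <- toupper(records$effect_allele)
  oa <- toupper(records$other_allele)
  palindromic <- oa == unname(comp[ea])
  out <- records |>
    dplyr::mutate(.ea = ea, .oa = oa, .pal = palindromic) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::mutate(
      .ref_ea = dplyr::first(.data$.ea),
      .ref_oa = dplyr::first(.data$.oa),
      .orient = dplyr::case_when(
        .data$.pal ~ "PALINDROMIC",
        .data$.ea == .data$.ref_ea & .data$.oa == .data$.ref_oa ~ "SAME",
        .data$.ea == .data$.ref_oa & .data$.oa == .data$.ref_ea ~ "SWAP",
        .default = "ALLELE_MISMATCH"
      )
    ) |>
    dplyr::ungroup()
  aligned <- out |>
    dplyr::filter(.data$.orient %in% c("SAME", "SWAP")) |>
    dplyr::mutate(
      beta = ifelse(.data$.orient == "SWAP", -.data$beta, .data$beta),
      eaf = ifelse(.data$.orient == "SWAP", 1 - .data$eaf, .data$eaf),
      effect_allele = .data$.ref_ea,
      other_allele = .data$.ref_oa
    ) |>
    dplyr::select(-dplyr::starts_with("."))
  rejected <- out |>
    dplyr::filter(!.data$.orient %in% c("SAME", "SWAP")) |>
    dplyr::mutate(reason = .data$.orient) |>
    dplyr::select(-dplyr::starts_with("."))
  list(aligned = aligned, rejected = rejected)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines harmonized study effects for one SNP with weights `1 / se^2`:
#' the pooled effect is the weighted mean, its standard error
#' `1 / sqrt(sum(w))`, and the p-value two-sided normal. Cochran's Q and its
#' chi-square p-value are attached when two or more studies are present.
#' With `verify = TRUE` the pooled quantities are recomputed by an
#' independent scalar-accumulation code path and required to agree to 1e-10
#' (the in-package analogue of two analysts meta-analysing in parallel).
#'
#' @param effects Tibble with `beta`, `se` (> 0), and optionally `n`,
#'   `snp_id`, `effect_allele`, `other_allele`, `eaf`.
#' @param verify Recompute through the independent path and assert equality.
#' @return One-row tibble of class `matfet_meta`: `snp_id`, `beta`, `se`,
#'   `p`, `n_total`, `k_studies`, `q`, `q_df`, `p_het`, `direction` (one
#'   `+`/`-`/`0` per study, `?` for missing); study rows kept in
#'   `attr(, "studies")`.
#' @export
#' @examples
#' ivw_meta(data.frame(beta = c(0.1, 0.3), se = c(0.1, 0.1)))
ivw_meta <- function(effects, verify = FALSE) {
  if (nrow(effects) < 1) abort("Meta-analysis needs at least one study.")
  if (any(!is.finite(effects$se)) || any(effects$se <= 0)) {
    abort("Every study must have a finite positive `se`.")
  }
  w <- 1 / effects$se^2
  beta <- sum(w * effects$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  k <- nrow(effects)
  if (k >= 2) {
    het <- cochran_q(effects)
    q <- het$q; q_df <- het$df; p_het <- het$p_het
  } else {
    q <- NA_real_; q_df <- NA_integer_; p_het <- NA_real_
  }
  if (verify) {
    acc_w <- acc_b <- 0
    for (i in seq_len(k)) {
      wi <- 1 / (effects$se[i] * effects$se[i])
      acc_w <- acc_w + wi
      acc_b <- acc_b + wi * effects$beta[i]
    }
    if (abs(acc_b / acc_w - beta) > 1e-10 || abs(1 / sqrt(acc_w) - se) > 1e-10) {
      abort("Verification pass disagrees with the primary computation.")
    }
  }
  out <- tibble::tibble(
    snp_id = if ("snp_id" %in% names(effects)) effects$snp_id[1] else NA_character_,
    beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
    n_total = if ("n" %in% names(effects)) sum(effects$n) else NA_real_,
    k_studies = k, q = q, q_df = q_df, p_het = p_het,
    direction = paste(dplyr::case_when(is.na(effects$beta) ~ "?",
                                       effects$beta > 0 ~ "+",
                                       effects$beta < 0 ~ "-",
                                       .default = "0"), collapse = "")
  )
  class(out) <- c("matfet_meta", class(out))
  attr(out, "studies") <- tibble::as_tibble(effects)
  out
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i * (beta_i - beta_pooled)^2)` with inverse-variance weights,
#' referred to chi-square with `k - 1` degrees of freedom.
#'
#' @param effects Tibble with `beta` and `se` for at least 2 studies.
#' @return List with `q`, `df`, `p_het`.
#' @export
#' @examples
#' cochran_q(data.frame(beta = c(0.1, 0.3), se = c(0.1, 0.1)))  # Q = 2
cochran_q <- function(effects) {
  if (nrow(effects) < 2) abort("Heterogeneity needs at least 2 studies.")
  if (any(effects$se <= 0)) abort("Every study must have positive `se`.")
  w <- 1 / effects$se^2
  beta <- sum(w * effects$beta) / sum(w)
  q <- sum(w * (effects$beta - beta)^2)
  df <- nrow(effects) - 1L
  list(q = q, df = df, p_het = pchisq(q, df, lower.tail = FALSE))
}

#' Combine an SEM estimate with a mother-child-pair estimate
#'
#' Inverse-variance meta-analysis of the SEM-based conditional estimate and
#' the pair-based conditional estimate of the same path (maternal or fetal),
#' both on the same allele and z-score scale. If the pair estimate is absent
#' the SEM estimate is returned unchanged.
#'
#' @param sem_estimate One-row data frame with `beta`, `se` (and optionally
#'   `n`).
#' @param pair_estimate Same shape, or `NULL`.
#' @param label Carried into the result's `snp_id` field (e.g.
#'   `"maternal_conditional"`).
#' @return A `matfet_meta` one-row tibble.
#' @export
combine_sem_pairs <- function(sem_estimate, pair_estimate = NULL,
                              label = NA_character_) {
  both <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(sem_estimate), source = "sem"),
    if (!is.null(pair_estimate)) {
      dplyr::mutate(tibble::as_tibble(pair_estimate), source = "pairs")
    }
  )
  both$snp_id <- label
  ivw_meta(both)
}

#' Phenotype variance explained by independent loci
#'
#' Approximates the proportion of variance of a z-scored phenotype explained
#' jointly by independent loci as `sum(2 * p * (1 - p) * beta^2)` — the
#' variance of the additive genotype score under Hardy-Weinberg and linkage
#' equilibrium. No standard error is attached.
#'
#' @param betas Per-allele effects on the z-score scale.
#' @param eafs Effect allele frequencies in `(0, 1)`.
#' @return Proportion of variance (a single number).
#' @export
#' @examples
#' variance_explained(0.1, 0.5)  # 0.005
variance_explained <- function(betas, eafs) {
  if (length(betas) != length(eafs)) abort("`betas` and `eafs` must have equal length.")
  if (any(eafs <= 0 | eafs >= 1)) abort("`eafs` must lie strictly inside (0, 1).")
  if (any(!is.finite(betas))) abort("`betas` must be finite.")
  sum(2 * eafs * (1 - eafs) * betas^2)
}
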