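# Tab-delimited interchange with '#'-prefixed provenance comments: the
# METAL-era GWAS convention — diff-able, no binary dependency.

provenance_header <- function(seed = NULL, config = NULL) {
  c(paste0("# matfet ", as.character(utils::packageVersion("matfet"))),
    paste0("# date: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(config)) paste0("# config_hash: ", rlang::hash(config)))
}

#' Write a cohort table with a provenance header
#'
#' Tab-delimited with header row; missing values encoded as `NA`; comment
#' lines prefixed `#` record the package version, timestamp, seed and config
#' hash so a run can be regenerated.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @param seed,config Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL, config = NULL) {
  writeLines(provenance_header(seed, config), path)
  suppressWarnings(
    readr::write_tsv(cohort, path, na = "NA", append = TRUE, col_names = TRUE)
  )
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path Input path.
#' @return Cohort tibble (provenance comments skipped).
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, comment = "#", na = "NA", show_col_types = FALSE,
                  progress = FALSE)
}

# Column synonym maps per summary-statistics dialect; GWAS formats drift, so
# resolution is by name, never by position.
sumstats_synonyms <- list(
  snp_id = c("SNP", "MARKERNAME", "RSID", "SNP_ID"),
  effect_allele = c("EFFECT_ALLELE", "ALLELE1", "EA", "A1"),
  other_allele = c("OTHER_ALLELE", "ALLELE2", "OA", "NEA", "A2"),
  eaf = c("EAF", "FREQ1", "AF", "EFFECT_ALLELE_FREQ"),
  beta = c("BETA", "EFFECT", "B"),
  se = c("SE", "STDERR", "STDERRLOGOR"),
  p = c("P", "P-VALUE", "PVALUE", "PVAL", "P_VALUE"),
  n = c("N", "WEIGHT", "SAMPLESIZE")
)

#' Read METAL-style GWAS summary statistics
#'
#' Resolves columns through a per-dialect synonym map (e.g. `BETA`/`Effect`,
#' `SE`/`StdErr`), types the rows, and collects malformed rows — allele
#' codes outside A/C/G/T, allele frequency outside `[0, 1]`, non-positive
#' standard error, non-finite effect — into a reject table instead of
#' silently dropping them.
#'
#' @param path Tab-delimited file with a header (comment lines `#` skipped).
#' @param study_id Study label attached to every row.
#' @return List with `effects` (study-effect tibble) and `rejected` (row
#'   index, reason). Errors, naming the column, if a required column cannot
#'   be resolved.
#' @export
read_summary_stats <- function(path, study_id = NA_character_) {
  raw <- readr::read_tsv(path, comment = "#", na = c("NA", ""),
                         show_col_types = FALSE, progress = FALSE)
  nm <- toupper(names(raw))
  resolve <- function(field) {
    hit <- which(nm %in% sumstats_synonyms[[field]])
    if (length(hit) == 0) {
      abort(paste0("Required column not found: ", field,
                   " (accepted names: ",
                   paste(sumstats_synonyms[[field]], collapse = "/"), ")"))
    }
    hit[1]
  }
  idx <- vapply(names(sumstats_synonyms), resolve, integer(1))
  eff <- tibble::tibble(
    study_id = study_id,
    snp_id = as.character(raw[[idx[["snp_id"]]]]),
    effect_allele = toupper(as.character(raw[[idx[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[idx[["other_allele"]]]])),
    eaf = as.numeric(raw[[idx[["eaf"]]]]),
    beta = as.numeric(raw[[idx[["beta"]]]]),
    se = as.numeric(raw[[idx[["se"]]]]),
    p = as.numeric(raw[[idx[["p"]]]]),
    n = as.numeric(raw[[idx[["n"]]]])
  )
  reason <- dplyr::case_when(
    !eff$effect_allele %in% c("A", "C", "G", "T") |
      !eff$other_allele %in% c("A", "C", "G", "T") ~ "BAD_ALLELE",
    is.na(eff$eaf) | eff$eaf < 0 | eff$eaf > 1 ~ "BAD_EAF",
    is.na(eff$se) | eff$se <= 0 ~ "BAD_SE",
    !is.finite(eff$beta) ~ "BAD_BETA",
    .default = "NONE"
  )
  bad <- which(reason != "NONE")
  list(effects = eff[reason == "NONE", , drop = FALSE],
       rejected = tibble::tibble(row = bad, reason = reason[bad]))
}

#' Write study effects in METAL-compatible naming
#'
#' @param effects Study-effect tibble (`snp_id`, alleles, `eaf`, `beta`,
#'   `se`, `p`, `n`).
#' @param path Output path.
#' @param seed,config Optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(effects, path, seed = NULL, config = NULL) {
  out <- tibble::tibble(
    SNP = effects$snp_id,
    EFFECT_ALLELE = effects$effect_allele,
    OTHER_ALLELE = effects$other_allele,
    EAF = effects$eaf, BETA = effects$beta, SE = effects$se,
    P = effects$p, N = effects$n
  )
  writeLines(provenance_header(seed, config), path)
  suppressWarnings(
    readr::write_tsv(out, path, na = "NA", append = TRUE, col_names = TRUE)
  )
  invisible(path)
}
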