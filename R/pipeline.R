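pipeline_stages <- c("simulate", "prep", "assoc", "meta", "sem", "pairs", "combine")

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, in order: cohort simulation (one table per study), phenotype
#' preparation (within-study z-scoring of offspring birth weight), per-study
#' additive association, allele harmonization and fixed-effects
#' inverse-variance meta-analysis, the FIML SEM on the first study's
#' patterned records, conditional regression in the complete mother-child
#' records of the remaining studies, and the final combination of SEM and
#' pair estimates. Per-stage record counts are logged; all randomness flows
#' from the root seed via fixed per-study offsets, so the same config and
#' seed reproduce identical numeric outputs.
#'
#' @param config Named list — or path to a YAML file — with fields `seed`,
#'   `out_dir`, optional `n_studies` (default 3), optional `sim` (arguments
#'   to [sim_config()]), optional `stages` (subset of the stage sequence to
#'   run; unknown names error before anything executes).
#' @return Named list of artifact paths, invisibly; writes tab-delimited
#'   outputs plus `log.tsv` under `out_dir`. A failing stage halts with the
#'   stage named; partial output files keep a `.partial` suffix.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$out_dir))
  stages <- config$stages %||% pipeline_stages
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown)) {
    abort(paste0("Unknown pipeline stage(s): ", paste(unknown, collapse = ", ")))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  n_studies <- config$n_studies %||% 3L
  seed <- as.integer(config$seed)
  sim_args <- config$sim %||% list()
  out <- list()
  log <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  finalize <- function(path) {
    final <- sub("\\.partial$", "", path)
    file.rename(path, final)
    final
  }

  run_stage("simulate", function() {
    state$cohorts <- purrr::map(seq_len(n_studies), function(s) {
      cfg <- do.call(sim_config, c(sim_args, list(seed = seed + s)))
      simulate_cohort(cfg)
    })
    out$cohorts <<- purrr::imap_chr(state$cohorts, function(co, s) {
      p <- file.path(config$out_dir, sprintf("cohort_%d.tsv.partial", s))
      write_cohort(co, p, seed = seed + s, config = sim_args)
      finalize(p)
    })
    log$simulate <<- sum(purrr::map_int(state$cohorts, nrow))
  })

  run_stage("prep", function() {
    state$cohorts <- purrr::map(state$cohorts, function(co) {
      co$bw_z <- NA_real_
      ok <- !is.na(co$bw_offspring)
      co$bw_z[ok] <- zscore(co$bw_offspring[ok])
      co
    })
    log$prep <<- sum(purrr::map_int(state$cohorts, ~ sum(!is.na(.x$bw_z))))
  })

  run_stage("assoc", function() {
    state$effects <- purrr::imap(state$cohorts, function(co, s) {
      res <- additive_assoc(co, "g_self", "bw_z", snp_id = "snp_1",
                            effect_allele = "A", other_allele = "G")
      res$study_id <- paste0("study_", s)
      res
    })
    p <- file.path(config$out_dir, "assoc.tsv.partial")
    write_summary_stats(dplyr::bind_rows(state$effects), p, seed = seed)
    out$assoc <<- finalize(p)
    log$assoc <<- length(state$effects)
  })

  run_stage("meta", function() {
    harm <- harmonize_alleles(dplyr::bind_rows(state$effects))
    state$meta <- ivw_meta(harm$aligned, verify = TRUE)
    p <- file.path(config$out_dir, "meta.tsv.partial")
    writeLines(provenance_header(seed), p)
    suppressWarnings(readr::write_tsv(state$meta, p, append = TRUE, col_names = TRUE))
    out$meta <<- finalize(p)
    log$meta <<- nrow(harm$aligned)
  })

  run_stage("sem", function() {
    state$sem <- fit_sem(state$cohorts[[1]])
    p <- file.path(config$out_dir, "sem.json.partial")
    jsonlite::write_json(
      list(estimates = as.list(state$sem$estimates),
           se = as.list(setNames(state$sem$se, names(state$sem$estimates))),
           loglik = state$sem$loglik, converged = state$sem$converged,
           n_by_pattern = as.list(state$sem$n_by_pattern),
           wald = state$sem$wald, seed = seed),
      p, auto_unbox = TRUE, digits = NA)
    out$sem <<- finalize(p)
    log$sem <<- sum(state$sem$n_by_pattern)
  })

  run_stage("pairs", function() {
    pair_studies <- if (n_studies > 1) seq(2, n_studies) else 1L
    state$pair_results <- purrr::map(pair_studies, function(s) {
      co <- state$cohorts[[s]]
      pairs <- tibble::tibble(g_mother = co$g_self, g_child = co$g_offspring,
                              bw_z = co$bw_z)
      conditional_regression(pairs[complete.cases(pairs), ], covariates = NULL)
    })
    state$pair_pooled <- pair_meta(state$pair_results)
    p <- file.path(config$out_dir, "pairs.tsv.partial")
    writeLines(provenance_header(seed), p)
    suppressWarnings(readr::write_tsv(state$pair_pooled, p, append = TRUE,
                                      col_names = TRUE))
    out$pairs <<- finalize(p)
    log$pairs <<- length(state$pair_results)
  })

  run_stage("combine", function() {
    sem_rows <- sem_study_effects(state$sem, snp_id = "snp_1")
    combined <- purrr::map(c("maternal_conditional", "fetal_conditional"),
      function(term) {
        sem_est <- sem_rows[sem_rows$term == term, c("beta", "se", "n")]
        pair_est <- state$pair_pooled[state$pair_pooled$term == term,
                                      c("beta", "se", "n_total")]
        names(pair_est)[3] <- "n"
        combine_sem_pairs(sem_est, pair_est, label = term)
      }) |> dplyr::bind_rows()
    p <- file.path(config$out_dir, "combined.tsv.partial")
    writeLines(provenance_header(seed), p)
    suppressWarnings(readr::write_tsv(combined, p, append = TRUE, col_names = TRUE))
    out$combined <<- finalize(p)
    log$combine <<- nrow(combined)
  })

  log_path <- file.path(config$out_dir, "log.tsv")
  readr::write_tsv(tibble::tibble(stage = names(log),
                                  records = unlist(log)), log_path)
  out$log <- log_path
  invisible(out)
}
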