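#' Tidy a fitted maternal-fetal SEM
#'
#' @param x A [fit_sem()] object.
#' @param conf.level Confidence level for the normal-theory interval.
#' @param ... Unused.
#' @return Tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy matfet_sem
#' @export
tidy.matfet_sem <- function(x, conf.level = 0.95, ...) {
  est <- x$estimates
  se <- x$se
  zcrit <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se))),
    conf.low = unname(est - zcrit * se),
    conf.high = unname(est + zcrit * se)
  )
}

#' Glance at a fitted maternal-fetal SEM
#'
#' @param x A [fit_sem()] object.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `nobs`, `n_own_only`,
#'   `n_offspring_only`, `n_both`, `npar`, `converged`.
#' @method glance matfet_sem
#' @export
glance.matfet_sem <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    nobs = sum(x$n_by_pattern),
    n_own_only = x$n_by_pattern[["OWN_ONLY"]],
    n_offspring_only = x$n_by_pattern[["OFFSPRING_ONLY"]],
    n_both = x$n_by_pattern[["BOTH"]],
    npar = length(x$estimates) - length(x$fixed),
    converged = x$converged
  )
}

#' Plot the conditional maternal and fetal path estimates
#'
#' Point estimates with normal-theory confidence intervals for the maternal
#' (intrauterine) and fetal paths.
#'
#' @param object A [fit_sem()] object.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot matfet_sem
#' @export
autoplot.matfet_sem <- function(object, conf.level = 0.95, ...) {
  zcrit <- qnorm(1 - (1 - conf.level) / 2)
  d <- object$wald |>
    dplyr::mutate(conf.low = .data$estimate - zcrit * .data$std.error,
                  conf.high = .data$estimate + zcrit * .data$std.error)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Effect on birth weight (SD units per allele)",
                  y = NULL,
                  title = "Conditional maternal and fetal genetic effects") +
    ggplot2::theme_minimal()
}

#' Forest plot of a meta-analysis
#'
#' Per-study effects with confidence intervals and the pooled fixed-effects
#' estimate.
#'
#' @param object An [ivw_meta()] result.
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot matfet_meta
#' @export
autoplot.matfet_meta <- function(object, conf.level = 0.95, ...) {
  zcrit <- qnorm(1 - (1 - conf.level) / 2)
  studies <- attr(object, "studies")
  studies$label <- if ("study_id" %in% names(studies)) {
    as.character(studies$study_id)
  } else paste0("study ", seq_len(nrow(studies)))
  d <- dplyr::bind_rows(
    tibble::tibble(label = studies$label, beta = studies$beta, se = studies$se,
                   pooled = FALSE),
    tibble::tibble(label = "pooled (IVW)", beta = object$beta, se = object$se,
                   pooled = TRUE)
  ) |>
    dplyr::mutate(conf.low = .data$beta - zcrit * .data$se,
                  conf.high = .data$beta + zcrit * .data$se,
                  label = factor(.data$label, levels = rev(unique(.data$label))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$label,
                                  shape = .data$pooled)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high),
                             show.legend = FALSE) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 18)) +
    ggplot2::labs(x = "Effect (SD units per allele)", y = NULL) +
    ggplot2::theme_minimal()
}
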