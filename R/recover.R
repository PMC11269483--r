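#' Parameter-recovery run: simulate, fit, compare to ground truth
#'
#' Generates a cohort from a [cohort_config()], fits the generating model,
#' and reports (i) whether each group-level mean's 95% HDI covers the true
#' generating mean (on the transformed scale the hierarchy is defined on),
#' (ii) the Spearman rank correlation between true and posterior-mean
#' subject-level parameters, and (iii) the dose-group contrast table.
#'
#' @param config A [cohort_config()].
#' @param ... Passed to [fit_vpvd()] (chains, iterations, seed...).
#' @return A list of class `vpvd_recovery`: `cohort`, `fit`, `coverage`,
#'   `rank_correlation`, `contrasts`.
#' @export
recover_cohort <- function(config, ...) {
  cohort <- generate_cohort(config)
  fit <- fit_vpvd(cohort$trials, model = config$spec, ...)
  truth <- true_group_means(config)
  coverage <- dplyr::mutate(
    dplyr::left_join(tidy(fit, scale = "transformed"), truth,
                     by = c("parameter", "group")),
    covered = .data$mean_transformed >= .data$hdi95_lower &
      .data$mean_transformed <= .data$hdi95_upper)
  subj <- dplyr::left_join(
    tidy(fit, what = "subject", scale = "transformed"),
    cohort$truth,
    by = c("subject_id", "parameter"))
  rank_correlation <- dplyr::summarise(
    dplyr::group_by(subj, .data$parameter),
    rho = cor(.data$value_transformed, .data$estimate, method = "spearman"),
    .groups = "drop")
  structure(
    list(cohort = cohort, fit = fit, coverage = coverage,
         rank_correlation = rank_correlation,
         contrasts = contrast_table(fit)),
    class = "vpvd_recovery")
}

#' @export
print.vpvd_recovery <- function(x, ...) {
  cat(sprintf(
    "<vpvd_recovery> model %d: %d/%d group means covered by 95%% HDI\n",
    x$fit$spec$model_id, sum(x$coverage$covered), nrow(x$coverage)))
  print(x$rank_correlation)
  invisible(x)
}
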