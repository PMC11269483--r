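#' Plot posterior group-level means with HDIs
#'
#' One panel per model parameter (natural scale), posterior mean with 95%
#' (thin) and 75% (thick) highest density intervals per dose group.
#'
#' @param object A [fit_vpvd()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vpvd_fit <- function(object, ...) {
  td <- tidy(object)
  td$group <- factor(td$group, levels = object$groups)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$hdi95_lower,
                                         ymax = .data$hdi95_upper),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$hdi75_lower,
                                         ymax = .data$hdi75_upper),
                            linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "posterior group mean (natural scale)",
                  title = sprintf("Model %d group-level parameters",
                                  object$spec$model_id)) +
    ggplot2::theme_minimal()
}

#' Learning curves from session-level metrics
#'
#' Group-mean percent correct (standard trials) and percent optimal choice
#' (probe trials) across sessions.
#'
#' @param session_metrics The `session` tibble of [vpvd_metrics()] (or any
#'   tibble with the same columns).
#' @return A ggplot.
#' @export
plot_learning_curves <- function(session_metrics) {
  long <- tidyr::pivot_longer(
    session_metrics,
    cols = c("pct_correct_standard", "pct_optimal_pos_probe",
             "pct_optimal_neg_probe"),
    names_to = "measure", values_to = "pct")
  avg <- dplyr::summarise(
    dplyr::group_by(long, .data$group_label, .data$session, .data$measure),
    pct = mean(.data$pct, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$session, y = .data$pct,
                                    colour = .data$group_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = "session", y = "%", colour = "group") +
    ggplot2::theme_minimal()
}

#' @rdname plot_learning_curves
#' @param object A [vpvd_metrics()] object.
#' @param ... Unused.
#' @export
autoplot.vpvd_metrics <- function(object, ...) {
  plot_learning_curves(object$session)
}

#' Plot dose-group contrasts
#'
#' Posterior mean differences (treated minus control) with 75% and 95% HDIs;
#' contrasts whose 75% HDI excludes zero are highlighted.
#'
#' @param contrasts A [contrast_table()] tibble.
#' @return A ggplot.
#' @export
plot_contrasts <- function(contrasts) {
  ggplot2::ggplot(contrasts,
                  ggplot2::aes(x = .data$group, y = .data$estimate,
                               colour = .data$flag)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$hdi95_lower,
                                         ymax = .data$hdi95_upper),
                            linewidth = 0.4) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$hdi75_lower,
                                         ymax = .data$hdi75_upper),
                            linewidth = 1.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(NONE = "grey40", MODERATE = "orange", STRONG = "red")) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "dose group vs control", y = "difference in group mean") +
    ggplot2::theme_minimal()
}
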