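# ggplot2 displays for the package's result tables.

#' Forest plot of the incident-outcome model grid
#'
#' Odds ratios per 1-SD log hArg with Wald 95% confidence intervals, one
#' panel per model tier, points coloured by sex stratum. Cells without an
#' estimate (annotated failures) are omitted.
#'
#' @param object A `"harg_incident_grid"` tibble from [run_model_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot harg_incident_grid
#' @export
autoplot.harg_incident_grid <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$or))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$outcome,
                                  colour = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~tier, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Odds ratio per 1-SD ln hArg (95% CI)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of MR causal estimates across outcomes
#'
#' Combined IVW estimates with random-effects 95% confidence intervals;
#' outcomes with heterogeneity (Q p-value below `q_alpha`) are marked.
#'
#' @param object A `"harg_mr_grid"` tibble from [mr_grid()].
#' @param q_alpha Heterogeneity flag threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot harg_mr_grid
#' @export
autoplot.harg_mr_grid <- function(object, q_alpha = 0.05, ...) {
  d <- dplyr::filter(object, !is.na(.data$estimate)) |>
    dplyr::mutate(heterogeneous = !is.na(.data$p_q) & .data$p_q < q_alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$outcome,
                                  shape = .data$heterogeneous)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "Causal estimate per 1-unit exposure (95% CI)", y = NULL,
                  shape = "Q p < 0.05") +
    ggplot2::theme_minimal()
}

#' Volcano-style display of a metabolome scan
#'
#' Association beta (SD per SD) against -log10 p, faceted by stratum, with
#' the effective-tests threshold drawn as a horizontal line.
#'
#' @param object A `"harg_scan"` tibble from [metabolome_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot harg_scan
#' @export
autoplot.harg_scan <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 0.002
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta,
                                       y = -log10(.data$p),
                                       colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2,
                        colour = "grey40") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Beta (SD metabolite per 1-SD ln hArg)",
                  y = expression(-log[10](p)), colour = "Below threshold") +
    ggplot2::theme_minimal()
}
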