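#' Plot a bootstrap mediation result
#'
#' Forest-style plot of ACME, ADE, total effect and proportion mediated with
#' their percentile bootstrap intervals.
#'
#' @param object A `prl_mediation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prl_mediation <- function(object, ...) {
  e <- object$estimates
  e$term <- factor(e$term, rev(c("acme", "ade", "total_effect", "prop_mediated")))
  ggplot2::ggplot(e, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper)) +
    ggplot2::labs(
      x = sprintf("Estimate (%d%% percentile bootstrap CI, %s replicates)",
                  round(100 * object$ci_level), format(object$n_boot, big.mark = ",")),
      y = NULL,
      title = "Mediation of the BA-WA EDSS difference by PRL percentage") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity curve
#'
#' ACME as a function of the hypothesised mediator-outcome residual
#' correlation rho, with the zero crossing marked.
#'
#' @param object A `prl_sensitivity` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prl_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$rho, y = .data$acme)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$zero_crossing, linetype = 3,
                        colour = "firebrick") +
    ggplot2::annotate("text", x = object$zero_crossing, y = max(object$curve$acme),
                      hjust = -0.1, vjust = 1, colour = "firebrick",
                      label = sprintf("rho = %.3f", object$zero_crossing)) +
    ggplot2::labs(x = expression(rho~"(mediator-outcome residual correlation)"),
                  y = "ACME (EDSS points)",
                  title = "Sequential-ignorability sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Plot per-race PRL percentage distributions of a cohort
#'
#' @param cohort A cohort data frame.
#' @return A ggplot.
#' @export
plot_prl_distribution <- function(cohort) {
  cohort <- validate_cohort(cohort)
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$prl_percentage, fill = .data$race)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 40) +
    ggplot2::labs(x = "PRL percentage of FLAIR lesions", y = "Patients") +
    ggplot2::theme_minimal()
}
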