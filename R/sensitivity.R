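#' Residual correlation between outcome and mediator models
#'
#' Pearson correlation of the residual vectors of the no-mediator outcome
#' model and the mediator model fitted on the same cohort and the same
#' non-mediator covariate set. Under the linear structural equations this is
#' the value of the sensitivity parameter rho at which the re-identified
#' ACME vanishes.
#'
#' @param total_fit `prl_ols` fit of the outcome on treatment + covariates,
#'   excluding the mediator.
#' @param mediator_fit `prl_ols` fit of the mediator on treatment + the same
#'   covariates.
#' @return The correlation (scalar).
#' @export
residual_correlation <- function(total_fit, mediator_fit) {
  stopifnot(inherits(total_fit, "prl_ols"), inherits(mediator_fit, "prl_ols"))
  if (total_fit$n != mediator_fit$n) {
    abort("fits must share the same cohort")
  }
  e1 <- total_fit$residuals; e2 <- mediator_fit$residuals
  if (sd(e1) == 0 || sd(e2) == 0) {
    abort("degenerate fit: zero-variance residuals",
          class = "prlmediate_degenerate_fit_error")
  }
  cor(e1, e2)
}

#' ACME under a hypothesised mediator-outcome residual correlation
#'
#' Sequential ignorability assumes no unobserved confounding of the
#' mediator-outcome relation; its violation is indexed by rho, the
#' correlation between the structural disturbances of the mediator and
#' outcome equations. In the linear case the ACME re-identified at a given
#' rho has the closed form
#' \deqn{ACME(\rho) = \frac{\hat\alpha\,\sigma_1}{\sigma_2}
#'   \left[\tilde\rho - \rho\sqrt{\frac{1-\tilde\rho^2}{1-\rho^2}}\right]}
#' where \eqn{\sigma_1, \sigma_2} are the residual sds of the no-mediator
#' outcome fit and the mediator fit, \eqn{\tilde\rho} their residual
#' correlation, and \eqn{\hat\alpha} the mediator-model treatment
#' coefficient. Two identities anchor the formula (and are verified in the
#' test suite): ACME(0) equals the product-of-coefficients ACME by the
#' Frisch-Waugh-Lovell theorem, and ACME(rho-tilde) = 0.
#'
#' Both fits must share the non-mediator covariate set (as produced by
#' [sensitivity_analysis()]), otherwise the anchors hold only approximately.
#'
#' @inheritParams residual_correlation
#' @param rho Hypothesised residual correlation, |rho| < 1 (vectorised).
#' @param treatment Treatment design column.
#' @return ACME (EDSS points) at each `rho`.
#' @export
acme_at_rho <- function(total_fit, mediator_fit, rho, treatment = "race_BA") {
  if (any(!is.finite(rho)) || any(abs(rho) >= 1)) {
    abort("`rho` must satisfy |rho| < 1", class = "prlmediate_domain_error")
  }
  alpha <- unname(mediator_fit$coefficients[treatment])
  # sample sds with a common divisor: only the ratio and the correlation
  # enter, so the divisor cancels and ACME(0) = alpha * beta exactly.
  s1 <- sd(total_fit$residuals)
  s2 <- sd(mediator_fit$residuals)
  rho_t <- residual_correlation(total_fit, mediator_fit)
  (alpha * s1 / s2) * (rho_t - rho * sqrt((1 - rho_t^2) / (1 - rho^2)))
}

#' Sensitivity curve of the ACME over a rho grid
#'
#' Tabulates [acme_at_rho()] over a grid and locates the zero crossing by
#' bisection to 1e-6 (analytically, the observed residual correlation).
#'
#' @inheritParams acme_at_rho
#' @param rho_grid Grid of rho values in (-1, 1); default -0.9 to 0.9 in
#'   steps of 0.01.
#' @return An object of class `prl_sensitivity` with elements `curve`
#'   (tibble `rho`, `acme`), `rho_tilde`, `zero_crossing`, `acme_0`.
#' @export
sensitivity_curve <- function(total_fit, mediator_fit,
                              rho_grid = seq(-0.9, 0.9, by = 0.01),
                              treatment = "race_BA") {
  if (any(abs(rho_grid) >= 1)) {
    abort("`rho_grid` must lie within (-1, 1)", class = "prlmediate_domain_error")
  }
  rho_grid <- sort(rho_grid)
  acme <- acme_at_rho(total_fit, mediator_fit, rho_grid, treatment = treatment)
  f <- function(r) acme_at_rho(total_fit, mediator_fit, r, treatment = treatment)
  rho_t <- residual_correlation(total_fit, mediator_fit)
  alpha <- unname(mediator_fit$coefficients[treatment])
  zero <- if (alpha == 0) rho_t else uniroot(f, c(-1 + 1e-9, 1 - 1e-9), tol = 1e-8)$root
  structure(list(
    curve = tibble::tibble(rho = rho_grid, acme = acme),
    rho_tilde = rho_t,
    zero_crossing = zero,
    acme_0 = f(0)
  ), class = "prl_sensitivity")
}

#' Sequential-ignorability sensitivity analysis of a cohort
#'
#' Convenience wrapper: refits the no-mediator outcome model and the
#' mediator model on a shared covariate set (by default the outcome model's
#' non-mediator covariates: age, DMT, non-PRL lesion volume) and returns the
#' [sensitivity_curve()]. The shared covariate set makes the
#' Frisch-Waugh-Lovell anchors exact: the curve at rho = 0 equals the
#' product-of-coefficients ACME computed from these harmonised fits.
#'
#' @param cohort A cohort data frame.
#' @param covariates Shared covariate set for both refits.
#' @inheritParams sensitivity_curve
#' @return A `prl_sensitivity` object.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 2)
#' sens <- sensitivity_analysis(cohort)
#' sens$zero_crossing
sensitivity_analysis <- function(cohort,
                                 covariates = c("age", "dmt", "non_prl_volume"),
                                 rho_grid = seq(-0.9, 0.9, by = 0.01)) {
  cohort <- validate_cohort(cohort)
  total_spec <- model_spec("total_effect", covariates = covariates)
  med_spec <- model_spec("mediator", covariates = covariates)
  dt <- build_design(cohort, total_spec)
  dm <- build_design(cohort, med_spec)
  sensitivity_curve(fit_ols(dt$X, dt$y, total_spec),
                    fit_ols(dm$X, dm$y, med_spec),
                    rho_grid = rho_grid)
}

#' @export
print.prl_sensitivity <- function(x, ...) {
  cat("<prl_sensitivity>\n")
  cat(sprintf("  observed residual correlation rho-tilde: %.4f\n", x$rho_tilde))
  cat(sprintf("  ACME at rho = 0: %.4f; zero crossing at rho = %.4f\n",
              x$acme_0, x$zero_crossing))
  cat(sprintf("  grid: %d points in [%.2f, %.2f]\n", nrow(x$curve),
              min(x$curve$rho), max(x$curve$rho)))
  invisible(x)
}

#' @rdname tidy.prl_mediation
#' @export
tidy.prl_sensitivity <- function(x, ...) x$curve

#' @rdname tidy.prl_mediation
#' @export
glance.prl_sensitivity <- function(x, ...) {
  tibble::tibble(rho_tilde = x$rho_tilde, zero_crossing = x$zero_crossing,
                 acme_0 = x$acme_0, n_grid = nrow(x$curve))
}
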