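#' Product-of-coefficients mediation point estimates
#'
#' In the linear no-interaction mediation model the average causal mediation
#' effect (ACME) is the product of the mediator-model treatment coefficient
#' (alpha) and the outcome-model mediator coefficient (beta); the average
#' direct effect (ADE) is the outcome-model treatment coefficient; the total
#' effect is their sum; and the proportion mediated is ACME / total effect.
#'
#' @param mediator_fit,outcome_fit `prl_ols` fits of the mediator and outcome
#'   models on the same cohort; the outcome fit must contain the mediator
#'   term.
#' @param treatment Treatment design column (default `"race_BA"`).
#' @param mediator Mediator design column (default `"prl_percentage"`).
#' @param tol If `|total effect| < tol` the proportion mediated is undefined
#'   and returned as `NA` (flagged by `prop_defined`).
#' @return A one-row tibble: `acme`, `ade`, `total_effect`, `prop_mediated`,
#'   `prop_defined`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 5)
#' point_estimates(fit_named_model(cohort, "mediator"),
#'                 fit_named_model(cohort, "outcome"))
point_estimates <- function(mediator_fit, outcome_fit,
                            treatment = "race_BA", mediator = "prl_percentage",
                            tol = 1e-6) {
  stopifnot(inherits(mediator_fit, "prl_ols"), inherits(outcome_fit, "prl_ols"))
  if (mediator_fit$n != outcome_fit$n) {
    abort("mediator and outcome fits must come from the same cohort")
  }
  if (!mediator %in% names(outcome_fit$coefficients)) {
    abort(sprintf("outcome fit does not contain the mediator term `%s`", mediator))
  }
  alpha <- unname(mediator_fit$coefficients[treatment])
  beta <- unname(outcome_fit$coefficients[mediator])
  ade <- unname(outcome_fit$coefficients[treatment])
  acme <- alpha * beta
  total <- acme + ade
  defined <- abs(total) >= tol
  tibble::tibble(acme = acme, ade = ade, total_effect = total,
                 prop_mediated = if (defined) acme / total else NA_real_,
                 prop_defined = defined)
}

#' Percentile bootstrap confidence interval
#'
#' Empirical quantiles at `(1 - level) / 2` and `1 - (1 - level) / 2` using
#' linear interpolation of order statistics (`stats::quantile()` type 7, the
#' fixed convention of this package).
#'
#' @param samples Numeric vector of at least 2 finite bootstrap draws.
#' @param level Confidence level in (0, 1).
#' @return Named vector `c(lower = , upper = )`.
#' @export
#' @examples
#' percentile_ci(1:1000, 0.95)
percentile_ci <- function(samples, level = 0.95) {
  if (any(!is.finite(samples))) abort("`samples` must all be finite")
  if (length(samples) < 2) abort("need at least 2 samples")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("`level` must lie in (0, 1)")
  }
  a <- (1 - level) / 2
  q <- quantile(samples, c(a, 1 - a), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

#' Sign-flip bootstrap p-value
#'
#' `p = 2 * min(fraction of draws <= 0, fraction of draws >= 0)`, capped at
#' 1. When no draw crosses zero the p-value is below the bootstrap
#' resolution and is reported as `2 / length(samples)` with attribute
#' `below_resolution = TRUE` (printed as "< 2/n_boot").
#'
#' @param samples Numeric vector of at least 100 bootstrap draws.
#' @return A single numeric p-value (see Details for the resolution flag).
#' @export
bootstrap_pvalue <- function(samples) {
  if (length(samples) < 100) abort("need at least 100 bootstrap samples")
  p <- 2 * min(mean(samples <= 0), mean(samples >= 0))
  if (p == 0) {
    structure(2 / length(samples), below_resolution = TRUE)
  } else {
    min(1, p)
  }
}

#' Nonparametric bootstrap mediation analysis
#'
#' Resamples patient rows with replacement (full-cohort by default;
#' stratified by race optionally), refits the mediator and outcome models on
#' each replicate, and recomputes ACME, ADE, total effect and proportion
#' mediated. Confidence intervals use the percentile method
#' ([percentile_ci()]); p-values use the sign-flip rule
#' ([bootstrap_pvalue()]). Replicates with a rank-deficient design (e.g. a
#' resample missing a DMT level) are redrawn and counted, up to 1% of
#' `n_boot`. Replicates with `|total effect| < tol` are excluded from the
#' proportion-mediated interval and counted as unstable.
#'
#' @param cohort A cohort data frame.
#' @param mediator_spec,outcome_spec [model_spec()] overrides (defaults: the
#'   named mediator and outcome models).
#' @param n_boot Number of bootstrap replicates (>= 100; the study analysis
#'   uses 25,000).
#' @param ci_level Confidence level of the percentile intervals.
#' @param seed Integer seed (required; the index stream is reproducible).
#' @param stratified Resample within race groups instead of the full cohort?
#' @param tol Instability threshold on the replicate total effect.
#' @param keep_draws Keep the replicate draws in the result (needed by
#'   [autoplot.prl_mediation()] densities)?
#' @return An object of class `prl_mediation`; see [tidy.prl_mediation()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 5)
#' med <- bootstrap_mediation(cohort, n_boot = 200, seed = 9)
#' tidy(med)
bootstrap_mediation <- function(cohort,
                                mediator_spec = NULL, outcome_spec = NULL,
                                n_boot = 25000, ci_level = 0.95, seed = NULL,
                                stratified = FALSE, tol = 1e-6,
                                keep_draws = TRUE) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) < 20) abort("cohort must have at least 20 rows")
  if (n_boot < 100) abort("`n_boot` must be at least 100")
  if (is.null(seed)) abort("`seed` is required for bootstrap_mediation()")
  mediator_spec <- mediator_spec %||% model_spec("mediator")
  outcome_spec <- outcome_spec %||% model_spec("outcome")
  dm <- build_design(cohort, mediator_spec)
  do <- build_design(cohort, outcome_spec)
  mediator_col <- outcome_spec$mediator
  point <- point_estimates(fit_ols(dm$X, dm$y, mediator_spec),
                           fit_ols(do$X, do$y, outcome_spec),
                           mediator = mediator_col, tol = tol)

  n <- nrow(cohort)
  strata <- if (stratified) split(seq_len(n), cohort$race) else list(seq_len(n))
  i_alpha <- match("race_BA", colnames(dm$X))
  i_beta <- match(mediator_col, colnames(do$X))
  i_gamma <- match("race_BA", colnames(do$X))
  pm <- ncol(dm$X); po <- ncol(do$X)
  max_redraws <- ceiling(0.01 * n_boot)

  draws <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("acme", "ade", "total_effect", "prop_mediated")))
  n_redrawn <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- unlist(lapply(strata, function(s) s[sample.int(length(s), length(s), replace = TRUE)]),
                      use.names = FALSE)
        fm <- lm.fit(dm$X[idx, , drop = FALSE], dm$y[idx])
        fo <- lm.fit(do$X[idx, , drop = FALSE], do$y[idx])
        if (fm$rank == pm && fo$rank == po) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraws) {
          abort(sprintf("resampling degeneracy: more than %d rank-deficient replicates",
                        max_redraws),
                class = "prlmediate_degeneracy_error")
        }
      }
      acme_b <- fm$coefficients[i_alpha] * fo$coefficients[i_beta]
      ade_b <- fo$coefficients[i_gamma]
      tot_b <- acme_b + ade_b
      draws[b, ] <- c(acme_b, ade_b, tot_b,
                      if (abs(tot_b) >= tol) acme_b / tot_b else NA_real_)
    }
  })

  n_unstable <- sum(is.na(draws[, "prop_mediated"]))
  est_row <- function(term) {
    x <- draws[, term]
    if (term == "prop_mediated") x <- x[!is.na(x)]
    ci <- percentile_ci(x, ci_level)
    p <- bootstrap_pvalue(x)
    tibble::tibble(term = term, estimate = point[[term]],
                   ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
                   p_value = as.numeric(p),
                   p_below_resolution = isTRUE(attr(p, "below_resolution")))
  }
  estimates <- dplyr::bind_rows(lapply(colnames(draws), est_row))

  structure(list(
    estimates = estimates, point = point, n_boot = n_boot,
    ci_level = ci_level, seed = as.integer(seed), stratified = stratified,
    n_unstable = n_unstable, n_redrawn = n_redrawn, nobs = n,
    mediator_spec = mediator_spec, outcome_spec = outcome_spec,
    draws = if (keep_draws) tibble::as_tibble(draws) else NULL
  ), class = "prl_mediation")
}

#' @export
print.prl_mediation <- function(x, ...) {
  cat(sprintf("<prl_mediation>  n = %d patients, %d bootstrap replicates (seed %d%s)\n",
              x$nobs, x$n_boot, x$seed,
              if (x$stratified) ", stratified by race" else ""))
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    pv <- if (e$p_below_resolution[i]) sprintf("< %g", e$p_value[i]) else sprintf("%.4g", e$p_value[i])
    cat(sprintf("  %-14s %8.4f  [%0.4f, %0.4f]  p %s\n", e$term[i], e$estimate[i],
                e$ci_lower[i], e$ci_upper[i], pv))
  }
  if (x$n_unstable > 0) {
    cat(sprintf("  (%d unstable replicates excluded from the proportion-mediated CI)\n",
                x$n_unstable))
  }
  invisible(x)
}

#' Tidiers for fitted prlmediate objects
#'
#' broom-style methods: `tidy()` returns the per-term estimates,
#' `glance()` the one-row fit summary.
#'
#' @param x A `prl_mediation`, `prl_ols` or `prl_sensitivity` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.prl_mediation <- function(x, ...) x$estimates

#' @rdname tidy.prl_mediation
#' @export
glance.prl_mediation <- function(x, ...) {
  tibble::tibble(nobs = x$nobs, n_boot = x$n_boot, ci_level = x$ci_level,
                 seed = x$seed, stratified = x$stratified,
                 n_unstable = x$n_unstable, n_redrawn = x$n_redrawn)
}

#' Serialise a mediation result to JSON
#'
#' @param x A `prl_mediation` object.
#' @param path Optional path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
mediation_to_json <- function(x, path = NULL) {
  payload <- list(
    estimates = x$estimates,
    n_boot = x$n_boot, ci_level = x$ci_level, seed = x$seed,
    stratified = x$stratified, n_unstable = x$n_unstable,
    n_redrawn = x$n_redrawn, nobs = x$nobs,
    mediator_spec_digest = config_digest(x$mediator_spec),
    outcome_spec_digest = config_digest(x$outcome_spec)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
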