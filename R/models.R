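#' Declarative specification of the mediation design's linear models
#'
#' The mediation design uses three ordinary-least-squares models:
#' * `mediator`: PRL percentage on race, adjusting for age and DMT;
#' * `outcome`: EDSS on race, the PRL percentage, age, DMT and non-PRL
#'   lesion volume;
#' * `total_effect`: EDSS on race with the full covariate list of the design
#'   (age, sex, disease duration, DMT, non-PRL lesion volume, median zip-code
#'   income) and no mediator.
#'
#' Race is coded 0/1 with BA = 1; DMT enters as two dummies (`lower`,
#' `untreated`) against the higher-efficacy reference; sex as a `male` dummy;
#' zip-code income is rescaled to units of $10,000 to condition the design.
#'
#' @param role One of `"mediator"`, `"outcome"`, `"total_effect"`.
#' @param response Response column (defaults by role).
#' @param covariates Character vector of adjustment columns (defaults by
#'   role); `dmt` and `sex` expand to dummy sets.
#' @param mediator Mediator column, included in the design iff
#'   `role = "outcome"`.
#' @param treatment Treatment column (default `"race"`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(role = c("mediator", "outcome", "total_effect"),
                       response = NULL, covariates = NULL,
                       mediator = "prl_percentage", treatment = "race") {
  role <- match.arg(role)
  response <- response %||% switch(role,
    mediator = mediator,
    outcome = "edss",
    total_effect = "edss")
  covariates <- covariates %||% switch(role,
    mediator = c("age", "dmt"),
    outcome = c("age", "dmt", "non_prl_volume"),
    total_effect = c("age", "sex", "disease_duration", "dmt",
                     "non_prl_volume", "zip_income"))
  structure(list(role = role, response = response, treatment = treatment,
                 covariates = covariates,
                 mediator = if (role == "outcome") mediator else NULL),
            class = "model_spec")
}

dummy_expansions <- list(
  dmt = list(column = "dmt", reference = "higher",
             levels = c("lower", "untreated"), prefix = "dmt_"),
  sex = list(column = "sex", reference = "female",
             levels = "male", prefix = "sex_")
)

#' Build the design matrix for a model specification
#'
#' Deterministic column order: intercept, treatment dummy (`race_BA`),
#' mediator (outcome role only), then covariates in specification order with
#' categorical columns expanded against their reference level
#' (DMT: higher-efficacy; sex: female). `zip_income` is divided by 10,000.
#'
#' @param cohort A cohort data frame.
#' @param spec A [model_spec()].
#' @return A list with the design matrix `X` (with column names), the
#'   response vector `y`, and the `spec`.
#' @export
build_design <- function(cohort, spec) {
  cols_needed <- setdiff(c(spec$response, spec$treatment, spec$covariates, spec$mediator),
                         NULL)
  missing_cols <- setdiff(cols_needed, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("model columns missing from cohort: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "prlmediate_plan_error")
  }
  n <- nrow(cohort)
  race <- cohort[[spec$treatment]]
  if (!all(race %in% c("BA", "WA"))) {
    abort("unseen treatment level: `race` must be BA or WA",
          class = "prlmediate_coding_error")
  }
  parts <- list("(Intercept)" = rep(1, n), race_BA = as.numeric(race == "BA"))
  if (!is.null(spec$mediator)) parts[[spec$mediator]] <- cohort[[spec$mediator]]
  for (cv in spec$covariates) {
    if (cv %in% names(dummy_expansions)) {
      d <- dummy_expansions[[cv]]
      vals <- cohort[[d$column]]
      known <- c(d$reference, d$levels)
      if (!all(vals %in% known)) {
        abort(sprintf("unseen level in `%s`: %s", d$column,
                      paste(setdiff(unique(vals), known), collapse = ", ")),
              class = "prlmediate_coding_error")
      }
      for (lv in d$levels) parts[[paste0(d$prefix, lv)]] <- as.numeric(vals == lv)
    } else if (cv == "zip_income") {
      parts[["zip_income_10k"]] <- cohort[[cv]] / 1e4
    } else {
      parts[[cv]] <- cohort[[cv]]
    }
  }
  X <- do.call(cbind, parts)
  colnames(X) <- names(parts)
  list(X = X, y = cohort[[spec$response]], spec = spec)
}

#' Ordinary least squares on an explicit design matrix
#'
#' QR-based least squares with classical standard errors
#' (sigma^2 (X'X)^-1, sigma^2 = RSS / (n - rank)) and two-sided p-values from
#' the t distribution with n - rank degrees of freedom. A rank-deficient
#' design raises a collinearity error listing the dependent columns.
#'
#' @param X Numeric design matrix with column names (include an intercept
#'   column explicitly if wanted).
#' @param y Numeric response.
#' @param spec Optional [model_spec()] carried along for downstream use.
#' @return An object of class `prl_ols` with elements `coefficients`,
#'   `se`, `statistic`, `p_value`, `residuals`, `fitted`, `sigma`, `df_residual`,
#'   `rank`, `n`, `r_squared`, `spec`.
#' @export
#' @examples
#' X <- cbind(1, 0:2)
#' fit_ols(X, c(1, 3, 5))$coefficients  # exact line y = 1 + 2x
fit_ols <- function(X, y, spec = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("`y` must match the number of design rows")
  fit <- lm.fit(X, y)
  if (fit$rank < p) {
    piv <- fit$qr$pivot
    abort(sprintf("collinear design: column(s) %s are linearly dependent",
                  paste(colnames(X)[piv[(fit$rank + 1):p]], collapse = ", ")),
          class = "prlmediate_collinearity_error")
  }
  if (n <= fit$rank) abort("need more observations than design rank")
  res <- fit$residuals
  rss <- sum(res^2)
  df <- n - fit$rank
  sigma2 <- rss / df
  R <- qr.R(fit$qr)[seq_len(p), seq_len(p), drop = FALSE]
  xtx_inv <- chol2inv(R)[order(fit$qr$pivot), order(fit$qr$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- fit$coefficients / se
  structure(list(
    coefficients = fit$coefficients, se = setNames(se, colnames(X)),
    statistic = tval, p_value = 2 * pt(-abs(tval), df),
    residuals = res, fitted = y - res, sigma = sqrt(sigma2),
    df_residual = df, rank = fit$rank, n = n,
    r_squared = if (var(y) > 0) 1 - rss / sum((y - mean(y))^2) else 0,
    spec = spec
  ), class = "prl_ols")
}

#' Fit one of the named mediation-design models
#'
#' Dispatches the default [model_spec()] for `role` (overridable) through
#' [build_design()] and [fit_ols()].
#'
#' @param cohort A cohort data frame.
#' @param role `"mediator"`, `"outcome"` or `"total_effect"`.
#' @param spec Optional [model_spec()] overriding the role default.
#' @return A `prl_ols` fit.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 11)
#' tidy(fit_named_model(cohort, "mediator"))
fit_named_model <- function(cohort, role = c("mediator", "outcome", "total_effect"),
                            spec = NULL) {
  role <- match.arg(role)
  cohort <- validate_cohort(cohort)
  spec <- spec %||% model_spec(role)
  d <- build_design(cohort, spec)
  fit_ols(d$X, d$y, spec = spec)
}

#' @export
print.prl_ols <- function(x, ...) {
  role <- if (!is.null(x$spec)) x$spec$role else "ols"
  cat(sprintf("<prl_ols: %s>  n = %d, residual sd = %.4g, R^2 = %.3f\n",
              role, x$n, x$sigma, x$r_squared))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname tidy.prl_mediation
#' @export
tidy.prl_ols <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(x$statistic),
                 p.value = unname(x$p_value))
}

#' @rdname tidy.prl_mediation
#' @export
glance.prl_ols <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = x$sigma,
                 df.residual = x$df_residual, nobs = x$n)
}
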