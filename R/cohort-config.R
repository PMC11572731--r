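#' Configuration of the synthetic MS cohort generator
#'
#' Builds the full parameter set for [generate_cohort()]. Defaults reproduce
#' the published study conditions: 117 Black-American (BA) and 123
#' White-American (WA) patients, per-race covariate distributions matched to
#' the cohort characteristics table, mediator and outcome structural
#' coefficients matched to the reported regression estimates (race effect on
#' PRL percentage 4.65, mediator effect on EDSS 0.021, direct race effect
#' 0.60, age 0.05, DMT lower vs higher -0.58, untreated vs higher -0.31,
#' non-PRL lesion volume 5e-5 per mm^3), and a lesion-count model calibrated
#' to the per-race mean PRL percentages (8.01 / 3.40) and PRL prevalences
#' (55% / 39%).
#'
#' Two generator modes are available. `"linear"` draws the PRL-percentage
#' mediator as an unbounded linear-Gaussian variable, so that ordinary least
#' squares recovers every structural coefficient exactly in expectation;
#' `"count"` draws a zero-truncated negative-binomial FLAIR lesion count and
#' an overdispersed-binomial PRL count (logit-normal per-patient rim
#' probability), so the mediator is a realistic bounded percentage.
#'
#' Intercepts left `NULL` are solved analytically so that the WA group means
#' of the mediator (`mediator$mean_wa`, percent) and of EDSS
#' (`outcome$mean_wa`) match their targets in expectation.
#'
#' @param n_ba,n_wa Group sizes (default 117 BA, 123 WA).
#' @param mode `"linear"` or `"count"` (see Details).
#' @param covariates Per-race covariate distribution parameters; see the
#'   default value for the structure. Each `c(ba = , wa = )` pair is on the
#'   natural scale; `non_prl_volume` gives arithmetic mean/sd of a lognormal;
#'   `flair` gives negative-binomial mean and size (zero-truncated at
#'   generation).
#' @param mediator Structural equation of the PRL percentage: intercept
#'   (`NULL` = solved from `mean_wa`), race effect, age and DMT loadings,
#'   per-race residual sd, and the target WA mean.
#' @param outcome Structural equation of latent EDSS: intercept (`NULL` =
#'   solved from `mean_wa`), direct race effect, mediator coefficient, age and
#'   DMT coefficients, non-PRL-volume coefficient, per-race residual sd, and
#'   the target WA mean.
#' @param count Lesion-count model parameters: `logit_intercept` (WA
#'   per-lesion rim log-odds), `logit_race` (BA shift), and per-race
#'   logit-scale overdispersion sd. Defaults equal the output of
#'   [calibrate_count_model()] on the published per-race targets.
#' @param confounder_strength Loading of a latent standard-normal confounder
#'   added to both the mediator and the outcome disturbances (default 0, i.e.
#'   sequential ignorability holds by construction).
#' @param round_edss If `TRUE`, EDSS is rounded onto the clinical half-point
#'   grid 0, 0.5, ..., 9.5; the default keeps the latent continuous value.
#' @param seed Integer seed stored with the configuration; may be overridden
#'   in [generate_cohort()].
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [calibrate_count_model()]
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cohort <- generate_cohort(cfg)
#' dplyr::count(cohort, race)
cohort_config <- function(n_ba = 117,
                          n_wa = 123,
                          mode = c("linear", "count"),
                          covariates = list(
                            age = list(mean = c(ba = 44.55, wa = 43.00),
                                       sd = c(ba = 12.09, wa = 10.58),
                                       min = 18),
                            male_frac = c(ba = 0.239, wa = 0.309),
                            duration = list(mean = c(ba = 11.00, wa = 10.60),
                                            sd = c(ba = 7.52, wa = 8.30),
                                            min = 0),
                            dmt = list(
                              ba = c(higher = 0.5043, lower = 0.3244, untreated = 0.1713),
                              wa = c(higher = 0.5203, lower = 0.3333, untreated = 0.1464)),
                            income = list(mean = c(ba = 66085.81, wa = 120000.00),
                                          sd = c(ba = 29486.83, wa = 40388.69),
                                          min = 1000),
                            non_prl_volume = list(mean = c(ba = 8029.30, wa = 3600.00),
                                                  sd = c(ba = 9336.09, wa = 5778.24)),
                            prl_lesion_volume = list(mean = 750, sd = 400),
                            flair = list(mu = c(ba = 23.83, wa = 22.00),
                                         size = c(ba = 1.3934, wa = 1.2394))
                          ),
                          mediator = list(intercept = NULL, race = 4.65,
                                          age = 0.05, dmt_lower = -1.5,
                                          dmt_untreated = 1.0,
                                          sd = c(ba = 15.25, wa = 7.50),
                                          mean_wa = 3.40),
                          outcome = list(intercept = NULL, race = 0.60,
                                         mediator = 0.021, age = 0.05,
                                         dmt_lower = -0.58,
                                         dmt_untreated = -0.31,
                                         non_prl_volume = 5e-5,
                                         sd = c(ba = 1.92, wa = 1.47),
                                         mean_wa = 1.30),
                          count = list(logit_intercept = -3.683901,
                                       logit_race = 0.646554,
                                       overdispersion_sd = c(ba = 1.261803,
                                                             wa = 0.862417)),
                          confounder_strength = 0,
                          round_edss = FALSE,
                          seed = NULL) {
  mode <- match.arg(mode)
  cfg <- structure(
    list(n_ba = n_ba, n_wa = n_wa, mode = mode, covariates = covariates,
         mediator = mediator, outcome = outcome, count = count,
         confounder_strength = confounder_strength, round_edss = round_edss,
         seed = seed),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg$mediator$intercept <- cfg$mediator$intercept %||% solve_mediator_intercept(cfg)
  cfg$outcome$intercept <- cfg$outcome$intercept %||% solve_outcome_intercept(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks group sizes, positivity of all scale parameters, DMT probability
#' normalisation, and mode-specific parameters. Errors name the offending
#' field.
#'
#' @param config A [cohort_config()] object.
#' @return `config`, invisibly, if valid.
#' @export
validate_cohort_config <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created by `cohort_config()`")
  }
  for (fld in c("n_ba", "n_wa")) {
    n <- config[[fld]]
    if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
      config_error(fld, "must be a positive integer")
    }
  }
  cv <- config$covariates
  for (fld in c("age", "duration", "income", "non_prl_volume")) {
    if (any(cv[[fld]]$sd <= 0)) config_error(paste0("covariates$", fld, "$sd"), "sd must be > 0")
  }
  if (any(cv$male_frac < 0 | cv$male_frac > 1)) {
    config_error("covariates$male_frac", "must lie in [0, 1]")
  }
  for (r in c("ba", "wa")) {
    pr <- cv$dmt[[r]]
    if (length(pr) != 3 || any(pr < 0) || abs(sum(pr) - 1) > 1e-6) {
      config_error(paste0("covariates$dmt$", r),
                   "must be 3 nonnegative probabilities summing to 1")
    }
    if (!identical(names(pr), c("higher", "lower", "untreated"))) {
      config_error(paste0("covariates$dmt$", r),
                   "must be named higher, lower, untreated")
    }
  }
  if (any(cv$flair$mu <= 0) || any(cv$flair$size <= 0)) {
    config_error("covariates$flair", "negative-binomial mu and size must be > 0")
  }
  if (any(config$mediator$sd <= 0)) config_error("mediator$sd", "must be > 0")
  if (any(config$outcome$sd <= 0)) config_error("outcome$sd", "must be > 0")
  if (any(config$count$overdispersion_sd < 0)) {
    config_error("count$overdispersion_sd", "must be >= 0")
  }
  if (!is.numeric(config$confounder_strength) || length(config$confounder_strength) != 1) {
    config_error("confounder_strength", "must be a single number")
  }
  invisible(config)
}

# Mean of a normal truncated below at `lo`.
truncnorm_mean <- function(mean, sd, lo) {
  a <- (lo - mean) / sd
  mean + sd * dnorm(a) / (1 - pnorm(a))
}

# Expected covariate values per race used in intercept calibration.
expected_covariates <- function(config, race = c("ba", "wa")) {
  race <- match.arg(race)
  cv <- config$covariates
  list(
    age = truncnorm_mean(cv$age$mean[[race]], cv$age$sd[[race]], cv$age$min),
    dmt = cv$dmt[[race]],
    non_prl_volume = cv$non_prl_volume$mean[[race]]
  )
}

# Expected mediator (PRL percentage) for a race under the current config.
expected_mediator <- function(config, race = c("ba", "wa")) {
  race <- match.arg(race)
  if (config$mode == "count") {
    eta <- config$count$logit_intercept +
      if (race == "ba") config$count$logit_race else 0
    tau <- config$count$overdispersion_sd[[race]]
    100 * logit_normal_mean(eta, tau)
  } else {
    e <- expected_covariates(config, race)
    m <- config$mediator
    m$intercept + (race == "ba") * m$race + m$age * e$age +
      m$dmt_lower * e$dmt[["lower"]] + m$dmt_untreated * e$dmt[["untreated"]]
  }
}

solve_mediator_intercept <- function(config) {
  e <- expected_covariates(config, "wa")
  m <- config$mediator
  m$mean_wa - (m$age * e$age + m$dmt_lower * e$dmt[["lower"]] +
                 m$dmt_untreated * e$dmt[["untreated"]])
}

solve_outcome_intercept <- function(config) {
  e <- expected_covariates(config, "wa")
  o <- config$outcome
  # expected WA mediator: linear mode pins it at mediator$mean_wa by
  # construction of the mediator intercept; count mode uses the logit-normal
  # mean implied by the count parameters.
  em <- if (config$mode == "count") expected_mediator(config, "wa") else config$mediator$mean_wa
  o$mean_wa - (o$mediator * em + o$age * e$age +
                 o$dmt_lower * e$dmt[["lower"]] +
                 o$dmt_untreated * e$dmt[["untreated"]] +
                 o$non_prl_volume * e$non_prl_volume)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  groups: %d BA / %d WA, mode = %s\n", x$n_ba, x$n_wa, x$mode))
  cat(sprintf("  mediator: race %.3f, residual sd %.2f/%.2f\n",
              x$mediator$race, x$mediator$sd[["ba"]], x$mediator$sd[["wa"]]))
  cat(sprintf("  outcome:  race %.3f, mediator %.4f, residual sd %.2f/%.2f\n",
              x$outcome$race, x$outcome$mediator,
              x$outcome$sd[["ba"]], x$outcome$sd[["wa"]]))
  cat(sprintf("  confounder_strength: %g, round_edss: %s, seed: %s\n",
              x$confounder_strength, x$round_edss,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Digest of a generator or run configuration
#'
#' Stable hash of every semantic field, used for provenance metadata.
#'
#' @param config Any configuration list.
#' @return A character hash.
#' @export
config_digest <- function(config) {
  rlang::hash(unclass(config))
}

#' Read / write a generator configuration
#'
#' YAML serialisation of [cohort_config()] objects. The packaged default,
#' `system.file("extdata", "default_config.yaml", package = "prlmediate")`,
#' reproduces the study-calibrated cohort.
#'
#' @param path File path.
#' @param config A `cohort_config` object.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (fld in c("n_ba", "n_wa", "mode", "confounder_strength", "round_edss", "seed")) {
    if (!is.null(raw[[fld]])) args[[fld]] <- raw[[fld]]
  }
  for (fld in c("covariates", "mediator", "outcome", "count")) {
    if (!is.null(raw[[fld]])) {
      dflt <- formals(cohort_config)[[fld]]
      args[[fld]] <- utils::modifyList(eval(dflt), lapply(raw[[fld]], yaml_to_vec))
    }
  }
  do.call(cohort_config, args)
}

yaml_to_vec <- function(x) {
  vec_names <- c("ba", "wa", "higher", "lower", "untreated")
  if (is.list(x) && length(x) && all(names(x) %in% vec_names) &&
      all(vapply(x, function(e) is.numeric(e) && length(e) == 1, TRUE))) {
    unlist(x)
  } else if (is.list(x)) {
    lapply(x, yaml_to_vec)
  } else x
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  yaml::write_yaml(vec_to_yaml(unclass(config)), path, precision = 17)
  invisible(path)
}

# named vectors -> maps so YAML round-trips names
vec_to_yaml <- function(x) {
  if (is.list(x)) {
    lapply(x, vec_to_yaml)
  } else if (!is.null(names(x)) && length(x) > 1) {
    as.list(x)
  } else x
}
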