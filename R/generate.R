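#' Generate a synthetic BA/WA MS cohort
#'
#' Draws one patient-level cohort from the structural model described in
#' [cohort_config()]. The mediator (percentage of FLAIR lesions that are
#' paramagnetic rim lesions) and latent EDSS follow the configured linear
#' structural equations in `"linear"` mode; in `"count"` mode the PRL count is
#' an overdispersed binomial given the FLAIR count and the realized percentage
#' feeds the outcome equation. A fixed seed yields a bit-identical cohort.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed; defaults to `config$seed`, which must then be
#'   set.
#' @return A tibble with one row per patient and columns `patient_id`, `race`
#'   (`"BA"`/`"WA"`), `age`, `sex`, `disease_duration`, `dmt`, `zip_income`,
#'   `flair_count`, `flair_volume`, `prl_count`, `prl_percentage`,
#'   `non_prl_volume`, `edss`. Provenance attributes: `mode`, `seed`,
#'   `config_digest`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(), seed = 42)
#' dplyr::summarise(dplyr::group_by(cohort, race),
#'                  prl = mean(prl_percentage), edss = mean(edss))
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  if (is.null(seed)) config_error("seed", "a seed is required to generate a cohort")
  cohort <- withr::with_seed(as.integer(seed), {
    dplyr::bind_rows(
      generate_race_group(config, "ba"),
      generate_race_group(config, "wa")
    )
  })
  cohort$patient_id <- sprintf("P%04d", seq_len(nrow(cohort)))
  cohort <- dplyr::relocate(cohort, "patient_id")
  attr(cohort, "mode") <- config$mode
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "config_digest") <- config_digest(config)
  cohort
}

# Inverse-CDF draw from a normal truncated below (vectorised, reproducible).
rtruncnorm_lower <- function(n, mean, sd, lo) {
  qnorm(runif(n, pnorm(lo, mean, sd), 1), mean, sd)
}

# Zero-truncated negative binomial via inverse CDF.
rztnb <- function(n, mu, size) {
  qnbinom(runif(n, dnbinom(0, mu = mu, size = size), 1), mu = mu, size = size)
}

# Lognormal parameterised by arithmetic mean and sd.
rlnorm_moments <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  exp(rnorm(n, log(mean) - s2 / 2, sqrt(s2)))
}

generate_race_group <- function(config, race) {
  n <- if (race == "ba") config$n_ba else config$n_wa
  cv <- config$covariates
  is_ba <- as.numeric(race == "ba")

  age <- rtruncnorm_lower(n, cv$age$mean[[race]], cv$age$sd[[race]], cv$age$min)
  sex <- ifelse(runif(n) < cv$male_frac[[race]], "male", "female")
  duration <- rtruncnorm_lower(n, cv$duration$mean[[race]], cv$duration$sd[[race]],
                               cv$duration$min)
  dmt <- sample(names(cv$dmt[[race]]), n, replace = TRUE, prob = cv$dmt[[race]])
  income <- rtruncnorm_lower(n, cv$income$mean[[race]], cv$income$sd[[race]],
                             cv$income$min)
  non_prl <- rlnorm_moments(n, cv$non_prl_volume$mean[[race]], cv$non_prl_volume$sd[[race]])
  flair_count <- rztnb(n, cv$flair$mu[[race]], cv$flair$size[[race]])

  dmt_lower <- as.numeric(dmt == "lower")
  dmt_untreated <- as.numeric(dmt == "untreated")
  u <- rnorm(n)  # latent confounder channel
  k <- config$confounder_strength

  if (config$mode == "linear") {
    m <- config$mediator
    prl_pct <- m$intercept + m$race * is_ba + m$age * age +
      m$dmt_lower * dmt_lower + m$dmt_untreated * dmt_untreated +
      k * u + rnorm(n, 0, m$sd[[race]])
    # descriptive count consistent with the (clamped) percentage
    prl_count <- pmin(pmax(round(pmin(pmax(prl_pct, 0), 100) / 100 * flair_count), 0),
                      flair_count)
  } else {
    ct <- config$count
    eta <- ct$logit_intercept + ct$logit_race * is_ba +
      ct$overdispersion_sd[[race]] * rnorm(n) + k * u
    prl_count <- rbinom(n, flair_count, plogis(eta))
    prl_pct <- 100 * prl_count / flair_count
  }

  prl_vol <- prl_count * rlnorm_moments(n, cv$prl_lesion_volume$mean,
                                        cv$prl_lesion_volume$sd)
  o <- config$outcome
  edss <- o$intercept + o$race * is_ba + o$mediator * prl_pct + o$age * age +
    o$dmt_lower * dmt_lower + o$dmt_untreated * dmt_untreated +
    o$non_prl_volume * non_prl + k * u + rnorm(n, 0, o$sd[[race]])
  if (config$round_edss) edss <- round(pmin(pmax(edss, 0), 9.5) * 2) / 2

  tibble::tibble(
    race = toupper(race), age = age, sex = sex, disease_duration = duration,
    dmt = dmt, zip_income = income, flair_count = as.integer(flair_count),
    flair_volume = non_prl + prl_vol, prl_count = as.integer(prl_count),
    prl_percentage = prl_pct, non_prl_volume = non_prl, edss = edss
  )
}

cohort_columns <- c("patient_id", "race", "age", "sex", "disease_duration",
                    "dmt", "zip_income", "flair_count", "flair_volume",
                    "prl_count", "prl_percentage", "non_prl_volume", "edss")

#' Validate a patient-level cohort table
#'
#' Checks the column contract and the structural invariants: both race groups
#' non-empty, no missing values, `prl_count <= flair_count`,
#' `non_prl_volume <= flair_volume`, valid `race`/`dmt`/`sex` levels. Errors
#' name the offending row and column.
#'
#' @param cohort A data frame in the cohort layout (see [generate_cohort()]).
#' @return `cohort` as a tibble, invisibly usable downstream.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    abort(sprintf("cohort is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "prlmediate_validation_error")
  }
  cohort <- tibble::as_tibble(cohort)
  bad_cell <- function(rows, col, why) {
    abort(sprintf("invalid cohort: column `%s`, row(s) %s: %s",
                  col, paste(head(rows, 5), collapse = ", "), why),
          class = "prlmediate_validation_error")
  }
  for (col in cohort_columns) {
    i <- which(is.na(cohort[[col]]))
    if (length(i)) bad_cell(i, col, "missing value")
  }
  num_cols <- setdiff(cohort_columns, c("patient_id", "race", "sex", "dmt"))
  for (col in num_cols) {
    if (!is.numeric(cohort[[col]])) bad_cell(which(!is.na(cohort[[col]]))[1], col, "must be numeric")
  }
  i <- which(!cohort$race %in% c("BA", "WA"))
  if (length(i)) bad_cell(i, "race", "must be BA or WA")
  i <- which(!cohort$dmt %in% c("higher", "lower", "untreated"))
  if (length(i)) bad_cell(i, "dmt", "must be higher, lower or untreated")
  i <- which(!cohort$sex %in% c("male", "female"))
  if (length(i)) bad_cell(i, "sex", "must be male or female")
  i <- which(cohort$prl_count > cohort$flair_count)
  if (length(i)) bad_cell(i, "prl_count", "invariant violated: prl_count <= flair_count")
  i <- which(cohort$non_prl_volume > cohort$flair_volume * (1 + 1e-8))
  if (length(i)) bad_cell(i, "non_prl_volume", "invariant violated: non_prl_volume <= flair_volume")
  i <- which(cohort$flair_count < 1)
  if (length(i)) bad_cell(i, "flair_count", "must be >= 1")
  if (!any(cohort$race == "BA") || !any(cohort$race == "WA")) {
    abort("invalid cohort: both race groups must be non-empty",
          class = "prlmediate_validation_error")
  }
  cohort
}
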