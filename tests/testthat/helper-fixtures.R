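# Shared fixtures: everything is generated in code at test time.

# A small but analysis-ready cohort (both race groups, all columns).
small_cohort <- function(seed = 1, n = 30, mode = "linear", ...) {
  generate_cohort(cohort_config(n_ba = n, n_wa = n, mode = mode, ...), seed = seed)
}

# Hand-built 3-patient table for design-matrix checks.
toy_cohort <- function() {
  tibble::tibble(
    patient_id = c("P1", "P2", "P3"),
    race = c("BA", "WA", "BA"),
    age = c(40, 50, 60),
    sex = c("male", "female", "female"),
    disease_duration = c(5, 10, 15),
    dmt = c("higher", "lower", "untreated"),
    zip_income = c(5e4, 9e4, 7e4),
    flair_count = c(10L, 20L, 30L),
    flair_volume = c(5000, 6000, 7000),
    prl_count = c(1L, 2L, 3L),
    prl_percentage = c(10, 10, 10),
    non_prl_volume = c(4000, 5000, 6000),
    edss = c(2, 1, 3)
  )
}

# Minimal prl_ols stub for functions that only need coefficients/residuals.
ols_stub <- function(coefficients, residuals = numeric(0), n = length(residuals)) {
  structure(list(coefficients = coefficients, residuals = residuals, n = n),
            class = "prl_ols")
}

# Independent normal-equations OLS oracle (solve(X'X) X'y), never qr-based.
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))[, 1]
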