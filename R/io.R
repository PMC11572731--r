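#' Read and write patient-level cohort CSV files
#'
#' The on-disk format is a headed CSV with exactly the cohort columns
#' (`patient_id, race, age, sex, disease_duration, dmt, zip_income,
#' flair_count, flair_volume, prl_count, prl_percentage, non_prl_volume,
#' edss`). Numeric fields are written at full double precision (15
#' significant digits), so a write/read round trip is the identity on every
#' field. `read_cohort()` validates the structural invariants and raises an
#' error naming the offending row and column on malformed input.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param path File path.
#' @return `read_cohort()` returns a validated tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' cohort <- generate_cohort(cohort_config(), seed = 7)
#' write_cohort(cohort, path)
#' identical(dim(read_cohort(path)), dim(cohort))
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort[, cohort_columns], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  spec <- readr::cols(
    patient_id = readr::col_character(),
    race = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    disease_duration = readr::col_double(),
    dmt = readr::col_character(),
    zip_income = readr::col_double(),
    flair_count = readr::col_integer(),
    flair_volume = readr::col_double(),
    prl_count = readr::col_integer(),
    prl_percentage = readr::col_double(),
    non_prl_volume = readr::col_double(),
    edss = readr::col_double()
  )
  cohort <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE)
  )
  probs <- readr::problems(cohort)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf("malformed cohort CSV `%s`: row %d, column %d: expected %s, got %s",
                  path, p$row, p$col, p$expected, p$actual),
          class = "prlmediate_validation_error")
  }
  validate_cohort(cohort)
}
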