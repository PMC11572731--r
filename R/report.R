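#' Run the full mediation analysis pipeline
#'
#' Orchestrates all stages on one cohort: the group-comparison table, the
#' three linear models (total-effect, mediator, outcome), the bootstrap
#' mediation analysis, and the sensitivity analysis.
#'
#' @param cohort A cohort data frame, or `NULL` to generate one from
#'   `config` and `seed`.
#' @param config A [cohort_config()] used when `cohort` is `NULL` (its
#'   digest is recorded either way).
#' @param n_boot,ci_level,stratified Bootstrap settings (see
#'   [bootstrap_mediation()]).
#' @param rho_grid Sensitivity grid (see [sensitivity_analysis()]).
#' @param seed Integer seed controlling generation (when `cohort` is `NULL`)
#'   and the bootstrap index stream.
#' @return An object of class `prl_report` containing every stage result.
#' @export
#' @examples
#' rep <- run_analysis(config = cohort_config(), seed = 1, n_boot = 200)
#' cat(substr(render_report(rep), 1, 300))
run_analysis <- function(cohort = NULL, config = cohort_config(),
                         n_boot = 25000, ci_level = 0.95, stratified = FALSE,
                         rho_grid = seq(-0.9, 0.9, by = 0.01), seed = NULL) {
  if (is.null(seed)) abort("`seed` is required for run_analysis()")
  if (is.null(cohort)) cohort <- generate_cohort(config, seed = seed)
  cohort <- validate_cohort(cohort)
  models <- lapply(
    setNames(c("total_effect", "mediator", "outcome"),
             c("total_effect", "mediator", "outcome")),
    function(role) fit_named_model(cohort, role))
  structure(list(
    config_digest = config_digest(config),
    seed = as.integer(seed),
    n_patients = nrow(cohort),
    table_one = table_one(cohort),
    models = models,
    mediation = bootstrap_mediation(cohort, n_boot = n_boot,
                                    ci_level = ci_level, seed = seed,
                                    stratified = stratified,
                                    keep_draws = FALSE),
    sensitivity = sensitivity_analysis(cohort, rho_grid = rho_grid),
    version = as.character(packageVersion("prlmediate")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ), class = "prl_report")
}

report_stages <- c("table_one", "models", "mediation", "sensitivity")

#' Render an analysis report
#'
#' Produces a single markdown or JSON document with identical numeric
#' content: the group-comparison block, the three model coefficient tables,
#' the mediation block and the sensitivity block. Markdown shows 6
#' significant digits; JSON keeps full precision.
#'
#' @param report A `prl_report` from [run_analysis()].
#' @param format `"markdown"` or `"json"`.
#' @return A character string (the document).
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  format <- match.arg(format)
  missing_stages <- report_stages[vapply(report_stages,
                                         function(s) is.null(report[[s]]), TRUE)]
  if (length(missing_stages)) {
    abort(sprintf("incomplete report: missing stage(s) %s",
                  paste(missing_stages, collapse = ", ")),
          class = "prlmediate_render_error")
  }
  if (format == "json") {
    payload <- list(
      config_digest = report$config_digest, seed = report$seed,
      n_patients = report$n_patients,
      table_one = report$table_one,
      models = lapply(report$models, tidy),
      mediation = report$mediation$estimates,
      mediation_meta = glance(report$mediation),
      sensitivity = glance(report$sensitivity),
      sensitivity_curve = report$sensitivity$curve,
      version = report$version, timestamp = report$timestamp
    )
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)))
  }
  g6 <- function(x) formatC(x, format = "g", digits = 6)
  md_table <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], g6)
    paste(c(sprintf("| %s |", paste(names(df), collapse = " | ")),
            sprintf("|%s", paste(rep("---|", ncol(df)), collapse = "")),
            do.call(sprintf,
                    c(list(fmt = sprintf("| %s |", paste(rep("%s", ncol(df)), collapse = " | "))),
                      lapply(df, as.character)))),
          collapse = "\n")
  }
  med <- report$mediation$estimates
  sens <- glance(report$sensitivity)
  paste(c(
    "# PRL mediation analysis report",
    sprintf("Generated by prlmediate %s at %s (seed %d, config %s, n = %d patients)",
            report$version, report$timestamp, report$seed,
            report$config_digest, report$n_patients),
    "", "## Group comparison (table one)", "",
    format_table_one(report$table_one),
    "", "## Linear models", "",
    unlist(lapply(names(report$models), function(nm) {
      c(sprintf("### %s model", gsub("_", " ", nm)), "",
        md_table(tidy(report$models[[nm]])), "")
    })),
    "## Mediation (nonparametric percentile bootstrap)", "",
    sprintf("%s bootstrap replicates, %d%% CIs, seed %d.",
            format(report$mediation$n_boot, big.mark = ","),
            round(100 * report$mediation$ci_level), report$mediation$seed),
    "",
    md_table(med),
    "", "## Sensitivity analysis", "",
    sprintf("Observed mediator-outcome residual correlation rho-tilde = %s;",
            g6(sens$rho_tilde)),
    sprintf("ACME(0) = %s; ACME crosses zero at rho = %s.",
            g6(sens$acme_0), g6(sens$zero_crossing)),
    ""), collapse = "\n")
}

#' @export
print.prl_report <- function(x, ...) {
  cat(sprintf("<prl_report>  %d patients, seed %d, prlmediate %s\n",
              x$n_patients, x$seed, x$version))
  cat("stages: table_one, models (total_effect, mediator, outcome), mediation, sensitivity\n")
  print(x$mediation)
  invisible(x)
}
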