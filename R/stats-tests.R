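#' Two-group comparison tests for cohort characteristics
#'
#' Thin, uniformly-shaped wrappers around the classical two-group tests used
#' in a clinical characteristics table: Yates-corrected chi-squared,
#' two-sample t (Welch or pooled), Wilcoxon rank-sum, and Fisher's exact
#' test. Each returns a one-row tibble (`variable`, `test`, `summary_ba`,
#' `summary_wa`, `statistic`, `p_value`) so results can be row-bound into a
#' full comparison table by [table_one()].
#'
#' @name comparison_tests
NULL

comparison_row <- function(variable, test, summary_ba, summary_wa, statistic, p_value) {
  tibble::tibble(variable = variable %||% NA_character_, test = test,
                 summary_ba = summary_ba, summary_wa = summary_wa,
                 statistic = statistic, p_value = p_value)
}

check_2x2 <- function(tab) {
  if (!is.matrix(tab) || !all(dim(tab) == c(2, 2))) {
    abort("`table` must be a 2x2 matrix of counts")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`table` must contain nonnegative integer counts")
  }
  tab
}

#' @describeIn comparison_tests Chi-squared test with Yates continuity
#'   correction on a 2x2 table (rows = groups). All margins must be positive.
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @param variable Optional variable label carried into the result.
#' @export
#' @examples
#' # PRL prevalence table reconstructed from 55% of 117 BA / 39% of 123 WA:
#' chi_square_2x2_cc(matrix(c(64, 53, 48, 75), 2, byrow = TRUE))
chi_square_2x2_cc <- function(table, variable = NULL) {
  tab <- check_2x2(table)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: all row and column margins must be > 0",
          class = "prlmediate_degenerate_table_error")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
  comparison_row(variable, "chi2_cc",
                 sprintf("%d / %d", tab[1, 1], sum(tab[1, ])),
                 sprintf("%d / %d", tab[2, 1], sum(tab[2, ])),
                 unname(ht$statistic), unname(ht$p.value))
}

#' @describeIn comparison_tests Fisher's exact test on a 2x2 table, two-sided
#'   (tables as improbable as the observed one). A table with an empty row or
#'   column gives p = 1 by convention.
#' @export
fisher_exact_2x2 <- function(table, variable = NULL) {
  tab <- check_2x2(table)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else {
    unname(fisher.test(tab)$p.value)
  }
  comparison_row(variable, "fisher",
                 sprintf("%d / %d", tab[1, 1], sum(tab[1, ])),
                 sprintf("%d / %d", tab[2, 1], sum(tab[2, ])),
                 NA_real_, p)
}

mean_sd_label <- function(x) sprintf("%.2f (%.2f)", mean(x), sd(x))

#' @describeIn comparison_tests Two-sample t test from raw data. Welch
#'   (unequal variances) by default; set `equal_var = TRUE` for the pooled
#'   test. Each group needs n >= 2 and positive variance.
#' @param x,y Numeric vectors, group BA and group WA respectively.
#' @param equal_var Pool the variances?
#' @export
two_sample_t <- function(x, y, equal_var = FALSE, variable = NULL) {
  if (length(x) < 2 || length(y) < 2) {
    abort("insufficient data: each group needs at least 2 observations",
          class = "prlmediate_insufficient_data_error")
  }
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    # identical constant groups: no evidence of a difference
    return(comparison_row(variable, if (equal_var) "pooled_t" else "welch_t",
                          mean_sd_label(x), mean_sd_label(y), 0, 1))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("insufficient data: group standard deviation is zero",
          class = "prlmediate_insufficient_data_error")
  }
  ht <- t.test(x, y, var.equal = equal_var)
  comparison_row(variable, if (equal_var) "pooled_t" else "welch_t",
                 mean_sd_label(x), mean_sd_label(y),
                 unname(ht$statistic), unname(ht$p.value))
}

#' @describeIn comparison_tests Two-sample t test from per-group summary
#'   statistics (mean, sd, n); numerically identical to [two_sample_t()] on
#'   raw data with matching summaries.
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Group summary statistics.
#' @export
#' @examples
#' # PRL percentage row: 8.01 (15.25) n=117 vs 3.40 (7.50) n=123
#' two_sample_t_summary(8.01, 15.25, 117, 3.40, 7.50, 123)
two_sample_t_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                                 equal_var = FALSE, variable = NULL) {
  if (n_x < 2 || n_y < 2) {
    abort("insufficient data: each group needs at least 2 observations",
          class = "prlmediate_insufficient_data_error")
  }
  if (sd_x <= 0 || sd_y <= 0) {
    abort("insufficient data: group standard deviations must be > 0",
          class = "prlmediate_insufficient_data_error")
  }
  if (equal_var) {
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
    df <- n_x + n_y - 2
  } else {
    vx <- sd_x^2 / n_x; vy <- sd_y^2 / n_y
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
  }
  t <- (mean_x - mean_y) / se
  comparison_row(variable, if (equal_var) "pooled_t" else "welch_t",
                 sprintf("%.2f (%.2f)", mean_x, sd_x),
                 sprintf("%.2f (%.2f)", mean_y, sd_y),
                 t, 2 * pt(-abs(t), df))
}

median_iqr_label <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
}

#' @describeIn comparison_tests Wilcoxon rank-sum test with midranks for
#'   ties. For combined n <= 12 the two-sided p-value is computed exactly by
#'   enumerating all group assignments of the pooled midranks; otherwise the
#'   normal approximation with tie-corrected variance and continuity
#'   correction is used.
#' @export
rank_sum <- function(x, y, variable = NULL) {
  if (length(x) < 1 || length(y) < 1) {
    abort("insufficient data: each group needs at least 1 observation",
          class = "prlmediate_insufficient_data_error")
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= 12) {
    sums <- combn(n, n1, function(i) sum(r[i]))
    p_le <- mean(sums <= w); p_ge <- mean(sums >= w)
    p <- min(1, 2 * min(p_le, p_ge))
    stat <- w - n1 * (n1 + 1) / 2  # Mann-Whitney U
  } else {
    ht <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    stat <- unname(ht$statistic)
    p <- unname(ht$p.value)
  }
  comparison_row(variable, "wilcoxon", median_iqr_label(x), median_iqr_label(y),
                 stat, p)
}

#' Default table-one variable plan
#'
#' Maps each cohort variable to the comparison its published presentation
#' implies: t tests for mean (SD) rows, the rank-sum test for the
#' median \[IQR\] EDSS row, and chi-squared tests (Yates-corrected when 2x2)
#' for proportions, including the derived PRL-prevalence indicator
#' `prl_count >= 1`.
#'
#' @return A tibble with columns `variable`, `test`.
#' @export
default_variable_plan <- function() {
  tibble::tribble(
    ~variable,          ~test,
    "sex",              "chi2_cc",
    "disease_duration", "welch_t",
    "age",              "welch_t",
    "zip_income",       "welch_t",
    "dmt",              "chi2_cc",
    "edss",             "wilcoxon",
    "flair_volume",     "welch_t",
    "flair_count",      "welch_t",
    "prl_count",        "welch_t",
    "prl_percentage",   "welch_t",
    "non_prl_volume",   "welch_t",
    "prl_prevalence",   "chi2_cc"
  )
}

#' Group-comparison table for a cohort
#'
#' Runs the per-variable two-group comparison implied by `plan` (see
#' [default_variable_plan()]) and returns one [comparison_tests] row per
#' planned variable, in plan order. `prl_prevalence` is the derived indicator
#' `prl_count >= 1`. Categorical variables are compared by chi-squared on the
#' group-by-level contingency table (Yates-corrected when 2x2), or Fisher's
#' exact test when the plan says `fisher`.
#'
#' @param cohort A cohort data frame.
#' @param plan A tibble with columns `variable` and `test`
#'   (`welch_t`, `pooled_t`, `wilcoxon`, `chi2_cc`, `fisher`).
#' @return A tibble with one row per planned variable.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(mode = "count"), seed = 3)
#' table_one(cohort)
table_one <- function(cohort, plan = default_variable_plan()) {
  cohort <- validate_cohort(cohort)
  cohort$prl_prevalence <- ifelse(cohort$prl_count >= 1, "yes", "no")
  unknown <- setdiff(plan$variable, names(cohort))
  if (length(unknown)) {
    abort(sprintf("variable plan names unknown column(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "prlmediate_plan_error")
  }
  ba <- cohort[cohort$race == "BA", ]
  wa <- cohort[cohort$race == "WA", ]
  purrr::pmap_dfr(plan, function(variable, test) {
    v_ba <- ba[[variable]]; v_wa <- wa[[variable]]
    if (test %in% c("chi2_cc", "fisher")) {
      tab <- table(factor(cohort$race, c("BA", "WA")), cohort[[variable]])
      tab <- unclass(tab)
      if (test == "fisher" || !all(dim(tab) == c(2, 2))) {
        if (test == "fisher") return(fisher_exact_2x2(tab, variable = variable))
        ht <- suppressWarnings(chisq.test(tab))
        lab <- function(x) paste(sprintf("%d (%.1f%%)", table(factor(x, colnames(tab))),
                                         100 * prop.table(table(factor(x, colnames(tab))))),
                                 collapse = ", ")
        return(comparison_row(variable, "chi2_cc", lab(v_ba), lab(v_wa),
                              unname(ht$statistic), unname(ht$p.value)))
      }
      res <- chi_square_2x2_cc(tab, variable = variable)
      lv <- colnames(tab)[2]  # report male / PRL-present, matching convention
      lab <- function(x) sprintf("%d (%.1f%%)", sum(x == lv), 100 * mean(x == lv))
      res$summary_ba <- lab(v_ba); res$summary_wa <- lab(v_wa)
      res
    } else if (test == "wilcoxon") {
      rank_sum(v_ba, v_wa, variable = variable)
    } else {
      two_sample_t(v_ba, v_wa, equal_var = (test == "pooled_t"), variable = variable)
    }
  })
}

#' Render a comparison table as markdown
#'
#' @param tab A [table_one()] result.
#' @return A single markdown character string.
#' @export
format_table_one <- function(tab) {
  hdr <- c("Variable", "Test", "BA", "WA", "Statistic", "P-value")
  rows <- sprintf("| %s | %s | %s | %s | %s | %s |",
                  tab$variable, tab$test, tab$summary_ba, tab$summary_wa,
                  ifelse(is.na(tab$statistic), "", formatC(tab$statistic, format = "g", digits = 4)),
                  formatC(tab$p_value, format = "g", digits = 3))
  paste(c(sprintf("| %s |", paste(hdr, collapse = " | ")),
          sprintf("|%s", paste(rep("---|", length(hdr)), collapse = "")),
          rows),
        collapse = "\n")
}
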