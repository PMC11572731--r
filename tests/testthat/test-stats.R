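# hand evaluation of the Yates-corrected chi-squared statistic
yates_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  num <- max(abs(a * d - b * c) - n / 2, 0)^2 * n
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  num / den
}

test_that("Yates chi-squared matches hand evaluation and the published PRL-prevalence comparison", {
  # 55% of 117 BA and 39% of 123 WA with at least one PRL
  tab <- matrix(c(64, 53, 48, 75), 2, byrow = TRUE)
  res <- chi_square_2x2_cc(tab)
  expect_equal(res$statistic, yates_oracle(tab), tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(yates_oracle(tab), 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(abs(res$p_value - 0.022), 0.005)

  flat <- chi_square_2x2_cc(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  diag5 <- matrix(c(5, 0, 0, 5), 2, byrow = TRUE)
  expect_equal(chi_square_2x2_cc(diag5)$statistic, yates_oracle(diag5),
               tolerance = 1e-10)
  expect_error(chi_square_2x2_cc(matrix(c(3, 4, 0, 0), 2, byrow = TRUE)),
               class = "prlmediate_degenerate_table_error")
})

test_that("Welch t from the published PRL-percentage summaries reproduces its p-value", {
  res <- two_sample_t_summary(8.01, 15.25, 117, 3.40, 7.50, 123)
  expect_equal(res$statistic, 2.948, tolerance = 1e-3)
  expect_gt(res$p_value, 0.003)
  expect_lt(res$p_value, 0.004)
})

test_that("summary-statistic and raw-data t tests agree to 10 significant digits", {
  withr::local_seed(10)
  for (i in 1:5) {
    x <- rnorm(17, 1, 2); y <- rnorm(23, 0, 3)
    for (ev in c(FALSE, TRUE)) {
      raw <- two_sample_t(x, y, equal_var = ev)
      summ <- two_sample_t_summary(mean(x), sd(x), length(x),
                                   mean(y), sd(y), length(y), equal_var = ev)
      expect_equal(summ$statistic, raw$statistic, tolerance = 1e-10)
      expect_equal(summ$p_value, raw$p_value, tolerance = 1e-10)
    }
  }
})

test_that("t-test edge behaviour: identical groups, pooled/Welch coincidence, short input", {
  res <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  withr::local_seed(2)
  x <- rnorm(12); y <- rnorm(12, 1)
  y <- mean(x) + 1 + (y - mean(y)) * sd(x) / sd(y)  # equal sds, equal ns
  expect_equal(two_sample_t(x, y, equal_var = TRUE)$p_value,
               two_sample_t(x, y, equal_var = FALSE)$p_value, tolerance = 1e-10)
  expect_error(two_sample_t(1, c(1, 2)), class = "prlmediate_insufficient_data_error")
})

test_that("rank-sum exact path matches full enumeration", {
  res <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)  # 2 * (1/20)
  expect_equal(rank_sum(1, 1)$p_value, 1)
  # exact vs normal-approximation agreement at the path boundary
  withr::local_seed(42)
  for (i in 1:5) {
    x <- round(rnorm(6), 1); y <- round(rnorm(6, 0.5), 1)
    exact_p <- rank_sum(x, y)$p_value
    approx_p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact_p - approx_p), 0.02)
  }
})

test_that("rank-sum is invariant under strictly monotone transforms", {
  withr::local_seed(7)
  x <- rexp(20); y <- rexp(25, 0.7)
  base <- rank_sum(x, y)$p_value
  expect_equal(rank_sum(log(x), log(y))$p_value, base, tolerance = 1e-12)
  expect_equal(rank_sum(x^3, y^3)$p_value, base, tolerance = 1e-12)
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  fisher_oracle <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    obs <- dhyper(tab[1, 1], m, n, k)
    xs <- max(0, k - n):min(k, m)
    sum(dhyper(xs, m, n, k)[dhyper(xs, m, n, k) <= obs * (1 + 1e-7)])
  }
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(tab)$p_value, fisher_oracle(tab), tolerance = 1e-8)
  expect_lt(abs(fisher_exact_2x2(tab)$p_value - 0.0028), 3e-4)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(2, 2, 2))$p_value, 1)
})

test_that("chi-squared and Fisher agree on well-populated 2x2 tables", {
  # the two-sided minimum-likelihood Fisher convention and the Yates
  # statistic track each other closely where it matters for inference
  # (small p); near p ~ 0.5 the conventions differ by construction
  withr::local_seed(11)
  checked <- 0
  for (i in 1:300) {
    tab <- matrix(rpois(4, 60) + 25, 2)
    p1 <- chi_square_2x2_cc(tab)$p_value
    p2 <- fisher_exact_2x2(tab)$p_value
    if (p1 < 0.1) {
      expect_lt(abs(p1 - p2), 0.02)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 10)
})

test_that("table_one follows the plan, in order, deterministically", {
  co <- small_cohort(seed = 6, n = 60, mode = "count")
  tab <- table_one(co)
  expect_identical(tab$variable, default_variable_plan()$variable)
  expect_identical(nrow(tab), 12L)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_identical(table_one(co), tab)

  single <- table_one(co, plan = tibble::tibble(variable = "age", test = "welch_t"))
  expect_identical(nrow(single), 1L)
  expect_error(table_one(co, plan = tibble::tibble(variable = "nope", test = "welch_t")),
               "nope", class = "prlmediate_plan_error")
})

test_that("table_one markdown rendering carries every variable", {
  co <- small_cohort(seed = 6, n = 40, mode = "count")
  md <- format_table_one(table_one(co))
  for (v in default_variable_plan()$variable) expect_match(md, v, fixed = TRUE)
})
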