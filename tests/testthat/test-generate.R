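test_that("the default configuration yields 117 BA and 123 WA patients", {
  co <- generate_cohort(cohort_config(), seed = 8)
  expect_identical(nrow(co), 240L)
  expect_identical(sum(co$race == "BA"), 117L)
  expect_identical(sum(co$race == "WA"), 123L)
  expect_identical(names(co),
                   c("patient_id", "race", "age", "sex", "disease_duration",
                     "dmt", "zip_income", "flair_count", "flair_volume",
                     "prl_count", "prl_percentage", "non_prl_volume", "edss"))
  expect_silent(validate_cohort(co))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- cohort_config(mode = "count")
  expect_identical(generate_cohort(cfg, seed = 123), generate_cohort(cfg, seed = 123))
  expect_false(identical(generate_cohort(cfg, seed = 123),
                         generate_cohort(cfg, seed = 124)))
  expect_error(generate_cohort(cohort_config()), "seed",
               class = "prlmediate_config_error")
})

test_that("a null structural model produces no race difference in EDSS", {
  cov <- eval(formals(cohort_config)$covariates)
  # identical covariate distributions across races
  for (f in c("age", "duration", "income", "non_prl_volume")) {
    cov[[f]]$mean[] <- mean(cov[[f]]$mean)
    cov[[f]]$sd[] <- mean(cov[[f]]$sd)
  }
  cov$male_frac[] <- 0.27
  cov$dmt$ba <- cov$dmt$wa
  cov$flair$mu[] <- 23; cov$flair$size[] <- 1.3
  cfg <- cohort_config(n_ba = 20000, n_wa = 20000, covariates = cov,
                       mediator = utils::modifyList(eval(formals(cohort_config)$mediator),
                                                    list(race = 0)),
                       outcome = utils::modifyList(eval(formals(cohort_config)$outcome),
                                                   list(race = 0, mediator = 0)))
  co <- generate_cohort(cfg, seed = 31)
  ba <- co$edss[co$race == "BA"]; wa <- co$edss[co$race == "WA"]
  mc_se <- sqrt(var(ba) / length(ba) + var(wa) / length(wa))
  expect_lt(abs(mean(ba) - mean(wa)), 3 * mc_se)
})

test_that("count mode satisfies the structural invariants exactly", {
  co <- generate_cohort(cohort_config(n_ba = 2000, n_wa = 2000, mode = "count"),
                        seed = 5)
  expect_true(all(co$prl_count <= co$flair_count))
  expect_true(all(co$prl_percentage >= 0 & co$prl_percentage <= 100))
  expect_equal(co$prl_percentage, 100 * co$prl_count / co$flair_count)
  expect_true(all(co$non_prl_volume <= co$flair_volume))
  expect_true(all(co$flair_count >= 1))
})

test_that("count-mode prevalence matches an independent hierarchical oracle", {
  cfg <- cohort_config(n_ba = 50000, n_wa = 1, mode = "count")
  co <- generate_cohort(cfg, seed = 77)
  prev_ba <- mean(co$prl_count[co$race == "BA"] >= 1)
  # independent Monte-Carlo oracle of the same draw: rejection-sampled
  # zero-truncated NB, then logit-normal-binomial
  set.seed(1234)
  n <- 50000
  fl <- rnbinom(3 * n, mu = 23.83, size = 1.3934)
  fl <- fl[fl >= 1][seq_len(n)]
  eta <- cfg$count$logit_intercept + cfg$count$logit_race +
    cfg$count$overdispersion_sd[["ba"]] * rnorm(n)
  oracle_prev <- mean(rbinom(n, fl, plogis(eta)) >= 1)
  expect_lt(abs(prev_ba - oracle_prev), 0.01)
})

test_that("large-sample OLS recovers the linear-mode structural coefficients", {
  cfg <- cohort_config(n_ba = 100000, n_wa = 100000)
  co <- generate_cohort(cfg, seed = 13)
  mf <- fit_named_model(co, "mediator")
  of <- fit_named_model(co, "outcome")
  a <- tidy(mf)[tidy(mf)$term == "race_BA", ]
  expect_lt(abs(a$estimate - cfg$mediator$race), 3 * a$std.error)
  b <- tidy(of)[tidy(of)$term == "prl_percentage", ]
  expect_lt(abs(b$estimate - cfg$outcome$mediator), 3 * b$std.error)
  g <- tidy(of)[tidy(of)$term == "race_BA", ]
  expect_lt(abs(g$estimate - cfg$outcome$race), 3 * g$std.error)
  ag <- tidy(of)[tidy(of)$term == "age", ]
  expect_lt(abs(ag$estimate - cfg$outcome$age), 3 * ag$std.error)
})

test_that("the confounder channel induces monotone residual correlation", {
  rho_at <- function(k) {
    cfg <- cohort_config(n_ba = 10000, n_wa = 10000, confounder_strength = k,
                         outcome = utils::modifyList(eval(formals(cohort_config)$outcome),
                                                     list(mediator = 0)))
    co <- generate_cohort(cfg, seed = 55)
    s <- sensitivity_analysis(co)
    s$rho_tilde
  }
  rhos <- vapply(c(0, 2, 6), rho_at, numeric(1))
  expect_lt(abs(rhos[1]), 0.03)   # no confounding, no mediation: corr -> 0
  expect_true(all(diff(rhos) > 0))
  expect_gt(rhos[3], 0.05)
})

test_that("rounded EDSS lands on the clinical half-point grid", {
  co <- generate_cohort(cohort_config(n_ba = 500, n_wa = 500, round_edss = TRUE),
                        seed = 3)
  expect_true(all(co$edss %in% seq(0, 9.5, by = 0.5)))
})

test_that("malformed cohorts are rejected with row/column diagnostics", {
  co <- small_cohort(seed = 2)
  bad <- co; bad$prl_count[4] <- bad$flair_count[4] + 5L
  expect_error(validate_cohort(bad), "prl_count <= flair_count",
               class = "prlmediate_validation_error")
  bad <- co[, setdiff(names(co), "edss")]
  expect_error(validate_cohort(bad), "edss", class = "prlmediate_validation_error")
  bad <- co; bad$race[1] <- "XX"
  expect_error(validate_cohort(bad), "race", class = "prlmediate_validation_error")
})
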