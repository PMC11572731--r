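test_that("point estimates reproduce the published product-of-coefficients arithmetic", {
  mf <- ols_stub(c(race_BA = 4.65), n = 240)
  of <- ols_stub(c(race_BA = 0.60, prl_percentage = 0.021), n = 240)
  pe <- point_estimates(mf, of)
  expect_equal(pe$acme, 0.09765, tolerance = 1e-12)
  expect_equal(pe$total_effect, 0.69765, tolerance = 1e-12)
  expect_equal(pe$prop_mediated, 0.09765 / 0.69765, tolerance = 1e-12)
  expect_equal(round(pe$acme, 2), 0.10)
  expect_equal(round(100 * pe$prop_mediated, 1), 14.0)
})

test_that("a zero mediator effect means no mediation", {
  mf <- ols_stub(c(race_BA = 4.65), n = 100)
  of <- ols_stub(c(race_BA = 0.8, prl_percentage = 0), n = 100)
  pe <- point_estimates(mf, of)
  expect_equal(pe$acme, 0)
  expect_equal(pe$prop_mediated, 0)
  expect_equal(pe$total_effect, pe$ade)
})

test_that("near-zero total effects flag the proportion as undefined", {
  mf <- ols_stub(c(race_BA = 1), n = 100)
  of <- ols_stub(c(race_BA = -1e-7, prl_percentage = 1e-7), n = 100)
  pe <- point_estimates(mf, of)
  expect_false(pe$prop_defined)
  expect_true(is.na(pe$prop_mediated))
  expect_false(is.na(pe$acme))
})

test_that("acme + ade equals the total effect and the difference of coefficients", {
  covs <- c("age", "dmt", "non_prl_volume")
  for (seed in c(21, 22, 23)) {
    co <- small_cohort(seed = seed, n = 50)
    mf <- fit_named_model(co, "mediator", spec = model_spec("mediator", covariates = covs))
    of <- fit_named_model(co, "outcome")
    tot <- fit_named_model(co, "total_effect",
                           spec = model_spec("total_effect", covariates = covs))
    pe <- point_estimates(mf, of)
    expect_equal(pe$acme + pe$ade, pe$total_effect, tolerance = 1e-10)
    # product of coefficients = difference of coefficients on shared covariates
    diff_coef <- unname(tot$coefficients["race_BA"] - of$coefficients["race_BA"])
    expect_equal(pe$acme, diff_coef, tolerance = 1e-10)
    expect_equal(pe$total_effect, unname(tot$coefficients["race_BA"]), tolerance = 1e-10)
  }
})

test_that("percentile intervals follow the fixed order-statistic interpolation", {
  expect_equal(percentile_ci(rep(3, 10), 0.95), c(lower = 3, upper = 3))
  expect_equal(unname(percentile_ci(c(1, 2, 3), 1e-9)), c(2, 2), tolerance = 1e-6)
  # 1..1000 at 95%: h = 1 + 999 p -> 25.975 and 975.025 by linear interpolation
  ci <- percentile_ci(1:1000, 0.95)
  expect_equal(unname(ci), c(25.975, 975.025), tolerance = 1e-10)
  expect_error(percentile_ci(c(1, NA, 3)), "finite")
  expect_error(percentile_ci(c(1, 2), 1.2), "level")
})

test_that("sign-flip bootstrap p-values count tail mass", {
  withr::local_seed(5)
  sym <- rnorm(10000)
  expect_gt(bootstrap_pvalue(sym), 0.9)
  pos <- abs(rnorm(500)) + 0.01
  p <- bootstrap_pvalue(pos)
  expect_equal(as.numeric(p), 2 / 500)
  expect_true(attr(p, "below_resolution"))
  mixed <- c(rep(-1, 25), rep(1, 975))
  expect_equal(as.numeric(bootstrap_pvalue(mixed)), 0.05, tolerance = 1e-12)
  expect_error(bootstrap_pvalue(rnorm(50)), "100")
})

test_that("bootstrap mediation is reproducible and honours its options", {
  co <- small_cohort(seed = 30, n = 40)
  m1 <- bootstrap_mediation(co, n_boot = 300, seed = 77)
  m2 <- bootstrap_mediation(co, n_boot = 300, seed = 77)
  expect_identical(tidy(m1), tidy(m2))
  expect_identical(m1$draws, m2$draws)
  m3 <- bootstrap_mediation(co, n_boot = 300, seed = 78)
  expect_false(identical(tidy(m1), tidy(m3)))

  wide <- bootstrap_mediation(co, n_boot = 300, seed = 77, ci_level = 0.99)
  t1 <- tidy(m1); tw <- tidy(wide)
  expect_true(all(tw$ci_upper - tw$ci_lower >= t1$ci_upper - t1$ci_lower))

  strat <- bootstrap_mediation(co, n_boot = 300, seed = 77, stratified = TRUE)
  expect_identical(glance(strat)$stratified, TRUE)
  expect_error(bootstrap_mediation(co, n_boot = 50, seed = 1), "n_boot")
  expect_error(bootstrap_mediation(co, n_boot = 300), "seed")
})

test_that("the bootstrap matches an independent replay of the same index stream", {
  co <- small_cohort(seed = 31, n = 12)  # 24 patients
  co$dmt <- rep(c("higher", "lower", "untreated"), 8)  # balanced: stable resamples
  n_boot <- 120
  med <- bootstrap_mediation(co, n_boot = n_boot, seed = 9)
  # independent replay: same RNG stream, models refit with lm()
  dm <- build_design(co, model_spec("mediator"))
  do <- build_design(co, model_spec("outcome"))
  draws <- withr::with_seed(9L, {
    t(vapply(seq_len(n_boot), function(b) {
      repeat {  # same redraw rule as the engine: full-rank designs only
        idx <- sample.int(24, 24, replace = TRUE)
        if (qr(dm$X[idx, ])$rank == ncol(dm$X) &&
            qr(do$X[idx, ])$rank == ncol(do$X)) break
      }
      cm <- coef(lm(dm$y[idx] ~ dm$X[idx, -1]))
      om <- coef(lm(do$y[idx] ~ do$X[idx, -1]))
      acme <- cm[2] * om[3]  # race_BA in mediator, prl_percentage in outcome
      c(acme, om[2], acme + om[2])
    }, numeric(3)))
  })
  expect_equal(unname(as.matrix(med$draws[, 1:3])), unname(draws), tolerance = 1e-9)
})

test_that("a null cohort yields an ACME interval covering zero", {
  cfg <- cohort_config(mediator = utils::modifyList(eval(formals(cohort_config)$mediator),
                                                    list(race = 0)),
                       outcome = utils::modifyList(eval(formals(cohort_config)$outcome),
                                                   list(mediator = 0)))
  co <- generate_cohort(cfg, seed = 40)
  med <- bootstrap_mediation(co, n_boot = 2000, seed = 41, keep_draws = FALSE)
  acme <- tidy(med)[tidy(med)$term == "acme", ]
  expect_lt(acme$ci_lower, 0)
  expect_gt(acme$ci_upper, 0)
})

test_that("degenerate resampling is detected and capped", {
  co <- small_cohort(seed = 33, n = 10)  # 20 patients
  co$dmt <- c("untreated", "lower", rep(c("higher", "lower"), 9))  # singleton level: often lost
  expect_error(bootstrap_mediation(co, n_boot = 200, seed = 3),
               class = "prlmediate_degeneracy_error")
})

test_that("mediation JSON serialisation is stable and complete", {
  co <- small_cohort(seed = 35, n = 60)
  med <- bootstrap_mediation(co, n_boot = 200, seed = 8, keep_draws = FALSE)
  js <- jsonlite::fromJSON(mediation_to_json(med))
  expect_equal(js$n_boot, 200)
  expect_setequal(js$estimates$term, c("acme", "ade", "total_effect", "prop_mediated"))
  expect_equal(js$estimates$estimate[js$estimates$term == "acme"],
               tidy(med)$estimate[tidy(med)$term == "acme"], tolerance = 1e-12)
})
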