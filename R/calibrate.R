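# Gauss-Hermite quadrature nodes/weights for E[f(Z)], Z ~ N(0,1),
# via the Golub-Welsch eigenvalue method.
gauss_hermite_normal <- function(k = 61) {
  i <- seq_len(k - 1)
  b <- sqrt(i / 2)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(z = e$values * sqrt(2), w = e$vectors[1, ]^2)
}

# E[plogis(eta + tau Z)]
logit_normal_mean <- function(eta, tau, quad = gauss_hermite_normal()) {
  sum(quad$w * plogis(eta + tau * quad$z))
}

ztnb_pmf <- function(nmax, mu, size) {
  n <- seq_len(nmax)
  p <- dnbinom(n, mu = mu, size = size) / (1 - dnbinom(0, mu = mu, size = size))
  p / sum(p)
}

#' Exact moments of the lesion-count PRL model
#'
#' Computes, by Gauss-Hermite quadrature over the logit-normal per-lesion rim
#' probability and summation over the (zero-truncated negative-binomial)
#' FLAIR-count distribution, the expected PRL percentage and the prevalence of
#' having at least one PRL.
#'
#' @param logit_p Logit-scale location of the per-lesion rim probability.
#' @param overdispersion_sd Logit-scale sd of the patient-level random effect.
#' @param flair_mu,flair_size Negative-binomial mean and size of the FLAIR
#'   lesion count (zero-truncated). Ignored when `flair_count` is given.
#' @param flair_count Optional fixed lesion count (degenerate distribution).
#' @param nmax Upper summation bound for the count distribution.
#' @return A named vector `c(mean_pct = , prevalence = )`.
#' @export
#' @examples
#' # with no overdispersion and 20 lesions, prevalence has a closed form:
#' count_model_moments(qlogis(0.05), 0, flair_count = 20)["prevalence"]
#' 1 - 0.95^20
count_model_moments <- function(logit_p, overdispersion_sd,
                                flair_mu = NULL, flair_size = NULL,
                                flair_count = NULL, nmax = 1000) {
  quad <- gauss_hermite_normal()
  p <- plogis(logit_p + overdispersion_sd * quad$z)
  mean_pct <- 100 * sum(quad$w * p)
  if (is.null(flair_count)) {
    if (is.null(flair_mu) || is.null(flair_size)) {
      abort("either `flair_count` or both `flair_mu` and `flair_size` are required")
    }
    pn <- ztnb_pmf(nmax, flair_mu, flair_size)
    none <- outer(seq_len(nmax), p, function(n, p) (1 - p)^n) %*% quad$w
    prevalence <- 1 - sum(pn * none)
  } else {
    prevalence <- 1 - sum(quad$w * (1 - p)^flair_count)
  }
  c(mean_pct = mean_pct, prevalence = prevalence)
}

#' Calibrate the lesion-count PRL model to per-race targets
#'
#' Finds logit-scale parameters of the overdispersed-binomial PRL model such
#' that the model's exact (quadrature) per-race mean PRL percentage and
#' prevalence of `prl_count >= 1` hit the supplied targets. The defaults are
#' the published per-race summaries: mean percentages 8.01 (BA) / 3.40 (WA)
#' and prevalences 0.55 / 0.39.
#'
#' Each race is a two-equation problem in (location, overdispersion sd),
#' solved by nested one-dimensional root finding: for a trial overdispersion
#' the location matching the mean percentage is found first, then the
#' overdispersion is adjusted until the prevalence matches. The procedure is
#' deterministic.
#'
#' @param targets List with `mean_pct = c(ba = , wa = )` (percent, in
#'   (0, 100)) and `prevalence = c(ba = , wa = )` (in (0, 1)).
#' @param flair_mu,flair_size Per-race `c(ba = , wa = )` negative-binomial
#'   parameters of the FLAIR lesion count (defaults from [cohort_config()]).
#' @param tol Named tolerances on the achieved values, in percentage points
#'   of the mean and prevalence fraction.
#' @param tau_upper Upper search bound for the overdispersion sd.
#' @return List with `logit_intercept` (WA location), `logit_race` (BA - WA
#'   location shift), `overdispersion_sd = c(ba = , wa = )`, and `achieved`,
#'   a tibble of per-race achieved moments and residuals.
#' @export
#' @examples
#' cal <- calibrate_count_model()
#' cal$achieved
calibrate_count_model <- function(targets = list(mean_pct = c(ba = 8.01, wa = 3.40),
                                                 prevalence = c(ba = 0.55, wa = 0.39)),
                                  flair_mu = c(ba = 23.83, wa = 22.00),
                                  flair_size = c(ba = 1.3934, wa = 1.2394),
                                  tol = c(mean_pct = 0.25, prevalence = 0.02),
                                  tau_upper = 8) {
  for (r in c("ba", "wa")) {
    mp <- targets$mean_pct[[r]]
    pv <- targets$prevalence[[r]]
    if (!is.finite(mp) || mp <= 0 || mp >= 100) {
      config_error(paste0("targets$mean_pct$", r), "must lie in (0, 100)")
    }
    if (!is.finite(pv) || pv <= 0 || pv >= 1) {
      config_error(paste0("targets$prevalence$", r), "must lie in (0, 1)")
    }
  }
  fit_one <- function(r) {
    mp <- targets$mean_pct[[r]]; pv <- targets$prevalence[[r]]
    mu <- flair_mu[[r]]; size <- flair_size[[r]]
    eta_for <- function(tau) {
      uniroot(function(e) count_model_moments(e, tau, mu, size)[["mean_pct"]] - mp,
              c(-25, 10), tol = 1e-12)$root
    }
    prev_gap <- function(tau) {
      count_model_moments(eta_for(tau), tau, mu, size)[["prevalence"]] - pv
    }
    g0 <- prev_gap(1e-8); g1 <- prev_gap(tau_upper)
    if (sign(g0) == sign(g1)) {
      best <- if (abs(g0) < abs(g1)) 1e-8 else tau_upper
      mom <- count_model_moments(eta_for(best), best, mu, size)
      abort(sprintf(paste0("calibration failure for group %s: prevalence target %.3f ",
                           "unreachable; best achievable (mean %.3f, prevalence %.3f) ",
                           "at overdispersion %.3g"),
                    toupper(r), pv, mom[["mean_pct"]], mom[["prevalence"]], best),
            class = "prlmediate_calibration_error")
    }
    tau <- uniroot(prev_gap, c(1e-8, tau_upper), tol = 1e-10)$root
    eta <- eta_for(tau)
    c(eta = eta, tau = tau, count_model_moments(eta, tau, mu, size))
  }
  ba <- fit_one("ba"); wa <- fit_one("wa")
  achieved <- tibble::tibble(
    race = c("BA", "WA"),
    mean_pct = c(ba[["mean_pct"]], wa[["mean_pct"]]),
    prevalence = c(ba[["prevalence"]], wa[["prevalence"]]),
    mean_pct_residual = c(ba[["mean_pct"]] - targets$mean_pct[["ba"]],
                          wa[["mean_pct"]] - targets$mean_pct[["wa"]]),
    prevalence_residual = c(ba[["prevalence"]] - targets$prevalence[["ba"]],
                            wa[["prevalence"]] - targets$prevalence[["wa"]])
  )
  if (any(abs(achieved$mean_pct_residual) > tol[["mean_pct"]]) ||
      any(abs(achieved$prevalence_residual) > tol[["prevalence"]])) {
    abort(paste0("calibration failure: residuals exceed tolerance; best residuals: ",
                 paste(sprintf("%s mean %+0.4f prev %+0.4f", achieved$race,
                               achieved$mean_pct_residual, achieved$prevalence_residual),
                       collapse = "; ")),
          class = "prlmediate_calibration_error")
  }
  list(logit_intercept = wa[["eta"]],
       logit_race = ba[["eta"]] - wa[["eta"]],
       overdispersion_sd = c(ba = ba[["tau"]], wa = wa[["tau"]]),
       achieved = achieved)
}
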