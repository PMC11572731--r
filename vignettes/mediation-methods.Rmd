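---
title: "Methods: simulating and analysing PRL-mediated disability disparities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing PRL-mediated disability disparities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prlmediate)
```

## The scientific setting

Black-American (BA) patients with multiple sclerosis experience higher
disability, on the Expanded Disability Status Scale (EDSS), than
White-American (WA) patients. Paramagnetic rim lesions (PRLs) — chronic
active lesions with an iron-rim signature on susceptibility MRI — are more
frequent in BA patients, both as a prevalence (having at least one PRL) and
as a share of all FLAIR white-matter lesions. `prlmediate` implements the
causal-mediation decomposition of the BA–WA EDSS gap into the component
transmitted through the PRL percentage and the residual direct component,
together with a calibrated synthetic-cohort generator that reproduces the
statistical structure this analysis assumes. Because individual patient data
from such studies are typically not deposited, the generator is the
package's substrate for testing: every inferential claim the package makes
is validated on cohorts whose ground truth is known.

## The mediation model

For patient $i$, with treatment $T_i \in \{0, 1\}$ (BA = 1), mediator $M_i$
(PRL percentage of FLAIR lesions), outcome $Y_i$ (EDSS, treated as
continuous) and covariates $X_i$:

$$M_i = a_0 + \alpha T_i + b^\top X^{(M)}_i + \varepsilon_{M,i}, \qquad
  Y_i = c_0 + \gamma T_i + \beta M_i + g^\top X^{(Y)}_i + \varepsilon_{Y,i}.$$

Under sequential ignorability and with no treatment–mediator interaction,
the average causal mediation effect is $\mathrm{ACME} = \alpha\beta$, the
average direct effect $\mathrm{ADE} = \gamma$, the total effect their sum,
and the proportion mediated $\alpha\beta / (\alpha\beta + \gamma)$. The
analytic product-of-coefficients estimator coincides, in this linear
no-interaction case, with the simulation-based ACME definition used by the
general mediation framework; we use the analytic form because it is exact
and makes the decomposition $\mathrm{ACME} + \mathrm{ADE} =
\mathrm{total}$ hold to machine precision on every fit.

The three named models (`fit_named_model()`) default to:

| role | response | right-hand side |
|---|---|---|
| `mediator` | `prl_percentage` | race + age + DMT |
| `outcome` | `edss` | race + `prl_percentage` + age + DMT + non-PRL volume |
| `total_effect` | `edss` | race + age + sex + disease duration + DMT + non-PRL volume + income |

DMT (disease-modifying therapy) enters as two dummies, lower-efficacy and
untreated, against the higher-efficacy reference; sex as a male dummy;
zip-code income is rescaled to \$10,000 units to condition the design
matrix. The engine's total effect is always the identity
$\mathrm{ACME}+\mathrm{ADE}$ from the mediator/outcome pair; the richer
`total_effect` specification is fitted and reported separately, so the two
"total" numbers may legitimately differ when their covariate sets differ.
EDSS is ordinal in the clinic but is modelled as continuous throughout,
deliberately mirroring the linear-model treatment that motivated this
package; no proportional-odds alternative is provided.

## The synthetic cohort generator

`cohort_config()` holds every distributional and structural parameter;
`generate_cohort()` draws a cohort reproducibly from a seed. Defaults encode
the published study conditions: 117 BA and 123 WA patients; per-race age,
sex, disease-duration, DMT, income and non-PRL-lesion-volume distributions
matched to the reported group summaries; mediator and outcome structural
coefficients matched to the reported regression estimates ($\alpha = 4.65$
percentage points, $\beta = 0.021$ EDSS per percentage point,
$\gamma = 0.60$ EDSS points, age 0.05 EDSS/year, DMT lower vs higher
$-0.58$, untreated vs higher $-0.31$, non-PRL volume $5\times 10^{-5}$ EDSS
per mm³).

Two modes trade realism against exact recoverability:

* **linear** — the mediator is an unbounded Gaussian realisation of its
  structural equation. OLS on the correctly-specified models is then exactly
  unbiased for every coefficient, which is what the seed-averaged recovery
  checks in the acceptance suite exploit. The PRL percentage can stray
  outside $[0, 100]$ (documented behaviour); `prl_count` is a descriptive
  rounding of the clamped percentage.
* **count** — each patient draws a FLAIR lesion count from a zero-truncated
  negative binomial (every patient has at least one lesion, so the
  percentage is always defined), then a per-lesion rim probability
  $p_i = \mathrm{logis}(\eta_r + \tau_r Z_i)$ with a patient-level
  logit-normal random effect, then
  $\texttt{prl\_count} \sim \mathrm{Bin}(\texttt{flair\_count}, p_i)$. The
  realized percentage $100\,\texttt{prl\_count}/\texttt{flair\_count}$ — a
  genuine bounded, zero-inflated quantity — feeds the outcome equation.

Choices a user should know about:

* **Residual sds.** The mediator residual sds are the per-race sds of the
  PRL percentage from the published summary table (15.25 BA / 7.50 WA),
  since covariates explain little of that variance. The outcome residual
  sds (1.92 BA / 1.47 WA) were derived once by subtracting the
  model-explained variance from the published within-race EDSS variances;
  they imply a direct-effect standard error of about 0.23 EDSS points and a
  per-cohort ACME sd of about 0.06, both consistent with the published
  bootstrap interval widths. Residuals are heteroscedastic across race by
  construction while the OLS stages assume homoscedasticity — deliberate,
  as in the analysis this package models.
* **Mediator covariate loadings.** The age and DMT loadings of the mediator
  equation are not published; small realistic values (age $+0.05$ pp/year,
  lower-efficacy $-1.5$, untreated $+1.0$) are used. The analysis models
  adjust for these covariates, so recovery of $\alpha$, $\beta$, $\gamma$
  does not depend on them.
* **Intercepts.** Left `NULL`, the mediator and outcome intercepts are
  solved analytically so that the WA group means equal their targets (PRL
  percentage 3.40; EDSS 1.30) in expectation, using truncated-normal means
  for age and the exact logit-normal mean in count mode. The BA group means
  are then implied by the structure (direct effect + mediated gap +
  covariate gaps), not separately dialled.
* **Truncations.** Age is truncated at 18 years, disease duration at 0,
  income at \$1,000 (inverse-CDF truncation, so draws stay vectorised and
  reproducible). Non-PRL volume is lognormal with moments matched to the
  published mean/sd; total FLAIR volume is non-PRL volume plus a per-PRL
  lognormal volume (mean 750 mm³, sd 400), keeping
  `non_prl_volume <= flair_volume` exactly.
* **Confounder channel.** `confounder_strength` adds a latent standard
  normal to both disturbances, violating sequential ignorability by a known
  amount; 0 (the default) makes the disturbances independent by
  construction. This is the lever the sensitivity-analysis tests use.

What the generator does **not** emulate: longitudinal trajectories, spatial
lesion structure, floor/ceiling dynamics of the EDSS scale (the latent
outcome is Gaussian; optional rounding onto the 0–9.5 half-point grid is
available but off by default because recovery targets use the latent
value), missing data, and any dependence of lesion counts on covariates.
Passing tests therefore demonstrate correctness of the estimators under the
assumed structural model, not robustness to real-data violations of it.

## Calibrating the lesion-count model

The count mode has four free parameters — a WA logit location, a BA shift,
and per-race overdispersion sds — and four targets: per-race mean PRL
percentage (8.01 / 3.40) and prevalence of at least one PRL (0.55 / 0.39).
`calibrate_count_model()` computes exact model moments by 61-node
Gauss–Hermite quadrature over the logit-normal random effect and summation
over the zero-truncated negative-binomial lesion-count distribution, and
solves each race's two-equation system by nested one-dimensional
root-finding (location matching the mean inside, overdispersion matching
the prevalence outside). The procedure is deterministic and solves to the
quadrature tolerance; a shared overdispersion sd was investigated and
cannot reach all four targets, which is why it is per-race — consistent
with every other per-race scale parameter in the configuration. Infeasible
targets (e.g. a prevalence the mean cannot support) raise a calibration
error reporting the best achievable moments.

The negative-binomial FLAIR parameters (mean 23.83 / 22.00, size 1.393 /
1.239) are moment-matched to the published count mean/sd before
zero-truncation; truncation shifts the mean up by under 3%, which is
immaterial for the percentage and prevalence targets.

## Bootstrap inference

`bootstrap_mediation()` resamples patient rows i.i.d. with replacement
(full-cohort by default; stratified-by-race available), refits both models
per replicate by QR least squares on pre-built design matrices, and
recomputes all four quantities. Conventions, fixed and documented:

* **Percentile intervals** use `stats::quantile()` type 7 (linear
  interpolation of order statistics).
* **P-values** use the sign-flip rule
  $p = 2\min(\hat F(0), 1 - \hat F(0^-))$, capped at 1; when no draw
  crosses zero the value is below the bootstrap resolution and reported as
  $< 2/n_\text{boot}$. The p-value convention used in the original
  analysis is unstated; this rule is a documented package choice, not a
  claim about theirs.
* **Degenerate replicates** (rank-deficient designs, e.g. a resample losing
  a DMT level) are redrawn and counted, capped at 1% of `n_boot`, beyond
  which the cohort is declared too fragile to bootstrap.
* **Proportion mediated** is computed per replicate as
  $\mathrm{acme}/(\mathrm{acme}+\mathrm{ade})$; replicates with
  $|\text{total}| < 10^{-6}$ are excluded from its interval and counted as
  unstable, since the ratio diverges as the total effect crosses zero. For
  the same reason, seed-averaged summaries of the proportion should be
  formed as the ratio of averaged effects, not the average of per-seed
  ratios: with a total effect only a few standard errors from zero the
  per-seed ratio is heavy-tailed and its mean does not converge to the
  population proportion.

The default `n_boot` is 25,000, the study-scale replicate count; the test
suite uses 150–2,000 replicates per call, and the bootstrap-coverage
property uses 1,000 replicates over 300 cohorts spanning null to moderate
effect sizes. These sizes were chosen to keep each property statistically
sharp at interactive runtimes.

## Sensitivity analysis

Sequential ignorability cannot be verified from data; its violation is
parameterised by $\rho$, the correlation between the mediator and outcome
disturbances. In the linear case the re-identified ACME has the closed form

$$\mathrm{ACME}(\rho) = \frac{\hat\alpha \sigma_1}{\sigma_2}
  \left[\tilde\rho - \rho\sqrt{\frac{1-\tilde\rho^2}{1-\rho^2}}\right],$$

with $\sigma_1, \sigma_2$ the residual sds of the no-mediator outcome fit
and the mediator fit and $\tilde\rho$ their residual correlation. Rather
than taking the formula on authority, the implementation anchors it to two
identities that must hold exactly and are verified numerically in the test
suite: $\mathrm{ACME}(0) = \hat\alpha\hat\beta$ (Frisch–Waugh–Lovell) and
$\mathrm{ACME}(\tilde\rho) = 0$. For the anchors to be exact the two fits
must share the outcome model's non-mediator covariate set, so
`sensitivity_analysis()` refits both models on that harmonised set (age,
DMT, non-PRL volume by default) instead of reusing the richer named
total-effect model. The zero crossing is located by bisection to $10^{-6}$;
analytically it equals $\tilde\rho$, and the curve is tabulated on a default
grid of $(-0.9, 0.9)$ in steps of 0.01. The reported crossing is a point
diagnostic; no claim is made that it matches any interval-valued
"sensitivity region" convention.

## Numerical and degenerate-input conventions

* Rank-deficient designs raise an error listing the dependent columns
  (QR pivoting); standard errors come from $\hat\sigma^2 (X^\top X)^{-1}$
  with $\hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{rank})$ and t-distribution
  p-values.
* The rank-sum test enumerates all midrank assignments exactly for combined
  $n \le 12$ (ties handled by midranks) and otherwise uses the normal
  approximation with tie-corrected variance and continuity correction.
* Fisher's test on a table with an empty row or column returns $p = 1$ by
  convention. The Yates-corrected chi-squared and the two-sided
  minimum-likelihood Fisher p-values track each other closely in the
  small-p region; near $p \approx 0.5$ the two-sided conventions differ by
  construction, which the property tests acknowledge.
* Identical constant groups in the t test return $t = 0, p = 1$; a single
  degenerate-variance group is an error.
* Cohort CSVs are written at full double precision, so write–read round
  trips are exact; validation errors name the offending row and column.

## Problem sizes used by the tests

Structural-fidelity checks regress on cohorts of 100,000 per group;
count-model calibration is verified by forward simulation at 50,000–100,000
per group; seed-averaged coefficient recovery uses 200 cohorts at the study
size (117/123); bootstrap coverage uses 300 cohorts at 1,000 replicates.
These sizes make Monte-Carlo error small relative to every asserted
tolerance while keeping the full suite interactive.

## Known limitations

* The generator's structural model is exactly the model the estimators
  assume; tests certify the estimators, not the model.
* No quasi-Bayesian inference, no treatment–mediator interaction, no
  multiple mediators, no multilevel structure, no robust/sandwich standard
  errors, and no R²-parameterised sensitivity variant.
* The count mode's overdispersion family (logit-normal) is a modelling
  choice; the data motivating the calibration constrain only the mean and
  prevalence, not the full shape of the PRL-percentage distribution.
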