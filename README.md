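# prlmediate

Causal mediation analysis of race-related disability in multiple sclerosis
(MS), with paramagnetic rim lesion (PRL) burden as the mediator.

Black-American (BA) MS patients carry, on average, higher disability —
measured by the Expanded Disability Status Scale (EDSS) — than White-American
(WA) patients. PRLs are chronic active lesions with an iron-laden immune-cell
rim, visible on susceptibility-based MRI, and BA patients carry a higher
percentage of them among their FLAIR white-matter lesions. `prlmediate` is a
simulation-and-analysis toolkit for the question: *how much of the BA–WA EDSS
gap is transmitted through PRL burden?* It is written for biostatisticians
and neuroimaging researchers who want a tested, reproducible implementation
of the full pipeline:

* a **synthetic cohort generator** calibrated to the published cohort
  (117 BA / 123 WA patients), with a linear-Gaussian mode for exact
  coefficient recovery and an overdispersed lesion-count mode for realistic
  bounded mediators, plus an optional latent-confounder channel;
* **table-one statistics** — Yates-corrected chi-squared, Welch/pooled t,
  Wilcoxon rank-sum (exact for small samples), Fisher's exact test;
* the **three linear models** of the mediation design (total-effect,
  mediator, outcome models) on explicit, deterministic design matrices;
* **mediation inference**: product-of-coefficients ACME, ADE, total effect
  and proportion mediated, with nonparametric percentile-bootstrap
  confidence intervals and sign-flip p-values;
* a **sequential-ignorability sensitivity analysis** giving the ACME as a
  function of the mediator–outcome residual correlation ρ.

## The model

With treatment `T` (race, BA = 1), mediator `M` (percentage of FLAIR lesions
that are PRLs), outcome `Y` (EDSS) and covariates `X` (age, DMT category,
non-PRL lesion volume, ...):

```
M = a0 + α T + b' X_M + ε_M          (mediator model)
Y = c0 + γ T + β M + g' X_Y + ε_Y    (outcome model)
```

In this linear, no-interaction setting the average causal mediation effect is
the product of coefficients, `ACME = α β`, the average direct effect is
`ADE = γ`, the total effect is `ACME + ADE`, and the proportion mediated is
`ACME / (ACME + ADE)`. Sequential ignorability (no unobserved
mediator–outcome confounding) is probed by re-identifying the ACME as a
function of the residual correlation ρ:

```
ACME(ρ) = (α̂ σ₁ / σ₂) · [ρ̃ − ρ √((1 − ρ̃²) / (1 − ρ²))]
```

where σ₁, σ₂ are the residual sds of the no-mediator outcome fit and the
mediator fit and ρ̃ their residual correlation. `ACME(0)` equals `α̂ β̂` by
the Frisch–Waugh–Lovell theorem, and `ACME(ρ̃) = 0`; both identities are
verified numerically in the test suite.

## Worked example

```r
library(prlmediate)

cohort <- generate_cohort(cohort_config(), seed = 1)   # 117 BA + 123 WA patients
med <- bootstrap_mediation(cohort, n_boot = 25000, seed = 1)
med
#> <prl_mediation>  n = 240 patients, 25000 bootstrap replicates (seed 1)
#>   acme             0.0711  [-0.0212, 0.2025]  p 0.1457
#>   ade              0.7621  [0.3090, 1.2376]  p 0.00144
#>   total_effect     0.8331  [0.3639, 1.3216]  p 0.00024
#>   prop_mediated    0.0853  [-0.0306, 0.2623]  p 0.1459

sensitivity_analysis(cohort)
#> <prl_sensitivity>
#>   observed residual correlation rho-tilde: 0.1962
#>   ACME at rho = 0: 0.0755; zero crossing at rho = 0.1962
#>   grid: 181 points in [-0.90, 0.90]
```

This one synthetic cohort carries a mediated effect of about 0.07 EDSS
points (the path race → PRL percentage → EDSS), a direct race effect of 0.76
EDSS points, and a proportion mediated around 9% — one random draw around
the structural values the generator encodes (ACME 0.098, ADE 0.60,
proportion 14%). The sensitivity analysis says the mediated effect would be
explained away by an unobserved confounder inducing a mediator–outcome
residual correlation of about 0.2. Single cohorts of this size are noisy;
seed-averaged recovery of the structural values is what the acceptance
script below measures.

Everything is a tibble or has `tidy()` / `glance()` / `autoplot()` methods:

```r
tidy(med)                      # term, estimate, ci_lower, ci_upper, p_value
tidy(fit_named_model(cohort, "mediator"))
autoplot(sensitivity_analysis(cohort))
table_one(cohort)              # 12-variable group comparison
```

A command-line front end wraps the same functions:

```sh
Rscript scripts/prlmediate.R report --seed 1 --out run/report
```

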