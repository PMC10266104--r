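---
title: "Mapping PedsQL 4.0 onto CHU-9D: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping PedsQL 4.0 onto CHU-9D: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chumap)
```

## The problem

Pediatric clinical studies very often collect the PedsQL 4.0 generic core
scales — 23 Likert items over physical (PF, 8 items), emotional (EF),
social (SF) and school (ScF) functioning (5 items each) — but PedsQL is
not preference-based: it cannot produce the health utility values that
cost-utility analyses need. The CHU-9D is preference-based: nine
dimensions (worried, sad, pain, tired, annoyed, schoolwork, sleep, daily
routine, activities) with five levels each define
$5^9 = 1{,}953{,}125$ states, and a country-specific tariff assigns each
state a utility anchored at 1 (full health). A *mapping* (crosswalk)
estimates CHU-9D utilities from PedsQL scores, letting existing PedsQL
data feed economic evaluation.

`chumap` implements the complete mapping workflow: scoring both
instruments, six estimator families over six regressor combinations,
cross-validated comparison and ranking, and a packaged published
crosswalk applicable to new data.

## Instrument scoring

PedsQL raw responses $r \in \{0,\dots,4\}$ are reverse-scored to
$100 - 25r$. A dimension score is the mean of its *answered* items, and
the total score the mean over all answered items (item-weighted). We
deliberately apply no imputation and no half-scale rule: a record whose
dimension is entirely missing gets a missing dimension score and is
excluded from fits requiring that regressor.

CHU-9D utilities use the additive multi-attribute form
$U(s) = 1 - \sum_d \delta_d(\ell_d)$, with $\delta_d(1) = 0$ and
decrements non-decreasing in level. The tariff is a configuration input
(`read_valueset()`), because tariffs are country-specific and
licence-bound. The package ships a clearly-labelled *synthetic* tariff
(worst state 0.315) for examples and tests only; whether a real tariff is
strictly additive is isolated behind the `chu9d_valueset` abstraction, so
a tariff with interaction terms would only require a new `chu9d_utility`
method, not changes to the estimators.

## The six estimators

Direct mapping regresses the observed utility $y_i$ on PedsQL regressors
$x_i$ (all scores divided by 100):

* **OLS** — baseline linear fit; predictions are the raw linear
  predictor, which can exceed 1 near full health.
* **GLM (logit link)** — $E[y] = \mathrm{logit}^{-1}(x'\beta)$ with
  Gaussian working errors, fitted by IRLS. Predictions always lie in
  (0, 1). (Published mapping tables sometimes report GLM maxima above 1,
  which a logit inverse link cannot produce; we implement the stated
  link and note the inconsistency rather than reverse-engineering a
  variant.)
* **MM** — high-breakdown robust regression (S-scale stage, then Tukey
  bisquare M-step at 95% Gaussian efficiency), resistant to outlying
  utilities.
* **Tobit** — latent $y^* = x'\beta + \varepsilon$,
  $\varepsilon \sim N(0,\sigma^2)$, observed $y = \min(y^*, 1)$. The
  log-likelihood mixes normal densities (uncensored) and upper-tail
  probabilities (ceiling observations). Censoring is upper-only by
  default: observed utility minima sit far above any floor, and the
  published prediction rule caps only at 1; a lower bound is available
  as an argument.
* **Beta** — $y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with
  $\mu = \mathrm{logit}^{-1}(x'\beta)$, suited to skewed,
  heteroscedastic unit-interval outcomes.

Response mapping (**MLOGIT**) fits one multinomial logit per CHU-9D
dimension on the same regressors and aggregates by expected utility:
$\hat U(x) = 1 - \sum_d \sum_k P_d(k \mid x)\, \delta_d(k)$, which is
exact under an additive tariff (verified in tests against brute-force
state enumeration on a reduced toy). Levels unobserved in training get
probability zero — the recognised weakness of response mapping with
sparse level coverage, which the fitter surfaces as a warning and the
ranking step treats by excluding MLOGIT from the default recommendation
while still reporting it.

### Numerical choices

Logit-mean models need $y \in (0,1)$, but utilities include exact 1.0
values; `adjust_boundary()` applies the conventional compression
$y' = (y(n-1) + 0.5)/n$ before GLM-logit and Beta fits (configurable).
Tobit and Beta are maximised by BFGS with analytic gradients, started
from OLS (Tobit: OLS $\beta$ and residual SD; Beta: OLS on
$\mathrm{logit}(y')$ with a method-of-moments precision), then polished
by damped Newton steps accepted on gradient-norm decrease — near the
optimum the objective change falls below likelihood summation noise, so
a function-decrease rule would stall early. Fits store `grad_max`, the
largest absolute score component at the returned optimum, as a
convergence self-check (typically below 1e-10). Standard errors come
from the inverse observed information. Degenerate inputs error early:
all-censored Tobit samples, scale collapse, rank-deficient designs
(reported with the offending column names), constant outcomes for
metrics.

## Variable combinations and selection

The six regressor combinations are: (1) total score; (2) total, gender,
age; (3) the four dimension scores; (4) those plus gender and age;
(5) 13 stepwise-selected item scores; (6) those plus gender and age.
Gender is coded female = 1. `spearman_screen()` reproduces the
conceptual-overlap screen with the conventional strength bands
(very weak < 0.20 ≤ weak < 0.40 ≤ moderate < 0.60 ≤ strong < 0.80 ≤
very strong). `stepwise_select()` is forward-backward OLS stepwise with
p-to-enter = p-to-remove = 0.05 on partial t-tests, run once on the full
sample (matching the fixed published item list) rather than per fold; a
per-fold re-selection is a one-line change if wanted. Note that with 23
candidates and $\alpha = 0.05$, null data still admit occasional
single-item false inclusions — an inherent property of unadjusted
stepwise testing, not a defect of the implementation.

## Validation and ranking

`compute_metrics()` reports mean/SD/min/max of predictions, MAE, RMSE,
adjusted $R^2$ and Lin's concordance correlation coefficient with
n-denominator moments. `kfold_cv()` shuffles with a mandatory seed,
builds folds whose sizes differ by at most one, computes metrics on each
held-out fold (adjusted $R^2$ with the fold's own n — the alternative
pooled aggregation is available via `aggregate = "pooled"`, which is
also the correct mode for leave-one-out, where fold-level moments are
undefined), and averages across folds. Training folds that lose a design
column's variation are skipped with a warning. Folds are simple random
draws without stratification.

`rank_models()` ranks each model per metric (MAE, RMSE ascending;
adjusted $R^2$, CCC descending), averages the four ranks, and breaks
ties by MAE — RMSE is more outlier-sensitive, so when the two disagree
MAE is the better arbiter. The aggregation rule ("comprehensive
ranking") is our interpretation of common practice: the mean of
per-metric ranks is the simplest symmetric choice, and the MAE tiebreak
is documented rather than hidden. `run_tournament()` drives all
family-by-combination cells and produces per-combination rank tables
with a recommended (non-MLOGIT) model.

## The published crosswalk

`load_crosswalk()` reads the versioned YAML table of published
coefficient sets (estimated on a Chinese pediatric functional-dyspepsia
cohort, n = 2,152): combinations 1–3 follow the Beta rule
$\hat u = \mathrm{logit}^{-1}(x'\beta)$, combinations 4–6 the Tobit rule
$\hat u = \min(x'\beta, 1)$. `predict_published()` applies them to new
data (raw items are scored automatically), and
`auto_select_combination()` picks the richest combination the available
fields support, warning and downgrading when demographics are partial —
missing inputs are never imputed. The retained EF5 coefficient in
combination 6 is not significant at the 10% level in the source table
but is part of the printed model, so it ships as printed.

## The synthetic-cohort generator

No respondent-level data are deposited with the source crosswalk, so the
package generates cohorts with the joint structure the analysis assumes.
One latent health trait $\theta_i \sim N(0,1)$ (plus small additive age
and gender shifts, defaults $+0.05(\text{age}-7)$ and $-0.05 \cdot
\text{female}$, so demographic combinations have something to detect)
drives every PedsQL item and CHU-9D dimension through cumulative-logistic
(graded-response) ordinal models. Thresholds were derived analytically
from target marginal category probabilities chosen to match the published
cohort profile: per-dimension mean scores near 67/57/57/62, total near
61.5, mean utility near 0.88 with SD near 0.09, a mass of exact-1
utilities and left skew, ages concentrated on 6–8 (mean ≈ 7.2, drawn from
a fixed weight vector over 6–17), and 45.31% girls. Item loadings of 0.5
and dimension loadings of 1.0 give a Spearman correlation between total
score and utility of about 0.62, inside the strong band the mapping
premise requires. Missingness is completely at random with default rate
0.

What the generator does *not* emulate: the published cohort's unusually
high total-score floor (53.1), multidimensional latent structure,
proxy-report response bias, and any tariff-specific utility clustering.
Passing tests therefore demonstrate correctness of the machinery and
qualitative reproduction of the study regime, not quantitative
reproduction of the published goodness-of-fit tables, which depend on
the undeposited clinical sample.

## Problem sizes

Tests and examples use cohorts of n = 2,000 (the scale of the source
study) for tournaments and cross-validation, n = 5,000 for
parameter-recovery experiments, and n = 10,000 for generator-calibration
checks; these sizes keep Monte-Carlo error comfortably inside the
asserted bands while the full suite runs in a few minutes on one CPU.

## Known limitations

* The additive-tariff assumption is structural; non-additive tariffs
  need a new utility method (the expected-utility step would then
  require full state enumeration rather than per-dimension sums).
* The published crosswalk ships point estimates and standard errors but
  no covariance matrix, so mapped utilities carry no confidence
  intervals.
* MLOGIT fits can be biased when dimension levels are sparsely observed;
  the package warns and excludes it from recommendations by default.
* Parent-proxy versus self-report differences and recall-period logic
  are out of scope; all records are treated identically.
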