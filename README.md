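# chumap — mapping PedsQL 4.0 onto CHU-9D health utilities

Pediatric clinical studies routinely collect the **PedsQL 4.0** generic
core scales (23 items over physical, emotional, social and school
functioning), but PedsQL is not preference-based and cannot produce the
health utility values that QALY-based economic evaluation needs. The
**CHU-9D** is preference-based: nine dimensions × five levels define
5⁹ = 1,953,125 health states, scored by a country tariff as
*U(s) = 1 − Σ_d δ_d(ℓ_d)*, anchored at 1 for full health.

`chumap` implements the full utility-mapping (crosswalk) workflow for
health economists and outcomes researchers:

- **scoring** both instruments (`pedsql_score()`, `chu9d_utility()`,
  user-supplied tariffs via `read_valueset()`);
- **six mapping estimators** over six regressor combinations — OLS,
  GLM with logit link, robust MM, upper-censored Tobit
  (*y = min(x'β + ε, 1)*, censored-normal MLE), Beta regression
  (*μ = logit⁻¹(x'β)*, precision φ), and multinomial-logit response
  mapping aggregated by expected utility;
- **validation**: MAE, RMSE, adjusted R², Lin's CCC, seeded 10-fold
  cross-validation, Spearman screening with strength bands, stepwise
  item selection, and a comprehensive mean-rank tournament
  (`run_tournament()`);
- the **published crosswalk** (six coefficient sets estimated on a
  Chinese pediatric functional-dyspepsia cohort, n = 2,152), applied to
  new PedsQL data with `predict_published()` and automatic combination
  selection;
- a **seeded synthetic-cohort generator** (`generate_cohort()`)
  reproducing the joint PedsQL/CHU-9D structure of such cohorts, so the
  whole pipeline is testable without clinical data.

See `vignettes/utility-mapping-methods.Rmd` for the models, assumptions
and design choices.

## Worked example

```r
library(chumap)
vs  <- synthetic_valueset()            # demo tariff; real use: read_valueset()
coh <- generate_cohort(2000, seed = 1) # synthetic paired-instrument cohort
prep <- prepare_mapping_data(coh, vs)

spearman_screen(prep[c("total", "PF", "EF", "SF", "ScF")], prep$utility)
#>   variable       rho     band
#> 1    total 0.6278926   strong
#> 2       PF 0.5019508 moderate
#> 3       EF 0.3857723     weak
#> 4       SF 0.4044751 moderate
#> 5      ScF 0.4105968 moderate
```

The strong total-score correlation is the conceptual-overlap evidence
mapping requires. Cross-validate one estimator:

```r
kfold_cv(coh, "tobit", combination = 4, vs, k = 10, seed = 1)
#> 10-fold CV: family tobit, combination 4
#> n = 2000, p = 6 | mean P 0.8779 (SD 0.0031), range [0.6706, 1.0000]
#> MAE 0.0536  RMSE 0.0689  adj R2 0.3918  CCC 0.5886
```

The Tobit maximum prediction is exactly 1.0000 — the censoring rule caps
at the full-health bound, while OLS/MM predictions overshoot it. Apply
the published crosswalk to new data:

```r
predict_published(data.frame(total = 61.52), combination = 1)
#>   id combination predicted_utility
#> 1  1           1         0.9093642

predict_published(data.frame(PF = 100, EF = 100, SF = 100, ScF = 100,
                             female = 0, age = 17), combination = 4)
#>   id combination predicted_utility
#> 1  1           4                 1
```

A boy aged 17 at the best PedsQL dimension profile has an uncapped
combination-4 linear predictor of 1.2294, so the Tobit rule returns the
bound 1 — the maximum attainable mapped utility.

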