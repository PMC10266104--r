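# Published PedsQL 4.0 -> CHU-9D crosswalk coefficients, six variable
# combinations, estimated on a Chinese pediatric functional-dyspepsia
# cohort (n = 2,152). Combinations 1-3 use the Beta-regression rule
# (inverse-logit of the linear predictor); combinations 4-6 use the Tobit
# rule (linear predictor capped at 1). All PedsQL score regressors enter
# divided by 100; female is coded 1, male 0; age in years.
version: "1.0"
gender_coding: "female = 1, male = 0"
score_scaling: "all PedsQL 0-100 scores divided by 100"
combinations:
  combination1:
    rule: beta_inverse_logit
    coefficients:
      intercept: -7.9832
      total: 16.7248
    se:
      intercept: 0.2245
      total: 0.3761
  combination2:
    rule: beta_inverse_logit
    coefficients:
      intercept: -7.6672
      total: 15.8034
      female: -0.1698
      age: 0.0446
    se:
      intercept: 0.2247
      total: 0.4217
      female: 0.0387
      age: 0.0155
  combination3:
    rule: beta_inverse_logit
    coefficients:
      intercept: -4.0199
      PF: 3.2633
      EF: -5.5249
      SF: 9.2555
      ScF: 3.3013
    se:
      intercept: 0.2942
      PF: 0.3777
      EF: 0.4787
      SF: 0.3088
      ScF: 0.4243
  combination4:
    rule: tobit_censor
    coefficients:
      intercept: 0.5415
      PF: -0.1221
      EF: -0.2637
      SF: 0.5415
      ScF: 0.1888
      female: -0.0058
      age: 0.0202
    se:
      intercept: 0.0263
      PF: 0.0465
      EF: 0.0409
      SF: 0.0259
      ScF: 0.0373
      female: 0.0033
      age: 0.0016
  combination5:
    rule: tobit_censor
    coefficients:
      intercept: 0.8991
      pf2: -0.1566
      pf5: 0.2031
      pf8: -0.1554
      ef1: -0.1134
      ef4: -0.0721
      ef5: 0.0423
      sf1: 0.0605
      sf3: 0.2412
      sf4: 0.1554
      scf1: 0.1453
      scf2: 0.0755
      scf3: -0.1907
      scf4: -0.1386
    se:
      intercept: 0.0301
      pf2: 0.0283
      pf5: 0.0123
      pf8: 0.0339
      ef1: 0.0221
      ef4: 0.0236
      ef5: 0.0176
      sf1: 0.0162
      sf3: 0.0188
      sf4: 0.0209
      scf1: 0.0120
      scf2: 0.0134
      scf3: 0.0360
      scf4: 0.0349
  combination6:
    rule: tobit_censor
    coefficients:
      intercept: 0.8652
      pf2: -0.1721
      pf5: 0.1234
      pf8: -0.1491
      ef1: -0.0996
      ef4: -0.0479
      ef5: 0.0338
      sf1: 0.0581
      sf3: 0.2432
      sf4: 0.1617
      scf1: 0.1403
      scf2: 0.0640
      scf3: -0.1996
      scf4: -0.1218
      female: 0.0016
      age: 0.0089
    se:
      intercept: 0.0313
      pf2: 0.0283
      pf5: 0.0209
      pf8: 0.0339
      ef1: 0.0222
      ef4: 0.0240
      ef5: 0.0175
      sf1: 0.0162
      sf3: 0.0187
      sf4: 0.0208
      scf1: 0.0120
      scf2: 0.0135
      scf3: 0.0360
      scf4: 0.0349
      female: 0.0030
      age: 0.0019
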