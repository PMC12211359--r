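model: soft
thresholds:
- 0.1
- 0.11
- 0.12
- 0.13
- 0.14
- 0.15
- 0.16
- 0.17
- 0.18
- 0.19
- 0.2
wtp:
- 10274.0
- 30823.0
discount: 0.05
psa_n: 1000.0
seed: 2.0190101e+07
parameters:
  rr_nonfatal_ihd:
    base: 0.67
    low: 0.59
    high: 0.76
    distribution: lognormal
  rr_nonfatal_is:
    base: 0.69
    low: 0.58
    high: 0.83
    distribution: lognormal
  rr_fatal_ascvd:
    base: 0.83
    low: 0.72
    high: 0.96
    distribution: lognormal
  p_adverse_diabetes:
    base: 0.003
    low: 0.0026
    high: 0.0035
    distribution: beta
  p_adverse_myopathy:
    base: 0.0024
    low: 0.002
    high: 0.0028
    distribution: beta
  p_discontinue_other:
    base: 0.1186
    low: 0.1008
    high: 0.1364
    distribution: beta
  statin_annual:
    base: 61.43
    low: 40.2
    high: 112.07
    distribution: gamma
  exam_per_visit:
    base: 4.35
    low: 2.9
    high: 7.25
    distribution: gamma
  registration_annual:
    base: 52.17
    low: 34.78
    high: 86.96
    distribution: gamma
  hosp_diabetes:
    base: 1149.7
    low: 977.25
    high: 1322.14
    distribution: gamma
  chronic_diabetes:
    base: 835.87
    low: 710.49
    high: 961.25
    distribution: gamma
  hosp_myopathy:
    base: 1793.36
    low: 1524.35
    high: 2062.36
    distribution: gamma
  hosp_acute_mi:
    base: 4401.23
    low: 2697.8
    high: 4738.36
    distribution: gamma
  hosp_other_ihd:
    base: 2037.71
    low: 1093.93
    high: 2372.42
    distribution: gamma
  hosp_is:
    base: 1421.91
    low: 944.87
    high: 1830.2
    distribution: gamma
  chronic_ihd:
    base: 427.04
    low: 362.99
    high: 491.1
    distribution: gamma
  chronic_is:
    base: 242.38
    low: 206.01
    high: 278.74
    distribution: gamma
  days_acute_mi:
    base: 8.05
    low: 7.59
    high: 8.3
    distribution: gamma
  days_other_ihd:
    base: 7.79
    low: 7.73
    high: 7.85
    distribution: gamma
  days_is:
    base: 10.01
    low: 9.5
    high: 10.73
    distribution: gamma
  days_diabetes:
    base: 9.39
    low: 8.83
    high: 9.88
    distribution: gamma
  days_myopathy:
    base: 9.21
    low: 9.03
    high: 9.37
    distribution: gamma
  salary_annual:
    base: 13116.09
    low: 11148.68
    high: 15083.51
    distribution: gamma
  unemployment:
    base: 0.052
    low: 0.044
    high: 0.06
    distribution: beta
  u_on_statin:
    base: 0.999
    low: 0.998
    high: 1.0
    distribution: beta
  u_acute_event:
    base: 0.5
    low: 0.2
    high: 0.8
    distribution: fixed
  u_chronic_ihd:
    base: 0.87
    low: 0.75
    high: 0.9
    distribution: beta
  u_chronic_is:
    base: 0.9
    low: 0.9
    high: 0.9
    distribution: fixed
  u_diabetes:
    base: 0.84
    low: 0.79
    high: 0.94
    distribution: beta
  u_myopathy:
    base: 0.56
    low: 0.56
    high: 0.56
    distribution: fixed
  discount_rate:
    base: 0.05
    low: 0.0
    high: 0.08
    distribution: fixed
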