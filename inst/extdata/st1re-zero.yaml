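# Degenerate test configuration: every coefficient zero, so the engine
# predicts the same risk (here 1 - exp(-exp(-2.25)) ~ 0.10) for all patients.
form: complementary-log-log
baseline_param: -2.25
horizon: 10
provenance: "degenerate all-zero coefficient set for smoke tests"
terms:
  - covariate: age
    transform: identity
    coefficient: 0.0
  - covariate: sex
    transform: indicator
    level: male
    coefficient: 0.0
  - covariate: sbp
    transform: identity
    coefficient: 0.0
  - covariate: ldl_chol
    transform: identity
    coefficient: 0.0
  - covariate: egfr
    transform: identity
    coefficient: 0.0
  - covariate: smoker
    transform: identity
    coefficient: 0.0
  - covariate: diabetes_duration
    transform: identity
    coefficient: 0.0
  - covariate: hba1c
    transform: identity
    coefficient: 0.0
  - covariate: albuminuria
    transform: indicator
    level: micro
    coefficient: 0.0
  - covariate: albuminuria
    transform: indicator
    level: macro
    coefficient: 0.0
  - covariate: exercise
    transform: identity
    coefficient: 0.0
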