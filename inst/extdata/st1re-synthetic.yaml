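# SYNTHETIC coefficient set, not a transcription of the published Steno Type 1
# Risk Engine. Signs and rough magnitudes are clinically plausible (risk rises
# with age, duration, SBP, LDL, HbA1c, smoking, albuminuria; falls with eGFR
# and exercise), calibrated so a typical young adult with T1D lands near a 4%
# 10-year total risk and an older multi-risk patient near 30-65%. Use only for
# simulation and testing; substitute a transcribed, provenance-tagged
# coefficient file for real analyses.
form: complementary-log-log
baseline_param: -7.4
horizon: 10
provenance: "synthetic, illustrative coefficients; not the published ST1RE fit"
terms:
  - covariate: age
    transform: identity
    coefficient: 0.06
  - covariate: sex
    transform: indicator
    level: male
    coefficient: 0.2
  - covariate: sbp
    transform: identity
    coefficient: 0.008
  - covariate: ldl_chol
    transform: identity
    coefficient: 0.005
  - covariate: egfr
    transform: identity
    coefficient: -0.01
  - covariate: smoker
    transform: identity
    coefficient: 0.6
  - covariate: diabetes_duration
    transform: identity
    coefficient: 0.02
  - covariate: hba1c
    transform: identity
    coefficient: 0.15
  - covariate: albuminuria
    transform: indicator
    level: micro
    coefficient: 0.4
  - covariate: albuminuria
    transform: indicator
    level: macro
    coefficient: 0.9
  - covariate: exercise
    transform: identity
    coefficient: -0.2
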