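---
title: "ESC risk categories versus the Steno Type 1 Risk Engine: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ESC risk categories versus the Steno Type 1 Risk Engine: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoconcord)
```

## The problem

Adults with type 1 diabetes (T1D) carry a markedly elevated cardiovascular
(CVD) risk, and the 2019 European Society of Cardiology (ESC) guidelines
stratify them into three categories — *moderate*, *high*, *very high* —
defined on 10-year **fatal** CVD risk bands (3–4%, 5–9%, ≥ 10%). The
classification is rule-based: very high risk is assigned to anyone with
previous CVD, target organ damage (proteinuria, eGFR < 30 ml/min/1.73 m²,
left ventricular hypertrophy, or retinopathy), three or more of the five
major risk factors (age > 35 years, hypertension, hypercholesterolemia,
smoking, obesity), or early-onset T1D (diagnosis at age 1–10) of more than
20 years' duration; moderate risk only to patients under 35 with duration
under 10 years and no risk factor; high risk to everyone else. A competing
view of the same patient comes from the Steno Type 1 Risk Engine (ST1RE), a
multivariable prediction model for the 10-year risk of a first fatal or
non-fatal CVD event (ischemic heart disease, ischemic stroke, heart failure,
peripheral artery disease) from ten clinical covariates.

`stenoconcord` implements both stratifications and their comparison: the
cross-tabulation of ESC category (with the very-high subcategory
decomposition) against binned ST1RE risk, in age strata, on real or
simulated cohorts.

## The classification rules and their edge cases

The guideline text leaves several boundaries open; the package fixes them as
follows (all configurable through `esc_thresholds()`):

* **Band gaps.** The printed fatal-risk bands ("5–9%", "3–4%") leave gaps
  (4–5%, 9–10%, < 3%). Because the three categories are exhaustive in the
  scheme, the bands are implemented as contiguous half-open intervals
  \[0.10, 1\], \[0.05, 0.10), \[0, 0.05) on the fatal scale, so every
  probability maps to exactly one category
  (`esc_category_total_bounds()`).
* **Strict inequalities.** The age risk factor is age *>* 35 and
  hypercholesterolemia LDL *>* 100 mg/dl, both strict as printed; the
  moderate category requires age *<* 35. A consequence: a patient aged
  exactly 35 carries no age risk factor yet can never be moderate. Age
  strata for reporting are `< 35` and `≥ 35`, matching how results are
  tabulated.
* **"Without other risk factors"** for the moderate category is read
  strictly: zero of the five major risk factors and no organ damage.
* **Obesity** is not defined in the source rules; the WHO convention
  BMI ≥ 30 kg/m² is used.
* **Missing data** propagate by three-valued logic: a category is assigned
  only when the rules decide it regardless of the missing values (e.g. a
  patient on lipid-lowering therapy is hypercholesterolemic even with
  missing LDL; a patient with retinopathy is very-high even with missing
  eGFR). Undecidable patients get `NA` and are reported, not guessed.

The very-high category is decomposed into mutually exclusive subcategories
(previous CVD dominant; otherwise *organ damage only*, *three-or-more risk
factors only*, *early-onset long duration only*, or *two or more of these*),
which partition the very-high row of every concordance table exactly.

## Derived clinical measures

LDL cholesterol is derived by the Friedewald formula
(LDL = TC − HDL − TG/5, invalid above 400 mg/dl triglycerides — such values
become missing, never zero; a measured LDL always takes precedence). eGFR
uses the 2009 CKD-EPI creatinine equation; the race coefficient defaults to
1 (omitted) because the emulated cohort reports none, and is an explicit
argument otherwise. A supplied eGFR takes precedence over a
creatinine-derived one. If onset age and duration disagree with age by more
than one year (rounding tolerance), duration is recomputed as
age − onset age and the repair logged.

## The risk engine as configuration

The coefficients of ST1RE are not part of this package's contract: the
engine is a configuration object (`st1re_config()`), with three supported
functional forms covering the plausible readings of published risk engines:

* complementary log-log: risk = 1 − exp(−exp(lp + b));
* Cox baseline survival: risk = 1 − S₀^exp(lp), S₀ ∈ (0, 1);
* logistic: risk = logistic(lp + b),

where lp is the configured linear predictor over the closed covariate set
{age, sex, SBP, LDL, eGFR, smoking, diabetes duration, HbA1c, albuminuria,
exercise}; transforms are identity, log, or indicator level (albuminuria
enters as indicator levels). Each form is continuous, strictly increasing in
lp, and numerically safe for linear predictors spanning at least \[−50, 50\]
(risks saturate at 0/1 rather than overflowing).

Two coefficient files ship with the package. `st1re-zero.yaml` is a
degenerate all-zero set for smoke tests (constant risk, so every
concordance row collapses into a single column). `st1re-synthetic.yaml` is a
**synthetic, illustrative** set — clinically plausible signs and magnitudes,
*not* a transcription of the published fit — used for simulation; its
provenance string says so, and `load_st1re_config()` warns whenever a config
carries no provenance. For real analyses, transcribe the published
coefficients into a config file and record their provenance.

### Binning predicted risk

The source rules never state which cutoffs map a predicted *total* risk to
the three bins. Both defensible schemes are implemented and the choice is an
explicit, logged run parameter:

* `esc-converted` (default): the fatal-risk edges 10% and 5% converted to
  the total (fatal + non-fatal) scale with the guideline multipliers —
  ×3 in men, ×4 in women — giving very-high ≥ 0.30/0.40 and high ≥
  0.15/0.20 (men/women). This is the scheme consistent with comparing
  against ESC categories defined on fatal risk.
* `uniform-10-20`: very-high ≥ 0.20, high ≥ 0.10, both sexes.

Lower bounds are inclusive; the ×3/×4 conversion caps products at 1.

## The synthetic cohort generator

The generator (`table1_default_config()`, `generate_cohort()`) emulates the
marginal structure of an adult European T1D outpatient population: n = 575
with a 272/303 female/male split; per-sex means and SDs for age (36 ± 13 /
35.6 ± 12.1, truncated to the study range 18–74), diabetes duration
(19.1 ± 10.5 / 18.8 ± 10.9), waist circumference, BMI, HbA1c, blood
pressure, lipids, and eGFR; per-sex prevalences for retinopathy
(15.2% / 22.1%), nephropathy, neuropathy, and previous CVD (3.3% / 4.3%).
Parameters with no published counterpart — smoking 0.25, exercise 0.40,
antihypertensive use 0.18, lipid-lowering use 0.25, LVH 0.03, proteinuria
0.04, albuminuria categories 0.89/0.08/0.03 — are assumptions, listed in the
config's `assumed` field, chosen as typical of contemporary T1D clinic
populations.

Numerical design choices:

* **Moment matching.** Continuous variables are truncated normals, but a
  truncated normal's mean is not its location parameter: with age truncated
  at 18 (only 1.5 SD below the target mean) naive sampling would bias the
  mean upward by about 1.7 years. The generator therefore calibrates each
  location parameter by root-finding on the closed-form truncated-normal
  mean, so the configured mean is the mean of what is actually sampled.
  (The realized SD is slightly below the configured SD under truncation;
  means, not SDs, are the validated targets.)
* **Internal consistency.** Diabetes duration is the sampled variable,
  truncated per patient to \[0, age − 0.5\] with its location calibrated by
  quadrature over the age marginal; onset age is derived as age − duration.
  This makes age = onset + duration hold exactly in every record while both
  age and duration hit their configured marginal means, and it makes
  duration available as a first-class variable for correlation.
* **Triglycerides** are log-normal (their published SD/mean ratio is far
  too large for a normal), parameterized exactly by mean and SD.
* **Correlation** defaults to independent, because no joint structure is
  published. A Gaussian copula is opt-in: all draws pass through a
  latent-uniform layer, so any pair of latent variables (continuous or
  flags; flags occupy the upper tail of their latent) can be given a rank
  correlation. Copula correlations perturb marginals whose truncation
  depends on other variables (duration) slightly; the default validation
  checks marginals under the default independent structure.
* **Emergent quantities.** Hypertension and hypercholesterolemia are
  *derived* flags (blood pressure/medication and LDL/medication), not
  generated ones; with the assumed medication prevalences they land near
  29% and 55% of the cohort. Likewise LDL is derived by Friedewald from
  generated TC/HDL/TG; because those are sampled independently, a small
  number of records (≲ 1%) get implausible (negative) or formula-invalid
  (TG > 400) LDL values, which become missing and flow into the
  missing-data exclusion — a realistic missingness mechanism.

`validate_marginals()` checks every configured mean and prevalence in
standard-error units (pass at |z| ≤ 4).

### What passing synthetic tests does and does not show

The generator reproduces marginal distributions and prevalences, not the
joint distribution of a real clinic population. Structural properties
(partitions, conservation, rule equivalences, engine monotonicity) proven on
synthetic cohorts hold on any input by construction. But quantities that
depend on the joint structure — how many patients fall in each ESC category,
how often the engine confirms a very-high classification — will differ from
any real cohort; the published cross-tabulation counts cannot be regenerated
from simulation, and the package does not try. Arithmetic consistency with
the published tables is instead checked by feeding the printed counts
themselves through the package's tabulation.

## Exclusions, denominators, and reporting

The engine's analysis set excludes, in order of precedence, patients with
previous CVD and then patients missing any engine covariate
(`apply_analysis_exclusions()`; the partition is exhaustive and disjoint and
the run manifest asserts the conservation identity). Category *shares* are
reported on the full classified cohort — previous-CVD patients are
ESC-classifiable — while concordance *tables* use the analyzed set only;
both denominators are explicit fields of the outputs.

Between-sex summaries use the Welch t test by default (the unequal-variance
choice is the robust default when the variant is unspecified; a
pooled-variance option exists) and the uncorrected Pearson chi-square for
categorical variables (Yates optional), standard at these sample sizes.
Degenerate cases are conventions, not crashes: both samples constant and
equal gives p = 1 with a message; a zero margin in a 2×2 table is an error
pointing to exact tests. Display percentages are rounded to one decimal;
full precision is kept internally.

## Reproducibility

Every stochastic step flows from a single integer seed. The same seed and
configuration produce byte-identical cohort CSVs and identical tables;
`run_pipeline()` writes a JSON manifest with the seed, config checksums, and
exclusion counts (its timestamp is the one field that varies between
otherwise identical runs). Default problem sizes keep everything light:
cohorts of 575 for pipeline runs and 10,000 for marginal-recovery checks run
in seconds.

## Worked example

```{r example, eval = FALSE}
library(stenoconcord)
res <- run_pipeline(seed = 1)
res$manifest$counts
res$concordance$at_least_35
validate_marginals(generate_cohort(table1_default_config(n = 10000), seed = 1),
                   table1_default_config(n = 10000))
```

## Known limitations

* The bundled non-degenerate coefficient set is synthetic; concordance
  levels computed with it characterize the pipeline, not the published
  engine.
* No imputation: undecidable ESC categories are `NA`, and missing engine
  covariates exclude a patient rather than being filled in.
* No agreement statistics beyond the cross-tabulation (no kappa), no
  confidence intervals on shares, no competing-risk or 5-year-horizon
  output, and no low-risk or pediatric classes.
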