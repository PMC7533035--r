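Package: stenoconcord
Title: Concordance Between Guideline Cardiovascular Risk Categories and the
    Steno Type 1 Risk Engine in Type 1 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to stratify adults with type 1 diabetes into the 2019
    European Society of Cardiology (ESC) cardiovascular risk categories,
    compute 10-year total cardiovascular risk with a configurable Steno
    Type 1 Risk Engine (ST1RE) implementation, and cross-tabulate the two
    stratifications in age strata. Includes derived clinical measures
    (Friedewald LDL, CKD-EPI eGFR), analysis-set exclusion accounting, a
    seeded synthetic cohort generator with moment-matched truncated-normal
    marginals and optional Gaussian-copula correlation, cohort summary
    statistics, and a reproducible end-to-end pipeline with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
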