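# In-code fixtures: a one-row patient builder and small cohort assembly.

make_patient <- function(...) {
  p <- list(
    patient_id = "P1", sex = "male", age = 30, onset_age = 22,
    diabetes_duration = 8, bmi = 24, waist_circumference = 80,
    sbp = 118, dbp = 73, total_chol = 170, hdl_chol = 50,
    triglycerides = 80, ldl_chol = 90, hba1c = 7.5,
    serum_creatinine = NA_real_, egfr = 100, albuminuria = "normo",
    smoker = FALSE, exercise = FALSE, antihypertensive_use = FALSE,
    lipid_lowering_use = FALSE, retinopathy = FALSE, lvh = FALSE,
    proteinuria = FALSE, nephropathy = FALSE, neuropathy = FALSE,
    previous_cvd = FALSE)
  over <- list(...)
  p[names(over)] <- over
  as.data.frame(p, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$patient_id <- sprintf("P%03d", seq_len(nrow(out)))
  out
}

# Direct transcription of the guideline rule, used as the classification
# oracle: works on explicit flags, independent of derive_risk_profile().
oracle_esc <- function(prev_cvd, tod, n_rf, eold, age, duration) {
  if (prev_cvd || tod || n_rf >= 3 || eold) return("very_high")
  if (age < 35 && duration < 10 && n_rf == 0 && !tod) return("moderate")
  "high"
}

# Textbook Welch statistic/df/p, written from the formulas.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# Textbook Pearson chi-square on a 2x2 table.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - E)^2 / E)
  list(statistic = x2, p_value = pchisq(x2, df = 1, lower.tail = FALSE))
}

# A 575-patient cohort with exactly 22 previous-CVD patients and 21 others
# missing an engine covariate, mirroring the analysis-set accounting.
cohort_575_with_exclusions <- function(seed = 42) {
  cfg <- table1_default_config(n = 575)
  cfg$prevalence$previous_cvd <- 0
  co <- generate_cohort(cfg, seed = seed)
  co <- suppressWarnings(derive_measures(co))  # rare implausible-lipid NAs replanted below
  co$ldl_chol[is.na(co$ldl_chol)] <- 100  # keep missingness fully planted
  co$previous_cvd[1:22] <- TRUE
  co$hba1c[23:43] <- NA
  co
}
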