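test_that("Friedewald LDL matches direct arithmetic and handles invalid inputs", {
  expect_equal(friedewald_ldl(175.6, 56.9, 86.5), 101.4, tolerance = 1e-10)
  expect_equal(friedewald_ldl(100, 50, 0), 50)
  expect_equal(friedewald_ldl(178, 62, 79), 178 - 62 - 15.8)
  expect_warning(out <- friedewald_ldl(200, 50, 450),
                 class = "stenoconcord_formula_invalid")
  expect_true(is.na(out))
  expect_warning(out <- friedewald_ldl(100, 80, 200),
                 class = "stenoconcord_implausible_lipids")
  expect_true(is.na(out))
  expect_error(friedewald_ldl(-1, 50, 80), "positive")
})

test_that("Friedewald is affine: LDL of means equals mean of LDLs", {
  set.seed(11)
  tc <- runif(50, 120, 250); hdl <- runif(50, 30, 70); tg <- runif(50, 40, 300)
  expect_equal(mean(friedewald_ldl(tc, hdl, tg)),
               friedewald_ldl(mean(tc), mean(hdl), mean(tg)))
})

test_that("CKD-EPI eGFR reproduces the published piecewise equation", {
  # at the sex-specific creatinine breakpoint both power terms are 1
  expect_equal(ckd_epi_egfr(0.9, 40, "male"), 141 * 0.993^40)
  expect_equal(ckd_epi_egfr(0.7, 36, "female"), 141 * 0.993^36 * 1.018)
  # independent transcription of the constants, off the breakpoint
  expect_equal(ckd_epi_egfr(0.5, 36, "female"),
               141 * (0.5 / 0.7)^(-0.329) * 0.993^36 * 1.018)
  expect_equal(ckd_epi_egfr(1.4, 60, "male"),
               141 * (1.4 / 0.9)^(-1.209) * 0.993^60)
  # strictly decreasing in creatinine and in age
  scr <- seq(0.4, 3, by = 0.1)
  expect_true(all(diff(ckd_epi_egfr(scr, 40, "male")) < 0))
  expect_true(all(diff(ckd_epi_egfr(1, 20:70, "female")) < 0))
  expect_error(ckd_epi_egfr(0, 40, "male"), "positive")
})

test_that("risk-factor profile agrees with a truth-table oracle at the boundaries", {
  grid <- expand.grid(sbp = c(139, 140), dbp = c(89, 90), ldl = c(100, 101),
                      bmi = c(29.9, 30), smoker = c(FALSE, TRUE),
                      age = c(34, 35, 36), aht = c(FALSE, TRUE),
                      llt = c(FALSE, TRUE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    make_patient(sbp = g$sbp, dbp = g$dbp, ldl_chol = g$ldl, bmi = g$bmi,
                 smoker = g$smoker, age = g$age, onset_age = g$age - 8,
                 antihypertensive_use = g$aht, lipid_lowering_use = g$llt)
  })
  co <- do.call(rbind, rows)
  prof <- derive_risk_profile(co)
  # oracle: direct transcription of the stated definitions
  expect_equal(prof$over_35, grid$age > 35)
  expect_equal(prof$hypertension, grid$sbp >= 140 | grid$dbp >= 90 | grid$aht)
  expect_equal(prof$hypercholesterolemia, grid$ldl > 100 | grid$llt)
  expect_equal(prof$smoking, grid$smoker)
  expect_equal(prof$obesity, grid$bmi >= 30)
  expect_equal(prof$n_major_risk_factors,
               as.integer((grid$age > 35) + (grid$sbp >= 140 | grid$dbp >= 90 | grid$aht) +
                          (grid$ldl > 100 | grid$llt) + grid$smoker + (grid$bmi >= 30)))
})

test_that("organ damage, early onset, and missing-LDL rules behave as defined", {
  co <- make_cohort(
    make_patient(),                                        # nothing
    make_patient(age = 40, sbp = 145, smoker = TRUE, bmi = 31, onset_age = 32),
    make_patient(age = 28, onset_age = 5, diabetes_duration = 23),
    make_patient(retinopathy = TRUE),
    make_patient(egfr = 25),
    make_patient(ldl_chol = NA, lipid_lowering_use = TRUE),
    make_patient(ldl_chol = NA))
  prof <- derive_risk_profile(co)
  expect_equal(prof$n_major_risk_factors[1], 0L)
  expect_false(any(unlist(prof[1, c("target_organ_damage", "early_onset_long_duration")])))
  expect_equal(prof$n_major_risk_factors[2], 4L)
  expect_true(prof$early_onset_long_duration[3])
  expect_true(prof$target_organ_damage[4])
  expect_true(prof$target_organ_damage[5])
  expect_true(prof$hypercholesterolemia[6])   # medication criterion decides
  expect_true(is.na(prof$hypercholesterolemia[7]))
  expect_true(is.na(prof$n_major_risk_factors[7]))
})

test_that("derive_measures fills LDL and eGFR and repairs inconsistent durations", {
  co <- make_cohort(
    make_patient(ldl_chol = NA, total_chol = 178, hdl_chol = 62, triglycerides = 79),
    make_patient(ldl_chol = NA, triglycerides = 450),
    make_patient(ldl_chol = 120, total_chol = 178, hdl_chol = 62, triglycerides = 79),
    make_patient(egfr = NA, serum_creatinine = 0.9, age = 40),
    make_patient(age = 50, onset_age = 20, diabetes_duration = 10))
  out <- derive_measures(co)
  expect_equal(out$ldl_chol[1], 100.2)
  expect_true(is.na(out$ldl_chol[2]))          # formula invalid above 400 mg/dl
  expect_equal(out$ldl_chol[3], 120)           # measured LDL takes precedence
  expect_equal(out$egfr[4], 141 * 0.993^40)
  expect_equal(out$diabetes_duration[5], 30)   # recomputed as age - onset
  expect_match(paste(attr(out, "derivation_log"), collapse = " "), "recomputed")
})

test_that("analysis-set exclusions partition the cohort with CVD precedence", {
  co <- cohort_575_with_exclusions()
  ex <- apply_analysis_exclusions(co)
  expect_equal(unname(ex$counts),
               c(575L, 532L, 22L, 21L))
  # conservation on arbitrary missingness patterns
  set.seed(9)
  co2 <- co
  co2$egfr[sample(575, 40)] <- NA
  ex2 <- apply_analysis_exclusions(co2)
  expect_equal(sum(ex2$counts[-1]), ex2$counts[["input"]])
  expect_equal(nrow(ex2$analyzed) + nrow(ex2$excluded_prev_cvd) +
                 nrow(ex2$excluded_missing), 575)
  # previous CVD takes precedence over missingness
  co3 <- make_cohort(make_patient(previous_cvd = TRUE, hba1c = NA))
  ex3 <- apply_analysis_exclusions(co3)
  expect_equal(nrow(ex3$excluded_prev_cvd), 1)
  expect_equal(nrow(ex3$excluded_missing), 0)
  # empty cohort: three empty sets
  ex0 <- apply_analysis_exclusions(co[0, ])
  expect_equal(unname(ex0$counts), c(0L, 0L, 0L, 0L))
})

test_that("cohort CSV round-trips and parses dialect variants", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "patient_id,sex,age,onset_age,diabetes_duration,triglycerides,ldl_chol,smoker,exercise,previous_cvd,clinic",
    "A1,F,45,20,25,120,95,yes,0,false,north",
    "A2,m,30,22,8,450,,no,1,true,south",
    "A3,female,52,12,40,80,110,0,true,FALSE,north"), f)
  co <- read_cohort(f)
  expect_equal(co$sex, c("female", "male", "female"))
  expect_equal(co$smoker, c(TRUE, FALSE, FALSE))
  expect_equal(co$exercise, c(FALSE, TRUE, TRUE))
  expect_true(is.na(co$ldl_chol[2]))           # empty cell stays missing
  expect_equal(co$clinic, c("north", "south", "north"))  # extras preserved

  # full-precision round trip of a generated cohort
  big <- suppressWarnings(
    derive_measures(generate_cohort(table1_default_config(n = 120), seed = 5)))
  g <- tempfile(fileext = ".csv")
  write_cohort(big, g)
  back <- read_cohort(g)
  for (cn in names(cohort_columns()))
    expect_identical(back[[cn]], big[[cn]], label = cn)

  # schema errors name the offending column / patient
  expect_error(read_cohort(f, schema = c(patient_id = "no_such_column")),
               "patient_id")
  h <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,sex,age", "B1,male,forty"), h)
  expect_error(read_cohort(h), "B1")
})
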