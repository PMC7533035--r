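# Patient-level cohort model: canonical columns, clinical derivations,
# risk-factor flags, analysis-set exclusions, CSV I/O.

#' Canonical cohort columns
#'
#' The cohort is a plain `data.frame`, one row per patient. These are the
#' canonical column names; extra columns are carried through untouched.
#'
#' @return Named character vector mapping column name to storage type
#'   (`"character"`, `"numeric"`, `"logical"`).
#' @export
cohort_columns <- function() {
  c(patient_id = "character", sex = "character",
    age = "numeric", onset_age = "numeric", diabetes_duration = "numeric",
    bmi = "numeric", waist_circumference = "numeric",
    sbp = "numeric", dbp = "numeric",
    total_chol = "numeric", hdl_chol = "numeric", triglycerides = "numeric",
    ldl_chol = "numeric", hba1c = "numeric",
    serum_creatinine = "numeric", egfr = "numeric",
    albuminuria = "character",
    smoker = "logical", exercise = "logical",
    antihypertensive_use = "logical", lipid_lowering_use = "logical",
    retinopathy = "logical", lvh = "logical", proteinuria = "logical",
    nephropathy = "logical", neuropathy = "logical", previous_cvd = "logical")
}

# Covariates the ST1RE engine may use; also the closed world for configs.
st1re_covariates <- function() {
  c("age", "sex", "sbp", "ldl_chol", "egfr", "smoker",
    "diabetes_duration", "hba1c", "albuminuria", "exercise")
}

#' Friedewald estimate of LDL cholesterol
#'
#' LDL = total cholesterol − HDL − triglycerides/5, all in mg/dl. The formula
#' is invalid above 400 mg/dl triglycerides; such inputs yield `NA` with a
#' `"stenoconcord_formula_invalid"` warning. A negative estimate is treated as
#' implausible and also yields `NA` (warning class
#' `"stenoconcord_implausible_lipids"`).
#'
#' @param total_chol,hdl_chol,triglycerides Numeric vectors, mg/dl, recycled.
#' @return Numeric vector of LDL estimates (mg/dl), `NA` where invalid.
#' @examples
#' friedewald_ldl(175.6, 56.9, 86.5)  # 101.4
#' @export
friedewald_ldl <- function(total_chol, hdl_chol, triglycerides) {
  n <- max(length(total_chol), length(hdl_chol), length(triglycerides))
  tc <- rep_len(as.numeric(total_chol), n)
  hdl <- rep_len(as.numeric(hdl_chol), n)
  tg <- rep_len(as.numeric(triglycerides), n)
  bad_in <- !is.na(tc) & !is.na(hdl) & !is.na(tg) & (tc <= 0 | hdl <= 0 | tg < 0)
  if (any(bad_in)) stop("friedewald_ldl: lipid inputs must be positive (triglycerides >= 0)")
  ldl <- tc - hdl - tg / 5
  invalid <- !is.na(tg) & tg > 400
  if (any(invalid)) {
    warning(warningCondition(
      sprintf("Friedewald formula invalid for %d record(s) with triglycerides > 400 mg/dl; LDL set to NA",
              sum(invalid)),
      class = "stenoconcord_formula_invalid"))
    ldl[invalid] <- NA_real_
  }
  implausible <- !is.na(ldl) & ldl < 0
  if (any(implausible)) {
    warning(warningCondition(
      sprintf("Implausible lipid profile for %d record(s): Friedewald LDL negative; set to NA",
              sum(implausible)),
      class = "stenoconcord_implausible_lipids"))
    ldl[implausible] <- NA_real_
  }
  ldl
}

#' CKD-EPI (2009) estimated glomerular filtration rate
#'
#' Serum-creatinine based CKD-EPI equation. The race coefficient is 1 by
#' default (no race term), which suits cohorts where race was not recorded;
#' it is exposed as an argument for other settings.
#'
#' @param serum_creatinine mg/dl, > 0.
#' @param age Years, >= 18.
#' @param sex `"female"` or `"male"` (vector recycled).
#' @param race_coefficient Multiplier applied to the estimate (default 1).
#' @return eGFR in ml/min/1.73 m^2.
#' @export
ckd_epi_egfr <- function(serum_creatinine, age, sex, race_coefficient = 1) {
  n <- max(length(serum_creatinine), length(age), length(sex))
  scr <- rep_len(as.numeric(serum_creatinine), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  if (any(!is.na(scr) & scr <= 0)) stop("ckd_epi_egfr: serum creatinine must be positive")
  if (any(!is.na(age) & age < 18)) stop("ckd_epi_egfr: adult equation requires age >= 18")
  if (!all(is.na(sex) | sex %in% c("female", "male")))
    stop("ckd_epi_egfr: sex must be 'female' or 'male'")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1) * race_coefficient
}

#' Fill in derived clinical measures
#'
#' Completes a cohort in place: missing LDL is derived by [friedewald_ldl()]
#' where triglycerides are at most 400 mg/dl (a measured LDL always takes
#' precedence); missing eGFR is derived from serum creatinine by
#' [ckd_epi_egfr()] (a supplied eGFR takes precedence); and if onset age and
#' diabetes duration disagree with age by more than `duration_tolerance`
#' years, duration is recomputed as `age - onset_age` and the repair is
#' recorded.
#'
#' @param cohort Cohort `data.frame` (see [cohort_columns()]).
#' @param duration_tolerance Years of rounding slack allowed between
#'   `age - onset_age` and `diabetes_duration` (default 1).
#' @return The cohort with derived fields filled; repairs and derivations are
#'   listed in `attr(, "derivation_log")`.
#' @export
derive_measures <- function(cohort, duration_tolerance = 1) {
  log <- character(0)
  need_ldl <- is.na(cohort$ldl_chol) & !is.na(cohort$total_chol) &
    !is.na(cohort$hdl_chol) & !is.na(cohort$triglycerides) &
    cohort$triglycerides <= 400
  if (any(need_ldl)) {
    cohort$ldl_chol[need_ldl] <- friedewald_ldl(
      cohort$total_chol[need_ldl], cohort$hdl_chol[need_ldl],
      cohort$triglycerides[need_ldl])
    log <- c(log, sprintf("ldl_chol derived by Friedewald for %d record(s)", sum(need_ldl)))
  }
  need_gfr <- is.na(cohort$egfr) & !is.na(cohort$serum_creatinine) &
    !is.na(cohort$age) & cohort$age >= 18
  if (any(need_gfr)) {
    cohort$egfr[need_gfr] <- ckd_epi_egfr(
      cohort$serum_creatinine[need_gfr], cohort$age[need_gfr], cohort$sex[need_gfr])
    log <- c(log, sprintf("egfr derived by CKD-EPI for %d record(s)", sum(need_gfr)))
  }
  have_all <- !is.na(cohort$age) & !is.na(cohort$onset_age) & !is.na(cohort$diabetes_duration)
  off <- have_all & abs(cohort$age - cohort$onset_age - cohort$diabetes_duration) > duration_tolerance
  if (any(off)) {
    cohort$diabetes_duration[off] <- cohort$age[off] - cohort$onset_age[off]
    log <- c(log, sprintf(
      "diabetes_duration recomputed as age - onset_age for record(s): %s",
      paste(cohort$patient_id[off], collapse = ", ")))
  }
  attr(cohort, "derivation_log") <- log
  cohort
}

#' Thresholds used by the ESC rule set
#'
#' One configuration block for every threshold of the guideline rules and the
#' fatal-to-total conversion. Defaults: hypertension at SBP >= 140 or
#' DBP >= 90 mmHg or antihypertensive use; hypercholesterolemia at
#' LDL > 100 mg/dl (strict) or lipid-lowering use; obesity at BMI >= 30;
#' the age risk factor at age > 35 (strict); early onset at onset age <= 10
#' with duration > 20 years; organ-damage eGFR bound 30; fatal-risk category
#' edges 10% and 5%; total-risk multipliers 3 (men) and 4 (women).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of thresholds.
#' @export
esc_thresholds <- function(...) {
  th <- list(
    sbp = 140, dbp = 90, ldl = 100, bmi = 30,
    age_risk_factor = 35, egfr_organ_damage = 30,
    early_onset_age = 10, long_duration = 20,
    moderate_age = 35, moderate_duration = 10,
    fatal_very_high = 0.10, fatal_high = 0.05,
    multiplier = c(male = 3, female = 4))
  override <- list(...)
  bad <- setdiff(names(override), names(th))
  if (length(bad)) stop("esc_thresholds: unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(override)] <- override
  th
}

#' Derive the ESC risk-factor profile
#'
#' Evaluates, per patient, the five major cardiovascular risk factors
#' (age > 35 years, hypertension, hypercholesterolemia, smoking, obesity),
#' their count, target organ damage (proteinuria, eGFR < 30, left ventricular
#' hypertrophy, or retinopathy), and early-onset long-duration type 1
#' diabetes. Three-valued logic is used throughout: a flag whose inputs are
#' missing is `NA` unless another input already decides it (e.g. missing LDL
#' with lipid-lowering therapy still gives hypercholesterolemia `TRUE`).
#'
#' @param cohort Cohort `data.frame`, after [derive_measures()].
#' @param thresholds See [esc_thresholds()].
#' @return `data.frame` with columns `patient_id`, the five risk-factor flags,
#'   `n_major_risk_factors` (NA when undecidable), `target_organ_damage`,
#'   `early_onset_long_duration`, plus internal bounds `n_rf_min`, `n_rf_max`.
#' @export
derive_risk_profile <- function(cohort, thresholds = esc_thresholds()) {
  th <- thresholds
  over_35 <- cohort$age > th$age_risk_factor
  hypertension <- (cohort$sbp >= th$sbp) | (cohort$dbp >= th$dbp) |
    (cohort$antihypertensive_use %in% TRUE)
  hyperchol <- (cohort$ldl_chol > th$ldl) | (cohort$lipid_lowering_use %in% TRUE)
  smoking <- cohort$smoker
  obesity <- cohort$bmi >= th$bmi
  flags <- cbind(over_35, hypertension, hyperchol, smoking, obesity)
  n_min <- rowSums(flags, na.rm = TRUE)
  n_na <- rowSums(is.na(flags))
  n_major <- ifelse(n_na == 0, n_min, NA_integer_)
  tod <- (cohort$proteinuria) | (cohort$egfr < th$egfr_organ_damage) |
    (cohort$lvh) | (cohort$retinopathy)
  eold <- (cohort$onset_age <= th$early_onset_age) &
    (cohort$diabetes_duration > th$long_duration)
  data.frame(
    patient_id = cohort$patient_id,
    over_35 = over_35, hypertension = hypertension,
    hypercholesterolemia = hyperchol, smoking = smoking, obesity = obesity,
    n_major_risk_factors = as.integer(n_major),
    target_organ_damage = tod, early_onset_long_duration = eold,
    n_rf_min = as.integer(n_min), n_rf_max = as.integer(n_min + n_na),
    stringsAsFactors = FALSE)
}

#' Partition a cohort into the analysis set and the exclusions
#'
#' Reproduces the analysis-set accounting of the study design: patients with
#' previous cardiovascular disease are excluded first; of the remainder,
#' patients missing any engine covariate are excluded as missing-data; the
#' rest form the analyzed set. The partition is exhaustive and disjoint.
#'
#' @param cohort Cohort `data.frame`, after [derive_measures()].
#' @param required Covariate columns that must be present for the risk engine
#'   (default: the ST1RE covariate set).
#' @return List with `analyzed`, `excluded_prev_cvd`, `excluded_missing`
#'   (cohort subsets) and `counts`, a named integer vector.
#' @export
apply_analysis_exclusions <- function(cohort, required = setdiff(st1re_covariates(), "sex")) {
  if (nrow(cohort) == 0) {
    return(list(analyzed = cohort, excluded_prev_cvd = cohort,
                excluded_missing = cohort,
                counts = c(input = 0L, analyzed = 0L,
                           excluded_prev_cvd = 0L, excluded_missing = 0L)))
  }
  prev <- cohort$previous_cvd %in% TRUE
  miss_any <- Reduce(`|`, lapply(required, function(v) is.na(cohort[[v]])))
  missing <- !prev & (miss_any | is.na(cohort$sex))
  analyzed <- !prev & !missing
  out <- list(analyzed = cohort[analyzed, , drop = FALSE],
              excluded_prev_cvd = cohort[prev, , drop = FALSE],
              excluded_missing = cohort[missing, , drop = FALSE])
  out$counts <- c(input = nrow(cohort), analyzed = sum(analyzed),
                  excluded_prev_cvd = sum(prev), excluded_missing = sum(missing))
  out
}

# --- CSV I/O -----------------------------------------------------------------

parse_boolean <- function(x, column, ids) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "yes", "t", "y")] <- TRUE
  out[s %in% c("0", "false", "no", "f", "n")] <- FALSE
  bad <- !is.na(s) & s != "" & s != "na" & is.na(out)
  if (any(bad))
    stop(sprintf("read_cohort: unparseable boolean in column '%s' for patient(s) %s",
                 column, paste(ids[bad], collapse = ", ")))
  out
}

parse_numeric <- function(x, column, ids) {
  s <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(s))
  bad <- !is.na(s) & s != "" & s != "NA" & is.na(out)
  if (any(bad))
    stop(sprintf("read_cohort: unparseable number in column '%s' for patient(s) %s",
                 column, paste(ids[bad], collapse = ", ")))
  out
}

#' Read a cohort from a delimited text file
#'
#' Comma-separated, UTF-8, header required. `schema` maps canonical column
#' names to the file's column names (defaults to identity for columns that
#' are present). Booleans are accepted as 0/1, true/false, yes/no (any case);
#' sex as female/male or f/m; empty cells become missing values, never zeros.
#' Unknown columns are preserved as opaque extras.
#'
#' @param path File path.
#' @param schema Named character vector, `canonical = file_column`; may be a
#'   path to a YAML/JSON mapping file.
#' @param required Canonical columns that must be mappable (default
#'   `patient_id`, `sex`, `age`).
#' @return Cohort `data.frame` with canonical columns first.
#' @export
read_cohort <- function(path, schema = NULL,
                        required = c("patient_id", "sex", "age")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", na.strings = c("", "NA"))
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    schema <- unlist(read_config_file(schema))
  }
  cols <- cohort_columns()
  mapping <- stats::setNames(names(cols), names(cols))
  if (!is.null(schema)) mapping[names(schema)] <- schema
  miss_req <- required[!(mapping[required] %in% names(raw))]
  if (length(miss_req))
    stop("read_cohort: required column(s) not mappable: ", paste(miss_req, collapse = ", "))
  ids <- if (mapping[["patient_id"]] %in% names(raw)) raw[[mapping[["patient_id"]]]]
         else as.character(seq_len(nrow(raw)))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  used <- character(0)
  for (cn in names(cols)) {
    src <- mapping[[cn]]
    if (src %in% names(raw)) {
      used <- c(used, src)
      v <- raw[[src]]
      out[[cn]] <- switch(cols[[cn]],
        character = as.character(v),
        numeric = parse_numeric(v, cn, ids),
        logical = parse_boolean(v, cn, ids))
    } else {
      out[[cn]] <- switch(cols[[cn]],
        character = rep(NA_character_, nrow(raw)),
        numeric = rep(NA_real_, nrow(raw)),
        logical = rep(NA, nrow(raw)))
    }
  }
  out$sex <- tolower(out$sex)
  out$sex[out$sex %in% "f"] <- "female"
  out$sex[out$sex %in% "m"] <- "male"
  bad_sex <- !is.na(out$sex) & !(out$sex %in% c("female", "male"))
  if (any(bad_sex))
    stop("read_cohort: unparseable sex for patient(s) ",
         paste(ids[bad_sex], collapse = ", "))
  if (!all(is.na(out$albuminuria)))
    out$albuminuria <- tolower(out$albuminuria)
  bad_alb <- !is.na(out$albuminuria) & !(out$albuminuria %in% c("normo", "micro", "macro"))
  if (any(bad_alb))
    stop("read_cohort: albuminuria must be one of normo/micro/macro; bad patient(s) ",
         paste(ids[bad_alb], collapse = ", "))
  extras <- setdiff(names(raw), used)
  for (e in extras) out[[e]] <- raw[[e]]
  out
}

#' Write a cohort to CSV
#'
#' Canonical columns first (in canonical order), extras after. Logicals are
#' written as `true`/`false`, missing values as empty cells, and numerics with
#' full precision so that `write_cohort()` then [read_cohort()] round-trips
#' exactly.
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  canon <- intersect(names(cohort_columns()), names(cohort))
  extras <- setdiff(names(cohort), canon)
  df <- cohort[, c(canon, extras), drop = FALSE]
  fmt <- lapply(df, function(col) {
    if (is.logical(col)) ifelse(is.na(col), "", ifelse(col, "true", "false"))
    else if (is.numeric(col)) ifelse(is.na(col), "", sprintf("%.17g", col))
    else ifelse(is.na(col), "", as.character(col))
  })
  mat <- do.call(cbind, fmt)
  con <- file(path, open = "wb")  # binary: fixed \n line endings for determinism
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0) writeLines(apply(mat, 1, paste, collapse = ","), con)
  invisible(path)
}

# Read a YAML or JSON config file by extension (YAML parser accepts JSON too).
read_config_file <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
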