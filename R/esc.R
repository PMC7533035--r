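# 2019 ESC three-category CVD risk classification for type 1 diabetes,
# very-high-risk subcategory decomposition, fatal-to-total conversion.

esc_categories <- function() c("very_high", "high", "moderate")
vh_subcategories <- function() {
  c("previous_cvd", "organ_damage_only", "multi_risk_factor_only",
    "early_onset_long_duration_only", "two_or_more", "not_applicable")
}

#' Classify patients into the 2019 ESC risk categories
#'
#' Very high risk: previous cardiovascular disease, or target organ damage,
#' or three or more of the five major risk factors, or early-onset type 1
#' diabetes of long duration (> 20 years). Moderate risk: age < 35 years with
#' diabetes duration < 10 years and no risk factor and no organ damage. High
#' risk: everyone else. There is no low-risk class. Missing inputs propagate
#' with three-valued logic: a category is assigned only when the rules decide
#' it; otherwise `NA`.
#'
#' @param cohort Cohort `data.frame`.
#' @param profile Output of [derive_risk_profile()] for the same rows.
#' @param thresholds See [esc_thresholds()].
#' @return Factor with levels `very_high`, `high`, `moderate`.
#' @export
classify_esc <- function(cohort, profile, thresholds = esc_thresholds()) {
  stopifnot(nrow(cohort) == nrow(profile))
  th <- thresholds
  nge3 <- ifelse(profile$n_rf_min >= 3, TRUE,
                 ifelse(profile$n_rf_max < 3, FALSE, NA))
  n0 <- ifelse(profile$n_rf_min > 0, FALSE,
               ifelse(profile$n_rf_max == 0, TRUE, NA))
  vh <- (cohort$previous_cvd) | (profile$target_organ_damage) | nge3 |
    (profile$early_onset_long_duration)
  mod <- (!vh) & (cohort$age < th$moderate_age) &
    (cohort$diabetes_duration < th$moderate_duration) &
    n0 & (!profile$target_organ_damage)
  cat <- ifelse(is.na(vh), NA_character_,
         ifelse(vh, "very_high",
         ifelse(is.na(mod), NA_character_,
         ifelse(mod, "moderate", "high"))))
  factor(cat, levels = esc_categories())
}

#' Decompose the very-high-risk category into mutually exclusive subcategories
#'
#' Previous cardiovascular disease dominates. Otherwise, among target organ
#' damage, three-or-more risk factors, and early-onset long-duration T1D:
#' exactly one criterion gives the corresponding `_only` subcategory, two or
#' three give `two_or_more`. Patients not classified very high get
#' `not_applicable`.
#'
#' @inheritParams classify_esc
#' @param esc Optional precomputed [classify_esc()] factor; computed if `NULL`.
#' @return Factor with the subcategory levels.
#' @export
very_high_subcategory <- function(cohort, profile, esc = NULL,
                                  thresholds = esc_thresholds()) {
  if (is.null(esc)) esc <- classify_esc(cohort, profile, thresholds)
  stopifnot(nrow(cohort) == nrow(profile), length(esc) == nrow(cohort))
  is_vh <- esc %in% "very_high"
  crit <- cbind(
    organ = profile$target_organ_damage %in% TRUE,
    multi = profile$n_rf_min >= 3,
    early = profile$early_onset_long_duration %in% TRUE)
  k <- rowSums(crit)
  sub <- rep("not_applicable", nrow(cohort))
  sub[is_vh & cohort$previous_cvd %in% TRUE] <- "previous_cvd"
  plain <- is_vh & !(cohort$previous_cvd %in% TRUE)
  sub[plain & k >= 2] <- "two_or_more"
  sub[plain & k == 1 & crit[, "organ"]] <- "organ_damage_only"
  sub[plain & k == 1 & crit[, "multi"]] <- "multi_risk_factor_only"
  sub[plain & k == 1 & crit[, "early"]] <- "early_onset_long_duration_only"
  if (any(plain & k == 0))
    stop("very_high_subcategory: very-high patient satisfies no criterion; inconsistent profile")
  sub[is.na(esc)] <- NA_character_
  factor(sub, levels = vh_subcategories())
}

#' Convert fatal CVD risk to total (fatal + non-fatal) CVD risk
#'
#' Multiplies the 10-year fatal risk by 3 in men and 4 in women, capping the
#' product at 1.
#'
#' @param fatal_risk Probability in \[0, 1\].
#' @param sex `"female"` or `"male"`.
#' @param multiplier Named numeric, per-sex multipliers.
#' @return Total-risk probability.
#' @export
fatal_to_total <- function(fatal_risk, sex,
                           multiplier = esc_thresholds()$multiplier) {
  n <- max(length(fatal_risk), length(sex))
  f <- rep_len(as.numeric(fatal_risk), n)
  sex <- rep_len(as.character(sex), n)
  if (any(!is.na(f) & (f < 0 | f > 1)))
    stop("fatal_to_total: fatal_risk must lie in [0, 1]")
  if (!all(is.na(sex) | sex %in% names(multiplier)))
    stop("fatal_to_total: sex must be one of ", paste(names(multiplier), collapse = "/"))
  pmin(1, f * unname(multiplier[sex]))
}

#' Total-risk band of an ESC category
#'
#' The fatal-risk bands (very high >= 10%, high 5-9%, moderate 3-4%) are
#' implemented as contiguous half-open intervals \[0.10, 1\], \[0.05, 0.10),
#' \[0, 0.05) on the fatal scale so every probability maps to exactly one
#' category, then mapped through [fatal_to_total()] for the requested sex.
#'
#' @param category `"very_high"`, `"high"` or `"moderate"`.
#' @param sex `"female"` or `"male"`.
#' @param thresholds See [esc_thresholds()].
#' @return List with `lower`, `upper`, and `upper_closed` (the very-high band
#'   is closed at 1; the others are right-open).
#' @export
esc_category_total_bounds <- function(category, sex, thresholds = esc_thresholds()) {
  category <- match.arg(category, esc_categories())
  th <- thresholds
  fatal <- switch(category,
    very_high = c(th$fatal_very_high, 1),
    high = c(th$fatal_high, th$fatal_very_high),
    moderate = c(0, th$fatal_high))
  tot <- fatal_to_total(fatal, c(sex, sex), th$multiplier)
  list(lower = tot[[1]], upper = tot[[2]], upper_closed = category == "very_high")
}
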