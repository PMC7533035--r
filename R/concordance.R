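# Age-stratified ESC x ST1RE concordance tables, category shares, and the
# cohort summary with between-sex tests.

strata_names <- function() c("all", "under_35", "at_least_35", "at_least_50")

stratum_filter <- function(age, stratum) {
  stratum <- match.arg(stratum, strata_names())
  switch(stratum,
    all = rep(TRUE, length(age)),
    under_35 = age < 35,
    at_least_35 = age >= 35,
    at_least_50 = age >= 50)
}

row_percentages <- function(counts, digits = 1) {
  n <- sum(counts)
  if (n == 0) return(rep(0, length(counts)))
  round(100 * counts / n, digits)
}

#' Cross-tabulate ESC categories against ST1RE risk bins
#'
#' Builds the concordance table for one age stratum: one row per ESC category
#' (with the very-high subcategory rows nested under the very-high row when
#' `subcategory` is supplied), one column per ST1RE bin, each cell a count
#' and a row percentage (rounded to one decimal for display; counts are
#' exact). Only pass patients that survived [apply_analysis_exclusions()]:
#' a missing prediction or label is a hard error.
#'
#' @param cohort Analyzed cohort `data.frame` (supplies `age`).
#' @param esc [classify_esc()] factor for the same rows.
#' @param bins [bin_risk()] factor for the same rows.
#' @param subcategory Optional [very_high_subcategory()] factor; adds the
#'   nested subcategory rows.
#' @param stratum `"all"`, `"under_35"`, `"at_least_35"`, or `"at_least_50"`.
#' @return `data.frame` of class `concordance_table` with columns `stratum`,
#'   `row`, `row_type`, `st1re_bin`, `count`, `pct`, `row_n`; attributes
#'   `stratum` and `n` (analyzed patients in the stratum).
#' @export
build_concordance <- function(cohort, esc, bins, subcategory = NULL,
                              stratum = "all") {
  stratum <- match.arg(stratum, strata_names())
  stopifnot(length(esc) == nrow(cohort), length(bins) == nrow(cohort))
  if (any(is.na(esc)))
    stop("build_concordance: unlabeled patient(s): ",
         paste(utils::head(cohort$patient_id[is.na(esc)], 5), collapse = ", "))
  if (any(is.na(bins)))
    stop("build_concordance: patient(s) without a prediction: ",
         paste(utils::head(cohort$patient_id[is.na(bins)], 5), collapse = ", "),
         " (apply exclusions upstream)")
  keep <- stratum_filter(cohort$age, stratum)
  esc <- factor(esc[keep], levels = esc_categories())
  bins <- factor(bins[keep], levels = esc_categories())
  rows <- list()
  add_row <- function(label, type, sel) {
    tab <- table(factor(bins[sel], levels = esc_categories()))
    counts <- as.integer(tab)
    rows[[length(rows) + 1]] <<- data.frame(
      stratum = stratum, row = label, row_type = type,
      st1re_bin = esc_categories(), count = counts,
      pct = row_percentages(counts), row_n = sum(sel),
      stringsAsFactors = FALSE)
  }
  for (cat in esc_categories()) {
    add_row(cat, "category", esc %in% cat)
    if (cat == "very_high" && !is.null(subcategory)) {
      sub <- factor(subcategory[keep], levels = vh_subcategories())
      for (s in setdiff(vh_subcategories(), c("previous_cvd", "not_applicable")))
        add_row(s, "subcategory", esc %in% cat & sub %in% s)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, stratum = stratum, n = sum(keep),
            class = c("concordance_table", "data.frame"))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("ESC x ST1RE concordance, stratum '%s' (n = %d analyzed)\n",
              attr(x, "stratum"), attr(x, "n")))
  labs <- unique(x$row)
  wide <- sapply(esc_categories(), function(b) {
    i <- match(paste(labs, b), paste(x$row, x$st1re_bin))
    sprintf("%d (%.1f)", x$count[i], x$pct[i])
  })
  if (is.null(dim(wide))) wide <- matrix(wide, nrow = 1)
  types <- x$row_type[match(labs, x$row)]
  df <- data.frame(`ESC row` = ifelse(types == "subcategory", paste0("  ", labs), labs),
                   n = x$row_n[match(labs, x$row)], wide, check.names = FALSE)
  colnames(df)[3:5] <- paste0("ST1RE ", c("very high", "high", "moderate"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' ESC category shares within an age stratum
#'
#' Percentage of patients in each ESC category, on the stratum's full
#' denominator (patients with previous cardiovascular disease are included:
#' they are ESC-classifiable even though the risk engine excludes them).
#' Patients with an undecidable (`NA`) category are dropped with a warning
#' and the denominator reported in attribute `n`.
#'
#' @param cohort Cohort `data.frame`.
#' @param esc [classify_esc()] factor.
#' @param stratum See [build_concordance()].
#' @param digits Rounding for the display percentage (default 1).
#' @return `data.frame` with `category`, `count`, `pct`; attributes `stratum`
#'   and `n`. Empty stratum gives zero counts and zero percentages.
#' @export
category_shares <- function(cohort, esc, stratum = "all", digits = 1) {
  stratum <- match.arg(stratum, strata_names())
  stopifnot(length(esc) == nrow(cohort))
  keep <- stratum_filter(cohort$age, stratum)
  esc <- esc[keep]
  if (anyNA(esc)) {
    warning(sprintf("category_shares: dropping %d patient(s) with undecidable category",
                    sum(is.na(esc))))
    esc <- esc[!is.na(esc)]
  }
  counts <- as.integer(table(factor(esc, levels = esc_categories())))
  out <- data.frame(category = esc_categories(), count = counts,
                    pct = row_percentages(counts, digits),
                    stringsAsFactors = FALSE)
  structure(out, stratum = stratum, n = length(esc))
}

#' Welch two-sample t test
#'
#' Unequal-variance (Welch) t test with the Welch-Satterthwaite degrees of
#' freedom, two-sided. If both samples are constant with equal means the
#' statistic is 0 and p = 1 by convention (with a message); a pooled-variance
#' Student test is available via `var_equal = TRUE`.
#'
#' @param xs,ys Numeric samples, each of size >= 2, finite.
#' @param var_equal Use the pooled-variance Student test instead.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(xs, ys, var_equal = FALSE) {
  xs <- as.numeric(xs); ys <- as.numeric(ys)
  if (length(xs) < 2 || length(ys) < 2 || !all(is.finite(c(xs, ys))))
    stop("welch_t_test: each sample needs >= 2 finite values")
  if (stats::var(xs) == 0 && stats::var(ys) == 0) {
    if (mean(xs) == mean(ys)) {
      message("welch_t_test: both samples constant and equal; p = 1 by convention")
      return(list(statistic = 0, df = length(xs) + length(ys) - 2, p_value = 1))
    }
    stop("welch_t_test: both samples constant with different means; t undefined")
  }
  tt <- stats::t.test(xs, ys, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square (1 df, two-sided) by default; Yates
#' continuity correction available via `correct = TRUE`. A zero margin is an
#' error (an exact test would be needed there).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param correct Apply the Yates correction.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("chi_square_test: need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("chi_square_test: counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi_square_test: zero margin; use an exact test for such tables")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Between-sex cohort summary
#'
#' For each continuous variable: overall, female, and male mean and sample SD
#' (n-1 denominator) with the Welch t-test p-value. For each binary variable:
#' prevalences in percent with the uncorrected Pearson chi-square p-value
#' (NA, with a note, where a margin is zero). Variables entirely missing are
#' omitted with a warning.
#'
#' @param cohort Cohort `data.frame`; both sexes must be present.
#' @param continuous,binary Character vectors of column names to summarize.
#' @return `data.frame`, one row per variable: `variable`, `type`, `n`,
#'   `overall`, `female`, `male` (means or percentages), `overall_sd`,
#'   `female_sd`, `male_sd` (continuous only), `p_value`.
#' @export
summarize_cohort <- function(cohort,
                             continuous = c("age", "diabetes_duration", "onset_age",
                                            "waist_circumference", "bmi", "hba1c",
                                            "sbp", "dbp", "total_chol", "ldl_chol",
                                            "hdl_chol", "triglycerides", "egfr"),
                             binary = c("smoker", "exercise", "antihypertensive_use",
                                        "lipid_lowering_use", "retinopathy",
                                        "nephropathy", "neuropathy", "lvh",
                                        "proteinuria", "previous_cvd")) {
  if (nrow(cohort) == 0) stop("summarize_cohort: empty cohort")
  f <- cohort$sex %in% "female"
  m <- cohort$sex %in% "male"
  if (!any(f) || !any(m)) stop("summarize_cohort: both sexes must be present")
  rows <- list()
  for (v in intersect(continuous, names(cohort))) {
    x <- cohort[[v]]
    if (all(is.na(x))) { warning("summarize_cohort: '", v, "' entirely missing; omitted"); next }
    xf <- x[f & !is.na(x)]; xm <- x[m & !is.na(x)]
    p <- if (length(xf) >= 2 && length(xm) >= 2 &&
             (stats::var(xf) > 0 || stats::var(xm) > 0))
      welch_t_test(xf, xm)$p_value else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, type = "continuous", n = sum(!is.na(x)),
      overall = mean(x, na.rm = TRUE), female = mean(xf), male = mean(xm),
      overall_sd = stats::sd(x, na.rm = TRUE),
      female_sd = stats::sd(xf), male_sd = stats::sd(xm),
      p_value = p, stringsAsFactors = FALSE)
  }
  for (v in intersect(binary, names(cohort))) {
    x <- cohort[[v]]
    if (all(is.na(x))) { warning("summarize_cohort: '", v, "' entirely missing; omitted"); next }
    xf <- x[f & !is.na(x)]; xm <- x[m & !is.na(x)]
    tab <- rbind(c(sum(xf), sum(!xf)), c(sum(xm), sum(!xm)))
    p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      chi_square_test(tab)$p_value else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, type = "binary", n = sum(!is.na(x)),
      overall = 100 * mean(x, na.rm = TRUE),
      female = 100 * mean(xf), male = 100 * mean(xm),
      overall_sd = NA_real_, female_sd = NA_real_, male_sd = NA_real_,
      p_value = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
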