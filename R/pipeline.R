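# End-to-end orchestration: simulate or load -> derive -> classify -> predict
# -> concordance/summary -> manifest (+ optional file outputs).

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full concordance pipeline
#'
#' Obtains a cohort (from a CSV path, a cohort `data.frame`, or by simulation
#' from `synthetic_config`), fills derived measures, derives risk-factor
#' profiles, applies the ESC classification with very-high subcategories,
#' applies the analysis-set exclusions, predicts and bins 10-year risk with
#' the configured engine for the analyzed patients, and assembles the
#' age-stratified concordance tables, category shares, between-sex summary,
#' and a run manifest. Re-running with identical inputs and seed reproduces
#' identical data outputs (the manifest timestamp excepted).
#'
#' @param cohort Cohort `data.frame` or path to a cohort CSV; `NULL` to
#'   simulate.
#' @param synthetic_config [table1_default_config()]-style config used when
#'   `cohort` is `NULL`.
#' @param seed Seed for simulation (ignored for file/data-frame cohorts).
#' @param st1re [st1re_config()] object or path to one.
#' @param scheme [binning_scheme()] object or scheme name.
#' @param thresholds [esc_thresholds()].
#' @param out_dir If non-`NULL`, outputs are written there: the cohort CSV
#'   with appended classification/prediction columns, a long-format
#'   concordance CSV, category-share and summary CSVs, a JSON manifest, and a
#'   markdown report.
#' @return List with `cohort` (augmented), `exclusions`, `concordance` (one
#'   [build_concordance()] table per stratum), `shares` (per stratum),
#'   `summary`, `manifest`.
#' @export
run_pipeline <- function(cohort = NULL,
                         synthetic_config = table1_default_config(),
                         seed = synthetic_config$seed,
                         st1re = system.file("extdata", "st1re-synthetic.yaml",
                                             package = "stenoconcord"),
                         scheme = "esc-converted",
                         thresholds = esc_thresholds(),
                         out_dir = NULL) {
  if (is.character(st1re)) st1re <- load_st1re_config(st1re)
  if (is.character(scheme)) scheme <- binning_scheme(scheme)
  simulated <- is.null(cohort)
  if (simulated) {
    cohort <- generate_cohort(synthetic_config, seed = seed)
  } else if (is.character(cohort)) {
    cohort <- read_cohort(cohort)
  }
  cohort <- derive_measures(cohort)
  profile <- derive_risk_profile(cohort, thresholds)
  esc <- classify_esc(cohort, profile, thresholds)
  subcat <- very_high_subcategory(cohort, profile, esc, thresholds)
  cohort$esc_category <- as.character(esc)
  cohort$esc_subcategory <- as.character(subcat)

  excl <- apply_analysis_exclusions(cohort)
  analyzed <- excl$analyzed
  pred <- st1re_predict(analyzed, st1re, scheme)
  analyzed$linear_predictor <- pred$linear_predictor
  analyzed$risk_10yr <- pred$risk_10yr
  analyzed$st1re_bin <- as.character(pred$st1re_bin)

  a_esc <- factor(analyzed$esc_category, levels = esc_categories())
  a_sub <- factor(analyzed$esc_subcategory, levels = vh_subcategories())
  a_bin <- factor(analyzed$st1re_bin, levels = esc_categories())
  conc <- lapply(stats::setNames(nm = strata_names()), function(s)
    build_concordance(analyzed, a_esc, a_bin, a_sub, stratum = s))
  shares <- lapply(stats::setNames(nm = strata_names()), function(s)
    category_shares(cohort, esc, stratum = s))
  summary_tab <- summarize_cohort(cohort)

  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (simulated) seed else NULL,
    cohort_source = if (simulated) "simulated" else "supplied",
    binning_scheme = scheme$name,
    st1re_provenance = st1re$provenance,
    config_md5 = list(
      st1re = md5_of_object(unclass(st1re)),
      binning = md5_of_object(unclass(scheme)),
      synthetic = if (simulated) md5_of_object(unclass(synthetic_config)) else NULL,
      thresholds = md5_of_object(thresholds)),
    counts = as.list(excl$counts),
    outputs = list())
  stopifnot(manifest$counts$input ==
              manifest$counts$analyzed + manifest$counts$excluded_prev_cvd +
              manifest$counts$excluded_missing)

  result <- list(cohort = cohort, analyzed = analyzed, exclusions = excl,
                 concordance = conc, shares = shares, summary = summary_tab,
                 manifest = manifest)
  if (!is.null(out_dir)) result <- write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    analyzed = file.path(out_dir, "analyzed.csv"),
    concordance = file.path(out_dir, "concordance.csv"),
    shares = file.path(out_dir, "category_shares.csv"),
    summary = file.path(out_dir, "cohort_summary.csv"),
    manifest = file.path(out_dir, "manifest.json"),
    report = file.path(out_dir, "report.md"))
  write_cohort(result$cohort, paths$cohort)
  write_cohort(result$analyzed, paths$analyzed)
  conc_long <- do.call(rbind, lapply(result$concordance, as.data.frame))
  utils::write.csv(conc_long, paths$concordance, row.names = FALSE)
  shares_long <- do.call(rbind, lapply(names(result$shares), function(s)
    cbind(stratum = s, n = attr(result$shares[[s]], "n"),
          as.data.frame(result$shares[[s]]))))
  utils::write.csv(shares_long, paths$shares, row.names = FALSE)
  utils::write.csv(result$summary, paths$summary, row.names = FALSE)
  result$manifest$outputs <- paths
  jsonlite::write_json(result$manifest, paths$manifest,
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  writeLines(render_report(result), paths$report)
  result
}

render_report <- function(result) {
  cnt <- result$manifest$counts
  lines <- c(
    "# ESC risk classification vs ST1RE 10-year risk prediction",
    "",
    sprintf("Cohort: %d patients (%d analyzed; %d excluded for previous CVD, %d for missing data).",
            cnt$input, cnt$analyzed, cnt$excluded_prev_cvd, cnt$excluded_missing),
    sprintf("Risk engine form: configurable ST1RE; binning scheme: %s.",
            result$manifest$binning_scheme),
    "", "## ESC category shares (all classified patients)", "")
  for (s in names(result$shares)) {
    sh <- result$shares[[s]]
    lines <- c(lines, sprintf("- %s (n = %d): very high %.1f%%, high %.1f%%, moderate %.1f%%",
                              s, attr(sh, "n"), sh$pct[1], sh$pct[2], sh$pct[3]))
  }
  lines <- c(lines, "", "## Concordance tables (analyzed patients)", "")
  for (s in names(result$concordance)) {
    tab <- result$concordance[[s]]
    lines <- c(lines, sprintf("### Stratum: %s (n = %d)", s, attr(tab, "n")), "",
               "| ESC row | n | ST1RE very high | ST1RE high | ST1RE moderate |",
               "|---|---|---|---|---|")
    for (lab in unique(tab$row)) {
      r <- tab[tab$row == lab, ]
      ind <- if (r$row_type[1] == "subcategory") "&nbsp;&nbsp;" else ""
      lines <- c(lines, sprintf("| %s%s | %d | %d (%.1f) | %d (%.1f) | %d (%.1f) |",
                                ind, lab, r$row_n[1],
                                r$count[1], r$pct[1], r$count[2], r$pct[2],
                                r$count[3], r$pct[3]))
    }
    lines <- c(lines, "")
  }
  lines
}
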