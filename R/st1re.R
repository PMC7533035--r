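# Configurable Steno Type 1 Risk Engine: linear predictor, three supported
# link forms, per-sex risk binning, config (de)serialization.

st1re_forms <- function() c("complementary-log-log", "cox-baseline-survival", "logistic")
st1re_transforms <- function() c("identity", "log", "indicator")

#' Build an ST1RE configuration
#'
#' The engine is fully configuration-driven: a functional form, a baseline
#' parameter (intercept, or baseline survival for the Cox form), an ordered
#' list of terms, and a horizon. Covariate names are restricted to the engine
#' covariate set (age, sex, SBP, LDL cholesterol, eGFR, smoking, diabetes
#' duration, HbA1c, albuminuria, physical exercise). Each term is a list with
#' `covariate`, `transform` (`identity`, `log`, or `indicator`), `coefficient`
#' and, for indicator terms, `level` (e.g. albuminuria `"micro"`, sex
#' `"male"`).
#'
#' @param form One of `"complementary-log-log"`, `"cox-baseline-survival"`,
#'   `"logistic"`.
#' @param baseline_param Intercept on the linear-predictor scale, or baseline
#'   survival in (0, 1) for the Cox form.
#' @param terms List of term lists (see above).
#' @param horizon Prediction horizon in years (default 10).
#' @param provenance Free-text citation for the coefficient source. A missing
#'   provenance draws a warning: coefficient sets must be traceable.
#' @return Object of class `st1re_config`.
#' @export
st1re_config <- function(form, baseline_param, terms, horizon = 10,
                         provenance = NULL) {
  form <- match.arg(form, st1re_forms())
  if (!is.numeric(baseline_param) || length(baseline_param) != 1 || !is.finite(baseline_param))
    stop("st1re_config: baseline_param must be a single finite number")
  if (form == "cox-baseline-survival" && (baseline_param <= 0 || baseline_param >= 1))
    stop("st1re_config: baseline survival must lie in (0, 1)")
  if (is.data.frame(terms))  # e.g. JSON deserialization simplifies to a frame
    terms <- lapply(seq_len(nrow(terms)), function(i) {
      t <- as.list(terms[i, , drop = FALSE])
      t[!vapply(t, function(v) is.na(v) || is.null(v), logical(1))]
    })
  terms <- lapply(terms, function(t) {
    t <- as.list(t)
    if (is.null(t$covariate) || is.null(t$transform) || is.null(t$coefficient))
      stop("st1re_config: each term needs covariate, transform, coefficient")
    if (!(t$covariate %in% st1re_covariates()))
      stop("st1re_config: unknown covariate '", t$covariate, "'")
    t$transform <- match.arg(t$transform, st1re_transforms())
    if (!is.finite(t$coefficient)) stop("st1re_config: coefficients must be finite")
    if (t$transform == "indicator" && is.null(t$level))
      stop("st1re_config: indicator term for '", t$covariate, "' needs a level")
    t[c("covariate", "transform", "coefficient",
        if (t$transform == "indicator") "level")]
  })
  if (!is.numeric(horizon) || horizon <= 0) stop("st1re_config: horizon must be positive")
  if (is.null(provenance)) {
    warning("st1re_config: no provenance recorded for the coefficient set")
    provenance <- ""
  }
  structure(list(form = form, baseline_param = baseline_param, terms = terms,
                 horizon = horizon, provenance = provenance),
            class = "st1re_config")
}

#' @export
print.st1re_config <- function(x, ...) {
  cat(sprintf("ST1RE configuration: %s form, %d-year horizon, %d term(s)\n",
              x$form, x$horizon, length(x$terms)))
  cat(sprintf("  baseline parameter: %g\n", x$baseline_param))
  for (t in x$terms)
    cat(sprintf("  %-18s %-9s %+g%s\n", t$covariate, t$transform, t$coefficient,
                if (!is.null(t$level)) paste0(" [", t$level, "]") else ""))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

term_value <- function(cohort, term) {
  x <- cohort[[term$covariate]]
  switch(term$transform,
    identity = if (is.logical(x)) as.numeric(x) else as.numeric(x),
    log = {
      v <- as.numeric(x)
      if (any(!is.na(v) & v <= 0))
        stop("st1re_linear_predictor: log transform of nonpositive '", term$covariate, "'")
      log(v)
    },
    indicator = as.numeric(as.character(x) == term$level))
}

#' ST1RE linear predictor
#'
#' Sum over configured terms of coefficient times transformed covariate.
#' Missing covariates raise an error naming the covariate and the offending
#' patients; apply [apply_analysis_exclusions()] upstream.
#'
#' @param cohort Cohort `data.frame` (after [derive_measures()]).
#' @param config [st1re_config()] object.
#' @return Numeric vector of linear predictors.
#' @export
st1re_linear_predictor <- function(cohort, config) {
  stopifnot(inherits(config, "st1re_config"))
  lp <- rep(0, nrow(cohort))
  for (term in config$terms) {
    v <- term_value(cohort, term)
    if (any(is.na(v))) {
      bad <- cohort$patient_id[is.na(v)]
      stop(sprintf("insufficient-data: covariate '%s' missing for patient(s) %s",
                   term$covariate, paste(utils::head(bad, 5), collapse = ", ")))
    }
    lp <- lp + term$coefficient * v
  }
  lp
}

risk_from_lp <- function(lp, config) {
  r <- switch(config$form,
    `complementary-log-log` = 1 - exp(-exp(lp + config$baseline_param)),
    `cox-baseline-survival` = 1 - config$baseline_param^exp(lp),
    logistic = stats::plogis(lp + config$baseline_param))
  pmin(1, pmax(0, r))
}

#' Predict 10-year total CVD risk with the configured engine
#'
#' Risk is `1 - exp(-exp(lp + b))` for the complementary-log-log form,
#' `1 - S0^exp(lp)` for the Cox baseline-survival form, and `plogis(lp + b)`
#' for the logistic form; always in \[0, 1\] and strictly increasing in the
#' linear predictor.
#'
#' @inheritParams st1re_linear_predictor
#' @param scheme Optional [binning_scheme()]; when supplied, the predictions
#'   are also binned.
#' @return `data.frame` with `patient_id`, `linear_predictor`, `risk_10yr`,
#'   and (if `scheme` given) `st1re_bin`.
#' @export
st1re_predict <- function(cohort, config, scheme = NULL) {
  lp <- st1re_linear_predictor(cohort, config)
  out <- data.frame(patient_id = cohort$patient_id,
                    linear_predictor = lp,
                    risk_10yr = risk_from_lp(lp, config),
                    stringsAsFactors = FALSE)
  if (!is.null(scheme))
    out$st1re_bin <- bin_risk(out$risk_10yr, cohort$sex, scheme)
  out
}

#' Risk binning schemes
#'
#' Per-sex cutpoints mapping predicted total 10-year risk to the three bins.
#' `"esc-converted"` (default elsewhere) converts the ESC fatal-risk category
#' edges (10%, 5%) to the total-risk scale with the times-3 (men) / times-4
#' (women) rule: very high at >= 0.30 / 0.40, high at >= 0.15 / 0.20.
#' `"uniform-10-20"` uses >= 0.20 very high and >= 0.10 high for both sexes.
#' Lower bounds are inclusive.
#'
#' @param name `"esc-converted"` or `"uniform-10-20"`, or supply `male` and
#'   `female` cut pairs directly for a custom scheme.
#' @param male,female Numeric `c(high_cut, very_high_cut)` overriding the
#'   named defaults.
#' @return Object of class `risk_binning_scheme`.
#' @export
binning_scheme <- function(name = c("esc-converted", "uniform-10-20"),
                           male = NULL, female = NULL) {
  if (is.null(male) || is.null(female)) {
    name <- match.arg(name)
    if (name == "esc-converted") {
      male <- c(high = 0.15, very_high = 0.30)
      female <- c(high = 0.20, very_high = 0.40)
    } else {
      male <- female <- c(high = 0.10, very_high = 0.20)
    }
  } else {
    name <- if (is.character(name)) name[[1]] else "custom"
    male <- stats::setNames(as.numeric(male), c("high", "very_high"))
    female <- stats::setNames(as.numeric(female), c("high", "very_high"))
  }
  for (cuts in list(male, female))
    if (!(0 < cuts[["high"]] && cuts[["high"]] < cuts[["very_high"]] &&
          cuts[["very_high"]] <= 1))
      stop("binning_scheme: need 0 < high_cut < very_high_cut <= 1")
  structure(list(name = name, male = male, female = female),
            class = "risk_binning_scheme")
}

#' Bin a predicted risk into very-high / high / moderate
#'
#' Very high at or above the sex's very-high cut; high at or above the high
#' cut; moderate below. Boundaries are inclusive at the lower edge of each
#' bin.
#'
#' @param risk Probability vector in \[0, 1\].
#' @param sex `"female"`/`"male"` vector.
#' @param scheme A [binning_scheme()].
#' @return Factor with levels `very_high`, `high`, `moderate`.
#' @export
bin_risk <- function(risk, sex, scheme = binning_scheme("esc-converted")) {
  stopifnot(inherits(scheme, "risk_binning_scheme"))
  n <- max(length(risk), length(sex))
  risk <- rep_len(as.numeric(risk), n)
  sex <- rep_len(as.character(sex), n)
  if (any(!is.na(risk) & (risk < 0 | risk > 1)))
    stop("bin_risk: risk must lie in [0, 1]")
  hc <- ifelse(sex == "female", scheme$female[["high"]], scheme$male[["high"]])
  vc <- ifelse(sex == "female", scheme$female[["very_high"]], scheme$male[["very_high"]])
  bin <- ifelse(risk >= vc, "very_high", ifelse(risk >= hc, "high", "moderate"))
  factor(bin, levels = esc_categories())
}

#' Load / save an ST1RE configuration
#'
#' YAML or JSON (by file extension). Unknown covariate names are refused
#' (closed-world schema); a missing provenance string draws a warning.
#'
#' @param path File path.
#' @return [st1re_config()] object.
#' @export
load_st1re_config <- function(path) {
  doc <- read_config_file(path)
  allowed <- c("form", "baseline_param", "terms", "horizon", "provenance")
  bad <- setdiff(names(doc), allowed)
  if (length(bad)) stop("load_st1re_config: unknown field(s): ", paste(bad, collapse = ", "))
  st1re_config(form = doc$form, baseline_param = doc$baseline_param,
               terms = doc$terms,
               horizon = if (is.null(doc$horizon)) 10 else doc$horizon,
               provenance = doc$provenance)
}

#' @rdname load_st1re_config
#' @param config [st1re_config()] object to write.
#' @export
save_st1re_config <- function(config, path) {
  stopifnot(inherits(config, "st1re_config"))
  doc <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}
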