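# Seeded synthetic T1D cohort generator. Continuous marginals are truncated
# normal (triglycerides log-normal) with the location parameter moment-matched
# so the configured mean is the mean of the *truncated* distribution; flags
# are Bernoulli; an optional Gaussian copula induces correlation.

# --- truncated-normal helpers ------------------------------------------------

tn_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

q_truncnorm <- function(u, mu, sd, lower, upper) {
  pl <- stats::pnorm(lower, mu, sd)
  pu <- stats::pnorm(upper, mu, sd)
  stats::qnorm(pl + u * (pu - pl), mu, sd)
}

# Location parameter such that the truncated-normal mean equals target.
calibrate_tn_mu <- function(target, sd, lower, upper) {
  if (!(lower < upper)) stop("generate_cohort: infeasible truncation (empty support)")
  stats::uniroot(function(mu) tn_mean(mu, sd, lower, upper) - target,
                 interval = target + c(-8, 8) * sd, tol = 1e-10)$root
}

# Location parameter such that the *marginal* mean over a per-patient upper
# bound (duration <= age - 0.5) equals target; quadrature over the age
# marginal at K quantile midpoints.
calibrate_tn_mu_marginal <- function(target, sd, lower, uppers, K = 256) {
  stats::uniroot(function(mu) mean(tn_mean(mu, sd, lower, uppers)) - target,
                 interval = target + c(-8, 8) * sd, tol = 1e-10)$root
}

lnorm_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Per-sex parameter lookup: spec may be a scalar (both sexes) or a named
# c(female = , male = ) pair.
sex_par <- function(spec, sex) {
  if (length(spec) == 1) return(rep(as.numeric(spec), length(sex)))
  as.numeric(spec[sex])
}

# --- configuration -----------------------------------------------------------

#' Default synthetic-cohort configuration
#'
#' Targets emulate the published characteristics of an adult European type 1
#' diabetes outpatient population: n = 575 with 272/575 women; age 36 +/- 13
#' (women) and 35.6 +/- 12.1 (men) years truncated to 18-74; diabetes
#' duration 19.1 +/- 10.5 / 18.8 +/- 10.9 years; per-sex anthropometrics,
#' blood pressure, lipids (triglycerides log-normal, 71.2 +/- 36.7 /
#' 86.5 +/- 62.3 mg/dl), HbA1c, and eGFR; complication prevalences
#' (retinopathy 15.2% / 22.1%, nephropathy, neuropathy, previous CVD 3.3% /
#' 4.3%). Parameters with no published counterpart (smoking, exercise,
#' medication use, LVH, proteinuria, albuminuria categories) are assumptions,
#' listed in the `assumed` field, and are pure configuration.
#'
#' @param n Cohort size (default 575).
#' @param seed Default seed stored in the config (overridable at generation).
#' @param correlation `list(method = "independent")` or
#'   `list(method = "gaussian-copula", pairs = data.frame(a, b, rho))` where
#'   `a`/`b` name latent variables (continuous names or flag names).
#' @return List of class `synthetic_cohort_config`.
#' @export
table1_default_config <- function(n = 575, seed = 20201003,
                                  correlation = list(method = "independent")) {
  cfg <- list(
    n = n, female_fraction = 272 / 575, seed = seed,
    continuous = list(
      age = list(family = "truncated-normal",
                 mean = c(female = 36, male = 35.6),
                 sd = c(female = 13, male = 12.1), lower = 18, upper = 74),
      diabetes_duration = list(family = "truncated-normal",
                               mean = c(female = 19.1, male = 18.8),
                               sd = c(female = 10.5, male = 10.9),
                               lower = 0, upper = NA),  # per-patient: age - 0.5
      waist_circumference = list(family = "truncated-normal",
                                 mean = c(female = 82.4, male = 89.3),
                                 sd = c(female = 11.3, male = 11.2),
                                 lower = 50, upper = 160),
      bmi = list(family = "truncated-normal",
                 mean = c(female = 24.7, male = 25.4),
                 sd = c(female = 3.8, male = 3.3), lower = 14, upper = 55),
      hba1c = list(family = "truncated-normal",
                   mean = c(female = 7.9, male = 7.7),
                   sd = c(female = 1.2, male = 1.22), lower = 4, upper = 16),
      sbp = list(family = "truncated-normal",
                 mean = c(female = 118, male = 123),
                 sd = c(female = 17, male = 14), lower = 75, upper = 220),
      dbp = list(family = "truncated-normal",
                 mean = c(female = 73, male = 76),
                 sd = c(female = 11, male = 9), lower = 40, upper = 130),
      total_chol = list(family = "truncated-normal",
                        mean = c(female = 181.5, male = 175.6),
                        sd = c(female = 35.7, male = 33), lower = 70, upper = 400),
      hdl_chol = list(family = "truncated-normal",
                      mean = c(female = 68, male = 56.9),
                      sd = c(female = 17.3, male = 13.9), lower = 20, upper = 140),
      triglycerides = list(family = "log-normal",
                           mean = c(female = 71.2, male = 86.5),
                           sd = c(female = 36.7, male = 62.3)),
      egfr = list(family = "truncated-normal",
                  mean = c(female = 100.7, male = 102.8),
                  sd = c(female = 18.6, male = 17.5), lower = 15, upper = 170)),
    prevalence = list(
      retinopathy = c(female = 0.152, male = 0.221),
      nephropathy = c(female = 0.094, male = 0.101),
      neuropathy = c(female = 0.109, male = 0.1007),
      previous_cvd = c(female = 0.033, male = 0.043),
      smoker = 0.25, exercise = 0.40,
      antihypertensive_use = 0.18, lipid_lowering_use = 0.25,
      lvh = 0.03, proteinuria = 0.04),
    albuminuria = c(normo = 0.89, micro = 0.08, macro = 0.03),
    assumed = c("smoker", "exercise", "antihypertensive_use",
                "lipid_lowering_use", "lvh", "proteinuria", "albuminuria"),
    correlation = correlation)
  structure(cfg, class = "synthetic_cohort_config")
}

validate_synth_config <- function(config) {
  stopifnot(is.numeric(config$n), config$n >= 1)
  if (config$female_fraction < 0 || config$female_fraction > 1)
    stop("generate_cohort: female_fraction must lie in [0, 1]")
  for (v in names(config$continuous)) {
    sp <- config$continuous[[v]]
    if (!sp$family %in% c("truncated-normal", "log-normal"))
      stop("generate_cohort: unknown family for '", v, "'")
    if (sp$family == "truncated-normal" && v != "diabetes_duration" &&
        !(sp$lower < sp$upper))
      stop("generate_cohort: infeasible truncation for '", v, "'")
  }
  for (p in names(config$prevalence)) {
    pr <- config$prevalence[[p]]
    if (any(pr < 0 | pr > 1)) stop("generate_cohort: prevalence out of [0,1] for '", p, "'")
  }
  if (abs(sum(config$albuminuria) - 1) > 1e-8)
    stop("generate_cohort: albuminuria probabilities must sum to 1")
  invisible(TRUE)
}

latent_names <- function(config) {
  c(names(config$continuous), names(config$prevalence), "albuminuria")
}

copula_chol <- function(config) {
  vars <- latent_names(config)
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  corr <- config$correlation
  if (!is.null(corr) && identical(corr$method, "gaussian-copula")) {
    pairs <- corr$pairs
    if (is.null(pairs) || nrow(pairs) == 0)
      stop("generate_cohort: gaussian-copula requires correlation pairs")
    for (i in seq_len(nrow(pairs))) {
      a <- as.character(pairs$a[i]); b <- as.character(pairs$b[i])
      if (!(a %in% vars) || !(b %in% vars))
        stop("generate_cohort: unknown correlation variable '",
             setdiff(c(a, b), vars)[1], "'")
      R[a, b] <- R[b, a] <- pairs$rho[i]
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("generate_cohort: correlation matrix is not positive semi-definite")
    R <- R + diag(1e-10, nrow(R))
  }
  chol(R)
}

# --- generation --------------------------------------------------------------

#' Generate a synthetic T1D cohort
#'
#' Samples `config$n` patient records. Sex is Bernoulli(`female_fraction`);
#' continuous variables are drawn from per-sex truncated normals whose
#' location is moment-matched so the configured mean is the marginal mean
#' despite truncation (triglycerides: log-normal, exact mean/SD
#' parameterization). Diabetes duration is sampled truncated to
#' `[0, age - 0.5]` with its location calibrated against the age marginal, and
#' onset age is derived as `age - diabetes_duration`, so internal consistency
#' is exact. Flags are Bernoulli at the configured (per-sex) prevalence;
#' albuminuria is categorical. All draws pass through a latent-uniform layer,
#' so `correlation = list(method = "gaussian-copula", pairs = ...)` induces
#' rank correlation between any latent variables. Identical seed and config
#' give an identical cohort.
#'
#' @param config [table1_default_config()]-style configuration.
#' @param seed Overrides `config$seed`.
#' @return Cohort `data.frame` (see [cohort_columns()]); LDL and serum
#'   creatinine are left missing (LDL is derived downstream by
#'   [derive_measures()]; eGFR is generated directly).
#' @export
generate_cohort <- function(config = table1_default_config(), seed = config$seed) {
  validate_synth_config(config)
  n <- as.integer(config$n)
  set.seed(seed)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  L <- copula_chol(config)
  vars <- colnames(L)
  Z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% L
  U <- stats::pnorm(Z)
  colnames(U) <- vars

  vals <- list()
  age_spec <- config$continuous$age
  mu_age <- c(female = calibrate_tn_mu(age_spec$mean[["female"]], age_spec$sd[["female"]],
                                       age_spec$lower, age_spec$upper),
              male = calibrate_tn_mu(age_spec$mean[["male"]], age_spec$sd[["male"]],
                                     age_spec$lower, age_spec$upper))
  age <- q_truncnorm(U[, "age"], mu_age[sex],
                     sex_par(age_spec$sd, sex), age_spec$lower, age_spec$upper)
  vals$age <- age

  dur_spec <- config$continuous$diabetes_duration
  K <- 256
  qs <- (seq_len(K) - 0.5) / K
  mu_dur <- vapply(c("female", "male"), function(s) {
    age_grid <- q_truncnorm(qs, mu_age[[s]], age_spec$sd[[s]],
                            age_spec$lower, age_spec$upper)
    calibrate_tn_mu_marginal(dur_spec$mean[[s]], dur_spec$sd[[s]],
                             dur_spec$lower, age_grid - 0.5)
  }, numeric(1))
  duration <- q_truncnorm(U[, "diabetes_duration"], mu_dur[sex],
                          sex_par(dur_spec$sd, sex), dur_spec$lower, age - 0.5)
  vals$diabetes_duration <- duration

  for (v in setdiff(names(config$continuous), c("age", "diabetes_duration"))) {
    sp <- config$continuous[[v]]
    if (sp$family == "log-normal") {
      pf <- lnorm_params(sp$mean[["female"]], sp$sd[["female"]])
      pm <- lnorm_params(sp$mean[["male"]], sp$sd[["male"]])
      meanlog <- ifelse(sex == "female", pf$meanlog, pm$meanlog)
      sdlog <- ifelse(sex == "female", pf$sdlog, pm$sdlog)
      vals[[v]] <- stats::qlnorm(U[, v], meanlog, sdlog)
    } else {
      mu <- c(female = calibrate_tn_mu(sp$mean[["female"]], sp$sd[["female"]],
                                       sp$lower, sp$upper),
              male = calibrate_tn_mu(sp$mean[["male"]], sp$sd[["male"]],
                                     sp$lower, sp$upper))
      vals[[v]] <- q_truncnorm(U[, v], mu[sex], sex_par(sp$sd, sex),
                               sp$lower, sp$upper)
    }
  }

  # flags occupy the upper tail of their latent so a positive copula
  # correlation with a continuous variable induces a positive association
  flags <- lapply(names(config$prevalence), function(p) {
    U[, p] > 1 - sex_par(config$prevalence[[p]], sex)
  })
  names(flags) <- names(config$prevalence)

  pa <- cumsum(config$albuminuria)  # cut the latent uniform at cumulative probabilities
  alb <- as.character(cut(U[, "albuminuria"],
                          breaks = c(0, pa[["normo"]], pa[["micro"]], 1),
                          labels = c("normo", "micro", "macro"),
                          include.lowest = TRUE))

  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = sex,
    age = age,
    onset_age = age - duration,
    diabetes_duration = duration,
    bmi = vals$bmi,
    waist_circumference = vals$waist_circumference,
    sbp = vals$sbp,
    dbp = vals$dbp,
    total_chol = vals$total_chol,
    hdl_chol = vals$hdl_chol,
    triglycerides = vals$triglycerides,
    ldl_chol = NA_real_,
    hba1c = vals$hba1c,
    serum_creatinine = NA_real_,
    egfr = vals$egfr,
    albuminuria = alb,
    smoker = flags$smoker,
    exercise = flags$exercise,
    antihypertensive_use = flags$antihypertensive_use,
    lipid_lowering_use = flags$lipid_lowering_use,
    retinopathy = flags$retinopathy,
    lvh = flags$lvh,
    proteinuria = flags$proteinuria,
    nephropathy = flags$nephropathy,
    neuropathy = flags$neuropathy,
    previous_cvd = flags$previous_cvd,
    stringsAsFactors = FALSE)
}

#' Check a generated cohort against its configured marginals
#'
#' For each continuous variable and sex, the difference between the empirical
#' and the configured mean is expressed in standard errors of the mean; for
#' each flag, a binomial z score against the configured prevalence. A
#' variable passes when |z| <= `z_max` (default 4). A configured prevalence
#' of 0 passes iff the empirical count is 0.
#'
#' @param cohort Cohort produced by [generate_cohort()].
#' @param config The configuration it was generated from.
#' @param z_max Pass threshold in absolute z units.
#' @return `data.frame` with `variable`, `group`, `target`, `empirical`, `z`,
#'   `pass`; attribute `pass` is the conjunction.
#' @export
validate_marginals <- function(cohort, config, z_max = 4) {
  rows <- list()
  add <- function(variable, group, target, empirical, z) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, group = group, target = target,
      empirical = empirical, z = z, pass = abs(z) <= z_max,
      stringsAsFactors = FALSE)
  }
  groups <- function(spec) if (length(spec) == 1) list(all = rep(TRUE, nrow(cohort)))
    else list(female = cohort$sex == "female", male = cohort$sex == "male")
  for (v in names(config$continuous)) {
    sp <- config$continuous[[v]]
    for (g in names(groups(sp$mean))) {
      sel <- groups(sp$mean)[[g]]
      x <- cohort[[v]][sel]
      target <- if (length(sp$mean) == 1) as.numeric(sp$mean) else sp$mean[[g]]
      se <- stats::sd(x) / sqrt(length(x))
      add(v, g, target, mean(x), (mean(x) - target) / se)
    }
  }
  for (p in names(config$prevalence)) {
    pr <- config$prevalence[[p]]
    for (g in names(groups(pr))) {
      sel <- groups(pr)[[g]]
      x <- cohort[[p]][sel]
      target <- if (length(pr) == 1) as.numeric(pr) else pr[[g]]
      k <- sum(x); m <- length(x)
      z <- if (target %in% c(0, 1)) { if (mean(x) == target) 0 else Inf }
           else (mean(x) - target) / sqrt(target * (1 - target) / m)
      add(p, g, target, mean(x), z)
    }
  }
  for (lev in names(config$albuminuria)) {
    target <- config$albuminuria[[lev]]
    phat <- mean(cohort$albuminuria == lev)
    z <- if (target %in% c(0, 1)) { if (phat == target) 0 else Inf }
         else (phat - target) / sqrt(target * (1 - target) / nrow(cohort))
    add(paste0("albuminuria_", lev), "all", target, phat, z)
  }
  out <- do.call(rbind, rows)
  structure(out, pass = all(out$pass))
}
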