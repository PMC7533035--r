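lv <- function(x) factor(x, levels = c("very_high", "high", "moderate"))

test_that("concordance cells are exact tallies on a hand-checked fixture", {
  co <- make_cohort(make_patient(age = 40), make_patient(age = 41),
                    make_patient(age = 42), make_patient(age = 30))
  esc <- lv(c("very_high", "very_high", "high", "moderate"))
  bins <- lv(c("moderate", "moderate", "high", "moderate"))
  tab <- build_concordance(co, esc, bins)
  get <- function(row, bin) tab$count[tab$row == row & tab$st1re_bin == bin]
  expect_equal(get("very_high", "moderate"), 2)
  expect_equal(get("very_high", "very_high"), 0)
  expect_equal(get("high", "high"), 1)
  expect_equal(get("moderate", "moderate"), 1)
  expect_equal(tab$pct[tab$row == "very_high" & tab$st1re_bin == "moderate"], 100)
  # stratum filters by age
  tab35 <- build_concordance(co, esc, bins, stratum = "at_least_35")
  expect_equal(attr(tab35, "n"), 3)
  expect_equal(tab35$count[tab35$row == "moderate"], c(0, 0, 0))
  # a missing prediction is a hard error
  expect_error(build_concordance(co, esc, lv(c(NA, "moderate", "high", "moderate"))),
               "without a prediction")
})

test_that("concordance conserves counts, nests subcategories, and is permutation-invariant", {
  co <- suppressWarnings(
    derive_measures(generate_cohort(table1_default_config(), seed = 202)))
  ex <- apply_analysis_exclusions(co)
  an <- ex$analyzed
  prof <- derive_risk_profile(an)
  esc <- classify_esc(an, prof)
  sub <- very_high_subcategory(an, prof, esc)
  pred <- st1re_predict(an, load_st1re_config(
    system.file("extdata", "st1re-synthetic.yaml", package = "stenoconcord")),
    binning_scheme("esc-converted"))
  for (s in c("all", "under_35", "at_least_35", "at_least_50")) {
    tab <- build_concordance(an, esc, pred$st1re_bin, sub, stratum = s)
    cat_rows <- tab[tab$row_type == "category", ]
    expect_equal(sum(cat_rows$count), attr(tab, "n"))
    # subcategory rows sum exactly to the very-high row, cell by cell
    vh <- tab[tab$row == "very_high", ]
    subs <- tab[tab$row_type == "subcategory", ]
    n_prev_cvd_vh <- sum(an$previous_cvd[stenoconcord:::stratum_filter(an$age, s)] &
                           esc[stenoconcord:::stratum_filter(an$age, s)] %in% "very_high")
    for (b in levels(esc)) {
      expect_equal(sum(subs$count[subs$st1re_bin == b]),
                   vh$count[vh$st1re_bin == b] - 0)  # analyzed set has no previous CVD
    }
    expect_equal(n_prev_cvd_vh, 0)
  }
  # permutation invariance
  set.seed(1); p <- sample(nrow(an))
  tab1 <- build_concordance(an, esc, pred$st1re_bin, sub)
  tab2 <- build_concordance(an[p, ], esc[p], pred$st1re_bin[p], sub[p])
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))
})

test_that("category shares use the stratum denominator and recombine across strata", {
  co <- data.frame(patient_id = as.character(1:100),
                   age = c(rep(30, 40), rep(50, 60)))
  esc <- lv(c(rep("very_high", 30), rep("high", 62), rep("moderate", 8)))
  sh <- category_shares(co, esc)
  expect_equal(sh$pct, c(30, 62, 8))
  expect_equal(sum(sh$count), 100)
  # single-category stratum and empty stratum
  sh1 <- category_shares(co[1:5, ], lv(rep("high", 5)))
  expect_equal(sh1$pct, c(0, 100, 0))
  empty <- category_shares(co[0, ], lv(character(0)))
  expect_equal(empty$pct, c(0, 0, 0))
  # weighted recombination of the age strata equals the all-stratum shares
  lo <- category_shares(co, esc, "under_35", digits = 10)
  hi <- category_shares(co, esc, "at_least_35", digits = 10)
  all_s <- category_shares(co, esc, "all", digits = 10)
  w <- c(attr(lo, "n"), attr(hi, "n")) / attr(all_s, "n")
  expect_equal(w[1] * lo$pct + w[2] * hi$pct, all_s$pct)
})

test_that("Welch t test matches the hand formula and its conventions", {
  out <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)  # = -3.674
  expect_equal(out$df, 4)
  expect_equal(out$p_value, 0.0213, tolerance = 1e-2)
  # antisymmetry
  rev_out <- welch_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev_out$statistic, -out$statistic)
  expect_equal(rev_out$p_value, out$p_value)
  # identical samples
  expect_message(same <- welch_t_test(c(2, 2), c(2, 2)), "convention")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("chi-square test matches sum((O-E)^2/E) and is transpose-invariant", {
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$p_value, 1)
  out <- chi_square_test(rbind(c(20, 10), c(10, 20)))
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(out$statistic,
               chi_square_test(t(rbind(c(20, 10), c(10, 20))))$statistic)
  expect_error(chi_square_test(rbind(c(0, 0), c(5, 5))), "margin")
})

test_that("statistics agree with independent textbook implementations on random fixtures", {
  set.seed(77)
  for (i in 1:150) {
    x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    got <- welch_t_test(x, y); want <- oracle_welch(x, y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
    tab <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chi_square_test(tab)$statistic, oracle_chisq(tab)$statistic,
                 tolerance = 1e-10)
  }
})

test_that("cohort summary reports means, prevalences and tests per sex", {
  co <- make_cohort(
    make_patient(sex = "female", hba1c = 8, smoker = TRUE),
    make_patient(sex = "female", hba1c = 8, smoker = FALSE),
    make_patient(sex = "male", hba1c = 7, smoker = TRUE),
    make_patient(sex = "male", hba1c = 7, smoker = FALSE))
  s <- summarize_cohort(co, continuous = "hba1c", binary = "smoker")
  expect_equal(s$female[s$variable == "hba1c"], 8)
  expect_equal(s$male[s$variable == "hba1c"], 7)
  expect_equal(s$female_sd[s$variable == "hba1c"], 0)
  expect_equal(s$p_value[s$variable == "smoker"], 1)  # 50% in both sexes
  # permutation invariance on a generated cohort
  co2 <- derive_measures(generate_cohort(table1_default_config(n = 300), seed = 8))
  s1 <- summarize_cohort(co2)
  s2 <- summarize_cohort(co2[sample(nrow(co2)), ])
  expect_equal(s1, s2, ignore_attr = TRUE)
  # entirely missing variable omitted with a warning
  co2$hba1c <- NA_real_
  expect_warning(s3 <- summarize_cohort(co2), "entirely missing")
  expect_false("hba1c" %in% s3$variable)
})
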