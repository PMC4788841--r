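# The cleaning cascade and its component rules.

test_that("BMI arithmetic and domain checks", {
  expect_equal(compute_bmi(86.7, 1.70), 30.0)
  expect_equal(compute_bmi(53.0, 1.70), 53.0 / 1.70^2)
  expect_error(compute_bmi(0, 1.70), "positive")
  expect_error(compute_bmi(70, -1), "positive")
  expect_true(is.na(compute_bmi(NA, 1.7)))
})

test_that("WHO categories use half-open intervals", {
  got <- categorize_bmi(c(18.49, 18.5, 24.99, 25, 29.99, 30, 50))
  expect_equal(as.character(got),
               c("underweight", "normal weight", "normal weight",
                 "overweight", "overweight", "obese", "obese"))
})

test_that("the last height is carried forward within patients", {
  tab <- dplyr::bind_rows(
    obs_row("p1", "2010-01-01", 1.80, 70),
    obs_row("p1", "2011-03-01", 1.75, 72),
    obs_row("p1", "2011-05-01", NA, 74))
  out <- carry_forward_height(tab)
  expect_equal(out$height[out$observation_date == as.Date("2011-05-01")],
               1.75)
  # single complete row unchanged
  one <- carry_forward_height(obs_row("p2", "2011-01-01", 1.6, 60))
  expect_equal(one$height, 1.6)
  # weights only: stays missing
  wonly <- carry_forward_height(dplyr::bind_rows(
    obs_row("p3", "2011-01-01", NA, 60),
    obs_row("p3", "2011-06-01", NA, 61)))
  expect_true(all(is.na(wonly$height)))
  # a row before any height gets the most recent height overall
  back <- carry_forward_height(dplyr::bind_rows(
    obs_row("p4", "2011-01-01", NA, 60),
    obs_row("p4", "2011-02-01", 1.70, 61),
    obs_row("p4", "2011-08-01", 1.68, 62)))
  expect_equal(back$height, c(1.68, 1.70, 1.68))
})

test_that("the pregnancy window spans 9 months before to 12 after the EDB", {
  edb <- as.Date("2011-06-01")
  dates <- as.Date(c("2010-08-15", "2010-09-01", "2010-09-15",
                     "2012-06-01", "2012-06-02"))
  tab <- tibble::tibble(observation_date = dates)
  kept <- exclude_pregnancy_window(tab, edb = edb)$observation_date
  expect_equal(kept, as.Date(c("2010-08-15", "2012-06-02")))
  # no EDB column value: nothing dropped
  norow <- obs_row("p1", "2011-01-01", 1.7, 70)
  expect_equal(nrow(exclude_pregnancy_window(norow)), 1)
})

test_that("final BMI selection keeps the latest in-year plausible measure", {
  mk <- function(id, date, bmi) obs_row(id, date, 1.0, bmi)
  two <- dplyr::bind_rows(mk("p1", "2011-03-01", 27.1),
                          mk("p1", "2011-11-01", 28.4))
  got <- select_final_bmi(two, 2011)
  expect_equal(got$bmi, 28.4)
  expect_equal(as.character(got$bmi_category), "overweight")
  # outlier bounds are strict: 14.9 excluded, 15.0 and 50.0 retained
  expect_equal(nrow(select_final_bmi(mk("p2", "2011-05-01", 14.9), 2011)), 0)
  expect_equal(select_final_bmi(mk("p3", "2011-05-01", 50.0), 2011)$bmi, 50)
  expect_equal(select_final_bmi(mk("p4", "2011-05-01", 15.0), 2011)$bmi, 15)
  expect_equal(nrow(select_final_bmi(mk("p5", "2011-05-01", 50.1), 2011)), 0)
})

test_that("the variation screen flags only wildly inconsistent series", {
  mk_series <- function(id, bmis) {
    tibble::tibble(patient_id = id, bmi = bmis)
  }
  # one patient swinging 10 BMI units among 99 patients with tiny ranges
  set.seed(3)
  cohort <- dplyr::bind_rows(
    lapply(1:99, function(i) {
      mk_series(sprintf("s%02d", i), 25 + c(0, runif(1)))
    }),
    mk_series("big", c(20, 30)))
  expect_equal(exclude_high_within_patient_variation(cohort), "big")
  expect_equal(
    exclude_high_within_patient_variation(cohort, strategy = "range_sd"),
    "big")
  # all-zero ranges: nothing flagged
  flat <- dplyr::bind_rows(lapply(1:10, function(i) {
    mk_series(sprintf("f%02d", i), c(25, 25))
  }))
  expect_length(exclude_high_within_patient_variation(flat), 0)
  # single-visit patients are never flagged
  singles <- dplyr::bind_rows(mk_series("a", 20), mk_series("b", 45))
  expect_length(exclude_high_within_patient_variation(singles), 0)
  # fewer than two multi-measure patients: no flags
  lone <- dplyr::bind_rows(mk_series("a", c(20, 40)), mk_series("b", 25))
  expect_length(exclude_high_within_patient_variation(lone), 0)
})

test_that("missingness cohorts are compared with chi-square and Welch t", {
  mk_cohort <- function(n, n_diab, ages) {
    tibble::tibble(age = ages, diabetes = rep(c(1L, 0L), c(n_diab, n - n_diab)))
  }
  ages <- rep(c(30, 40, 50, 60), 25)
  same <- compare_missingness_cohorts(mk_cohort(100, 50, ages),
                                      mk_cohort(100, 50, ages))
  expect_equal(same$statistic[same$variable == "diabetes"], 0)
  expect_equal(same$statistic[same$variable == "age"], 0)
  expect_equal(same$p_value[same$variable == "age"], 1)
  diff <- compare_missingness_cohorts(mk_cohort(100, 30, ages),
                                      mk_cohort(100, 50, ages))
  expect_equal(diff$statistic[diff$variable == "diabetes"], 25 / 3,
               tolerance = 1e-12)
  expect_error(compare_missingness_cohorts(mk_cohort(10, 5, rep(30, 10)),
                                           mk_cohort(0, 0, numeric(0))),
               "non-empty")
  # cross-check both tests against the stats package on a random cohort
  set.seed(11)
  a <- mk_cohort(80, 22, rnorm(80, 50, 10))
  b <- mk_cohort(120, 51, rnorm(120, 47, 12))
  got <- compare_missingness_cohorts(a, b)
  ref_chi <- stats::chisq.test(
    matrix(c(22, 58, 51, 69), nrow = 2, byrow = TRUE), correct = FALSE)
  ref_t <- stats::t.test(a$age, b$age)
  expect_equal(got$statistic[got$variable == "diabetes"],
               unname(ref_chi$statistic))
  expect_equal(got$statistic[got$variable == "age"],
               unname(ref_t$statistic))
  expect_equal(got$p_value[got$variable == "age"], ref_t$p.value)
})

test_that("the handcrafted cascade fixture loses exactly one patient per filter", {
  cc <- run_cascade(cascade_fixture(), year = 2011)
  att <- cc$attrition
  expect_equal(att$step,
               c("extracted", "eligibility", "duplicates",
                 "pregnancy_window", "missing_measures", "bmi_outliers",
                 "bmi_variation"))
  expect_equal(att$patients_removed, c(0, 1, 0, 1, 1, 1, 1))
  expect_equal(att$patients_remaining, c(9, 8, 8, 7, 6, 5, 4))
  expect_equal(att$rows_removed[att$step == "duplicates"], 1)
  expect_setequal(cc$patients$patient_id, c("B", "G", "H", "I"))
  expect_equal(cc$excluded$step[cc$excluded$patient_id == "F"],
               "bmi_variation")
  # latest in-year measure is the one reported
  expect_equal(cc$patients$bmi[cc$patients$patient_id == "G"],
               64.5 / 1.6^2)
})

test_that("attrition counts telescope on arbitrary inputs", {
  for (seed in c(1, 2)) {
    b <- generate_bundle(sim_config(n_patients = 300, seed = seed))
    att <- run_cascade(b$observations)$attrition
    expect_equal(att$patients_remaining[-1],
                 head(att$patients_remaining, -1) - att$patients_removed[-1])
  }
})

test_that("every retained record has a category consistent with its BMI", {
  b <- generate_bundle(sim_config(n_patients = 500, seed = 21))
  pats <- run_cascade(b$observations)$patients
  expect_true(all(pats$bmi >= 15 & pats$bmi <= 50))
  expect_equal(pats$bmi_category, categorize_bmi(pats$bmi))
  expect_true(all(pats$age >= 20))
})

test_that("the cascade is idempotent on its own output", {
  b <- generate_bundle(sim_config(n_patients = 300, seed = 13))
  cc1 <- run_cascade(b$observations)
  cc2 <- run_cascade(cc1$observations)
  expect_equal(sort(cc2$patients$patient_id), sort(cc1$patients$patient_id))
  expect_true(all(cc2$attrition$patients_removed == 0))
  expect_equal(dplyr::arrange(cc2$patients, patient_id)$bmi,
               dplyr::arrange(cc1$patients, patient_id)$bmi)
})

test_that("filter order matters and is fixed: pregnancy before outliers", {
  # a pregnant patient whose only measure is also implausible is attributed
  # to the pregnancy window under the cascade's fixed order
  tab <- dplyr::bind_rows(
    obs_row("dual", "2011-05-01", 1.60, 140.8,
            edb = as.Date("2011-06-01")),
    obs_row("ok", "2011-05-01", 1.60, 64.0))
  att <- run_cascade(tab, year = 2011)$attrition
  expect_equal(att$patients_removed[att$step == "pregnancy_window"], 1)
  expect_equal(att$patients_removed[att$step == "bmi_outliers"], 0)
  # permuting the two filters moves the loss to the outlier step
  no_outliers <- tab[compute_bmi(tab$weight, tab$height) <= 50, ]
  att2 <- run_cascade(no_outliers, year = 2011)$attrition
  expect_equal(att2$patients_removed[att2$step == "pregnancy_window"], 0)
})
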