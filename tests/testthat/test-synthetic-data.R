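# The generator must be reproducible, respect its configured defect rates,
# and plant a recoverable deprivation-obesity gradient.

test_that("configuration is validated", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(sex_ratio = 1.2), "proportions")
  expect_error(sim_config(duplicate_rate = -0.1), "proportions")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(age_distribution = c(0.5, 0.5)), "age_distribution")
  expect_error(sim_config(quintile_obesity_prevalence = c(0.2, 0.3)),
               "quintile_obesity_prevalence")
  expect_error(sim_config(visits_per_patient = 0.5), "visits_per_patient")
})

test_that("identical config and seed give identical bundles", {
  cfg <- sim_config(n_patients = 150, seed = 404)
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1$observations, b2$observations)
  expect_identical(b1$conversion, b2$conversion)
  expect_identical(b1$deprivation, b2$deprivation)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_bundle(sim_config(n_patients = 150, seed = 405))
  expect_false(identical(b1$observations, b3$observations))
})

test_that("truth covers every patient and postal codes resolve as configured", {
  b <- generate_bundle(sim_config(n_patients = 400, seed = 2))
  expect_setequal(b$truth$patient_id, unique(b$observations$patient_id))
  by_patient <- dplyr::distinct(b$observations, patient_id, postal_code)
  tab <- dplyr::left_join(by_patient, b$truth, by = "patient_id")
  resolvable <- tab$postal_code %in% b$conversion$postal_code
  # everything resolves except the deliberately erroneous/missing codes
  expect_true(all(resolvable[!tab$postal_defect %in%
                               c("erroneous", "missing")]))
  expect_true(all(!resolvable[tab$postal_defect %in%
                                c("erroneous", "missing")]))
})

test_that("generated postal codes follow the Canadian format and urban flag", {
  b <- generate_bundle(sim_config(n_patients = 350, seed = 9))
  codes <- b$conversion$postal_code
  expect_gt(length(codes), 500)
  expect_true(all(grepl("^[A-Z][0-9][A-Z][0-9][A-Z][0-9]$", codes)))
  # second character encodes urban/rural consistently with the flag
  second <- substr(codes, 2, 2)
  expect_true(all((second == "0") == !b$conversion$urban))
  # 1000 fresh codes all match the pattern
  set.seed(1)
  fresh <- generate_postal_code(sample.int(200, 1000, replace = TRUE),
                                urban = sample(c(TRUE, FALSE), 1000,
                                               replace = TRUE))
  expect_true(all(grepl("^[A-Z][0-9][A-Z][0-9][A-Z][0-9]$", fresh)))
})

test_that("a defect-free cohort passes the cascade untouched", {
  cfg <- sim_config(n_patients = 100, seed = 5,
                    missing_height_rate = 0, missing_weight_rate = 0,
                    duplicate_rate = 0, outlier_rate = 0,
                    pregnancy_rate = 0, out_of_region_postal_rate = 0,
                    unmatched_da_rate = 0)
  b <- generate_bundle(cfg)
  cc <- run_cascade(b$observations, year = cfg$year)
  expect_equal(nrow(cc$patients), 100)
  expect_true(all(cc$attrition$patients_removed == 0))
})

test_that("injected defect counts match the configured rates exactly", {
  cfg <- sim_config(n_patients = 2000, seed = 77)
  b <- generate_bundle(cfg)
  md <- table(b$truth$measure_defect)
  expect_equal(unname(md[["pregnancy"]]), round(0.04 * 2000))
  expect_equal(unname(md[["missing_height"]]), round(0.07 * 2000))
  expect_equal(unname(md[["missing_weight"]]), round(0.07 * 2000))
  expect_equal(unname(md[["outlier"]]), round(0.009 * 2000))
  pd <- table(b$truth$postal_defect)
  oor <- sum(pd[c("out_of_region", "erroneous", "missing")])
  expect_equal(unname(oor), round(0.09 * 2000))
  expect_equal(unname(pd[["unmatched"]]), round(0.05 * 2000))
  # duplicated rows: at least the injected count, at most a whisker more
  n_dup <- sum(duplicated(b$observations))
  base_rows <- nrow(b$observations) / 1.05
  expect_gte(n_dup, round(0.05 * base_rows) - 1)
  expect_lte(n_dup, round(0.05 * base_rows) + 0.01 * nrow(b$observations))
})

test_that("the cascade removes defect patients at the configured rates", {
  cfg <- sim_config(n_patients = 2000, seed = 31)
  b <- generate_bundle(cfg)
  cc <- run_cascade(b$observations, year = cfg$year)
  att <- cc$attrition
  get <- function(s) att$patients_removed[att$step == s]
  se <- function(p) sqrt(p * (1 - p) / 2000)
  expect_lt(abs(get("pregnancy_window") / 2000 - 0.04), 3 * se(0.04) + 1e-9)
  expect_lt(abs(get("missing_measures") / 2000 - 0.14), 3 * se(0.14) + 1e-9)
  expect_lt(abs(get("bmi_outliers") / 2000 - 0.009), 3 * se(0.009) + 1e-9)
})

test_that("a planted gradient is present in the truth draws", {
  planted <- c(0.279, 0.366, 0.380, 0.396, 0.444)
  cfg <- sim_config(n_patients = 4000, seed = 12,
                    missing_height_rate = 0, missing_weight_rate = 0,
                    duplicate_rate = 0, outlier_rate = 0,
                    pregnancy_rate = 0, out_of_region_postal_rate = 0,
                    unmatched_da_rate = 0)
  b <- generate_bundle(cfg)
  by_q <- b$truth |>
    dplyr::group_by(true_quintile) |>
    dplyr::summarise(p = mean(true_obese), n = dplyr::n())
  expect_equal(nrow(by_q), 5)
  for (q in 1:5) {
    se <- sqrt(planted[q] * (1 - planted[q]) / by_q$n[q])
    expect_lt(abs(by_q$p[q] - planted[q]), 3 * se)
  }
})

test_that("the pipeline recovers a planted gradient end to end", {
  cfg <- sim_config(n_patients = 4000, seed = 8,
                    missing_height_rate = 0, missing_weight_rate = 0,
                    duplicate_rate = 0, outlier_rate = 0,
                    pregnancy_rate = 0, out_of_region_postal_rate = 0,
                    unmatched_da_rate = 0)
  study <- run_study(cfg)
  est <- study$disparity$combined$prevalence
  planted <- 100 * cfg$quintile_obesity_prevalence
  n_q <- study$report$distribution$combined_quintile$n
  for (q in 1:5) {
    se <- 100 * sqrt(planted[q] / 100 * (1 - planted[q] / 100) / n_q[q])
    expect_lt(abs(est[q] - planted[q]), 3 * se + 1e-9)
  }
})

test_that("bundles round-trip through CSV files", {
  b <- generate_bundle(sim_config(n_patients = 30, seed = 6))
  dir <- withr::local_tempdir()
  paths <- write_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_csv(paths[1], show_col_types = FALSE)
  expect_equal(nrow(back), nrow(b$observations))
  expect_setequal(names(back), names(b$observations))
})
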