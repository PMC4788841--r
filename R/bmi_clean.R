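# The cleaning cascade: visit-level observations -> one BMI record per
# patient for the study year, with a telescoping attrition report and a
# missing-data cohort comparison.

BMI_CATEGORIES <- c("underweight", "normal weight", "overweight", "obese")
AGE_GROUPS <- c("20-39", "40-59", "60-79", "80+")

#' Compute body mass index
#'
#' BMI = weight (kg) / height (m)^2.
#'
#' @param weight weight in kilograms.
#' @param height height in metres.
#' @return numeric BMI in kg/m2 (vectorized; `NA` in gives `NA` out).
#' @export
#' @examples
#' compute_bmi(86.7, 1.70)
compute_bmi <- function(weight, height) {
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight / height^2
}

#' Categorize BMI with the WHO adult cut-points
#'
#' Half-open intervals: underweight < 18.5, normal weight \[18.5, 25),
#' overweight \[25, 30), obese >= 30 kg/m2.
#'
#' @param bmi numeric BMI values (kg/m2).
#' @return factor with levels underweight, normal weight, overweight, obese.
#' @export
#' @examples
#' categorize_bmi(c(18.5, 24.99, 30))
categorize_bmi <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf),
      labels = BMI_CATEGORIES, right = FALSE)
}

# Age at December 31 of the study year equals year minus birth year, however
# coarsely the birth date is recorded (full date, year-month, year, or
# 5-year band, whose leading year — the oldest bound — is used).
age_at_year_end <- function(birth_date, year) {
  y <- suppressWarnings(as.integer(substr(as.character(birth_date), 1, 4)))
  year - y
}

age_group_of <- function(age) {
  cut(age, breaks = c(-Inf, 39, 59, 79, Inf), labels = AGE_GROUPS)
}

#' Carry the last height measurement forward within each patient
#'
#' A weight-only row receives the most recent height measured on or before
#' its date; rows before any height measurement receive the patient's most
#' recent height overall.  Patients with no height anywhere keep `NA`.
#'
#' @param observations observation tibble with `patient_id`, `height`,
#'   `observation_date`.
#' @return the tibble with `height` filled, original row content otherwise
#'   unchanged (row order may change: rows are sorted by patient and date).
#' @export
carry_forward_height <- function(observations) {
  observations %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::arrange(.data$observation_date, .by_group = TRUE) %>%
    dplyr::mutate(height = {
      h <- .data$height
      seen <- cummax(ifelse(!is.na(h), dplyr::row_number(), 0L))
      filled <- ifelse(seen > 0L, h[pmax(seen, 1L)], NA_real_)
      any_h <- rev(h[!is.na(h)])
      if (length(any_h)) filled[is.na(filled)] <- any_h[1]
      filled
    }) %>%
    dplyr::ungroup()
}

#' Drop measurements inside a pregnancy exclusion window
#'
#' Removes rows dated within 9 months before to 12 months after the
#' estimated date of birth of the infant (inclusive endpoints).  With
#' `edb = NULL` the window is taken per-row from a `pregnancy_edb` column;
#' rows without one are always retained.
#'
#' @param observations observation tibble with `observation_date`.
#' @param edb optional single estimated date of birth applied to all rows.
#' @return the tibble with in-window rows removed.
#' @export
#' @examples
#' tab <- tibble::tibble(observation_date = as.Date(c("2010-09-15",
#'                                                    "2010-08-15")))
#' exclude_pregnancy_window(tab, edb = as.Date("2011-06-01"))
exclude_pregnancy_window <- function(observations, edb = NULL) {
  if (is.null(edb)) {
    if (!"pregnancy_edb" %in% names(observations)) return(observations)
    e <- as.Date(observations$pregnancy_edb)
  } else {
    e <- rep(as.Date(edb), nrow(observations))
  }
  d <- as.Date(observations$observation_date)
  inside <- !is.na(e) &
    d >= (e %m-% lubridate::period(9, "months")) &
    d <= (e %m+% lubridate::period(12, "months"))
  observations[!inside, , drop = FALSE]
}

#' Select the final in-year BMI measure per patient
#'
#' Deduplicates exact-duplicate rows, computes a BMI per row, drops rows
#' with BMI below `outlier_low` or above `outlier_high` (strict
#' inequalities: values equal to the bounds are retained), restricts to the
#' study year, and keeps the latest measure per patient.
#'
#' @param observations observation tibble (heights already carried forward).
#' @param year study year.
#' @param outlier_low,outlier_high plausibility bounds in kg/m2.
#' @return tibble of `PatientYearRecord`s: `patient_id`, `sex`, `age`,
#'   `age_group`, `bmi`, `bmi_category`, `postal_code` (plus any chronic
#'   disease flag columns present).  Patients with no surviving valid
#'   measure are absent.
#' @export
select_final_bmi <- function(observations, year,
                             outlier_low = 15, outlier_high = 50) {
  obs <- dplyr::distinct(observations)
  obs <- obs[!is.na(obs$height) & !is.na(obs$weight), , drop = FALSE]
  obs$bmi <- compute_bmi(obs$weight, obs$height)
  obs <- obs[obs$bmi >= outlier_low & obs$bmi <= outlier_high, ,
             drop = FALSE]
  obs <- obs[format(as.Date(obs$observation_date), "%Y") == as.character(year), ,
             drop = FALSE]
  if (nrow(obs) == 0) return(patient_year_skeleton(obs))
  final <- obs %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::arrange(.data$observation_date, .by_group = TRUE) %>%
    dplyr::slice_tail(n = 1) %>%
    dplyr::ungroup()
  patient_year_skeleton(final, year)
}

patient_year_skeleton <- function(obs, year = NA_integer_) {
  keep_flags <- intersect(DISEASE_FLAGS, names(obs))
  out <- tibble::tibble(
    patient_id = obs$patient_id,
    sex = obs$sex,
    age = age_at_year_end(obs$birth_date, year),
    bmi = obs$bmi,
    bmi_category = categorize_bmi(obs$bmi),
    postal_code = obs$postal_code)
  out$age_group <- age_group_of(out$age)
  out <- out[, c("patient_id", "sex", "age", "age_group", "bmi",
                 "bmi_category", "postal_code")]
  dplyr::bind_cols(out, obs[, keep_flags, drop = FALSE])
}

#' Flag patients with inconsistent repeat BMI measures
#'
#' Among patients with two or more in-year BMI values, computes each
#' patient's BMI range (max minus min) and flags those whose range strictly
#' exceeds `multiplier` standard deviations, where the SD scale is set by
#' the chosen strategy:
#'
#' * `"cohort_bmi_sd"` (default): the SD of all in-year BMI measurements in
#'   the cohort.  A patient is flagged when their own measures span more
#'   than `multiplier` cohort-SDs of BMI — the kind of rare, internally
#'   inconsistent series produced by unit or data-entry errors.  Ordinary
#'   measurement noise (a fraction of a BMI unit) sits far below the
#'   threshold, so only a handful of patients are ever flagged.
#' * `"range_sd"`: the SD of the per-patient ranges themselves.  Because
#'   i.i.d. measurement noise concentrates ranges around their mean, this
#'   scale can fall below typical ranges and flag large parts of a cohort;
#'   it is kept as an alternative strategy, not the default.
#'
#' With fewer than two multi-measure patients nothing is flagged.
#'
#' @param bmi_series tibble with `patient_id` and `bmi` (one row per
#'   in-year measure).
#' @param multiplier threshold multiple of the strategy's SD.
#' @param strategy `"cohort_bmi_sd"` or `"range_sd"`.
#' @return character vector of flagged patient ids.
#' @export
exclude_high_within_patient_variation <- function(bmi_series,
                                                  multiplier = 2,
                                                  strategy =
                                                    c("cohort_bmi_sd",
                                                      "range_sd")) {
  strategy <- match.arg(strategy)
  ranges <- bmi_series %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(n = dplyr::n(),
                     range = max(.data$bmi) - min(.data$bmi),
                     .groups = "drop") %>%
    dplyr::filter(.data$n >= 2)
  if (nrow(ranges) < 2) return(character(0))
  scale_sd <- switch(strategy,
                     cohort_bmi_sd = sd(bmi_series$bmi),
                     range_sd = sd(ranges$range))
  if (!is.finite(scale_sd)) return(character(0))
  threshold <- multiplier * scale_sd
  ranges$patient_id[ranges$range > threshold]
}

# Pearson chi-square on a 2x2 success/failure split of two cohorts
two_by_two <- function(x1, n1, x2, n2) {
  pearson_chi_square(matrix(c(x1, n1 - x1, x2, n2 - x2),
                            nrow = 2, byrow = TRUE))
}

#' Compare patients with and without a usable BMI
#'
#' For each chronic-disease flag, a 2x2 Pearson chi-square between the two
#' cohorts; for age, a two-sample Welch (unequal-variance) t-test.  Used to
#' judge whether dropping patients without a BMI record biases the sample.
#'
#' @param with_bmi,without_bmi patient-level tibbles, each with an `age`
#'   column and 0/1 chronic-disease flag columns.
#' @param flags names of the flag columns to compare; defaults to the
#'   flags present in both tables.
#' @return tibble with one row per variable: cohort summaries (percentage
#'   for flags, mean for age), test statistic, df and p-value.
#' @export
compare_missingness_cohorts <- function(with_bmi, without_bmi,
                                        flags = NULL) {
  if (nrow(with_bmi) == 0 || nrow(without_bmi) == 0) {
    stop("both cohorts must be non-empty", call. = FALSE)
  }
  if (is.null(flags)) {
    flags <- intersect(intersect(DISEASE_FLAGS, names(with_bmi)),
                       names(without_bmi))
  }
  n1 <- nrow(with_bmi)
  n2 <- nrow(without_bmi)
  rows <- lapply(flags, function(f) {
    x1 <- sum(with_bmi[[f]] > 0)
    x2 <- sum(without_bmi[[f]] > 0)
    ct <- two_by_two(x1, n1, x2, n2)
    tibble::tibble(variable = f, test = "chi-square",
                   value_with_bmi = round(100 * x1 / n1, 1),
                   value_without_bmi = round(100 * x2 / n2, 1),
                   statistic = ct$statistic, df = ct$df,
                   p_value = ct$p_value)
  })
  tt <- welch_t(with_bmi$age, without_bmi$age)
  rows <- c(rows, list(tibble::tibble(
    variable = "age", test = "t-test",
    value_with_bmi = mean(with_bmi$age),
    value_without_bmi = mean(without_bmi$age),
    statistic = tt$statistic, df = tt$df, p_value = tt$p_value)))
  dplyr::bind_rows(rows)
}

# Welch two-sample t; degenerate zero-variance case handled explicitly
welch_t <- function(x, y) {
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / length(x) + v2 / length(y)
  if (se2 == 0) {
    return(list(statistic = 0, df = NA_real_,
                p_value = if (m1 == m2) 1 else 0))
  }
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / length(x))^2 / (length(x) - 1) +
                 (v2 / length(y))^2 / (length(y) - 1))
  list(statistic = stat, df = df,
       p_value = 2 * pt(-abs(stat), df))
}

#' Run the full cleaning cascade
#'
#' Applies, in order: restriction to in-study-year observations of adults
#' (age >= 20 at year end); exact-duplicate removal; pregnancy-window
#' exclusion; last-height carry-forward; removal of rows missing height or
#' weight; BMI plausibility bounds; the within-patient variation screen;
#' and finally selection of the latest in-year measure per patient.  The
#' attrition report counts, per step, how many patients were lost and how
#' many remain; counts telescope.
#'
#' @param observations visit-level observation tibble (see the data
#'   dictionary in `inst/extdata`).
#' @param year study year.
#' @param min_age minimum age at year end.
#' @param outlier_low,outlier_high BMI plausibility bounds (strict).
#' @param variation_multiplier SD multiple beyond which a patient's repeat
#'   measures are deemed inconsistent.
#' @param variation_strategy SD scale for the variation screen; see
#'   [exclude_high_within_patient_variation()].
#' @return list of class `bmi_cascade` with
#'   `patients` (one `PatientYearRecord` per retained patient),
#'   `attrition` (tibble `step`, `patients_removed`, `patients_remaining`,
#'   `rows_removed`),
#'   `observations` (the rows backing the final selection), and
#'   `excluded` (tibble `patient_id`, `step` for every dropped patient).
#' @export
#' @examples
#' b <- generate_bundle(sim_config(n_patients = 60, seed = 3))
#' cc <- run_cascade(b$observations, year = 2011)
#' cc$attrition
run_cascade <- function(observations, year = 2011, min_age = 20,
                        outlier_low = 15, outlier_high = 50,
                        variation_multiplier = 2,
                        variation_strategy = "cohort_bmi_sd") {
  steps <- list()
  excluded <- list()
  note_step <- function(name, before, after, rows_removed) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      step = name,
      patients_removed = length(before) - length(after),
      patients_remaining = length(after),
      rows_removed = rows_removed)
    lost <- setdiff(before, after)
    if (length(lost)) {
      excluded[[length(excluded) + 1L]] <<-
        tibble::tibble(patient_id = lost, step = name)
    }
  }
  pats <- function(x) unique(x$patient_id)

  obs <- tibble::as_tibble(observations)
  p0 <- pats(obs)
  steps[[1]] <- tibble::tibble(step = "extracted", patients_removed = 0L,
                               patients_remaining = length(p0),
                               rows_removed = 0L)

  # adults with an in-year observation
  age <- age_at_year_end(obs$birth_date, year)
  in_year <- format(as.Date(obs$observation_date), "%Y") == as.character(year)
  obs1 <- obs[!is.na(age) & age >= min_age & in_year, , drop = FALSE]
  note_step("eligibility", p0, pats(obs1), nrow(obs) - nrow(obs1))

  # exact-duplicate rows
  obs2 <- dplyr::distinct(obs1)
  note_step("duplicates", pats(obs1), pats(obs2), nrow(obs1) - nrow(obs2))

  # pregnancy exclusion window
  obs3 <- exclude_pregnancy_window(obs2)
  note_step("pregnancy_window", pats(obs2), pats(obs3),
            nrow(obs2) - nrow(obs3))

  # carry heights forward, then drop rows still missing either measure
  obs4 <- carry_forward_height(obs3)
  obs5 <- obs4[!is.na(obs4$height) & !is.na(obs4$weight), , drop = FALSE]
  note_step("missing_measures", pats(obs4), pats(obs5),
            nrow(obs4) - nrow(obs5))

  # plausibility bounds on per-row BMI
  bmi <- compute_bmi(obs5$weight, obs5$height)
  keep <- bmi >= outlier_low & bmi <= outlier_high
  obs6 <- obs5[keep, , drop = FALSE]
  note_step("bmi_outliers", pats(obs5), pats(obs6), sum(!keep))

  # within-patient variation screen
  series <- tibble::tibble(patient_id = obs6$patient_id,
                           bmi = compute_bmi(obs6$weight, obs6$height))
  flagged <- exclude_high_within_patient_variation(
    series, multiplier = variation_multiplier,
    strategy = variation_strategy)
  obs7 <- obs6[!obs6$patient_id %in% flagged, , drop = FALSE]
  note_step("bmi_variation", pats(obs6), pats(obs7),
            nrow(obs6) - nrow(obs7))

  patients <- select_final_bmi(obs7, year,
                               outlier_low = outlier_low,
                               outlier_high = outlier_high)
  final_rows <- dplyr::semi_join(obs7, patients, by = "patient_id")

  structure(list(patients = patients,
                 attrition = dplyr::bind_rows(steps),
                 observations = final_rows,
                 excluded = if (length(excluded)) dplyr::bind_rows(excluded)
                            else tibble::tibble(patient_id = character(0),
                                                step = character(0))),
            class = "bmi_cascade")
}

#' @export
print.bmi_cascade <- function(x, ...) {
  cat("<bmi_cascade> ", nrow(x$patients), " patients retained\n", sep = "")
  print(x$attrition)
  invisible(x)
}
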