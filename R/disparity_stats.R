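# Prevalences, Pearson chi-square tests and disparity summary measures
# (simple differences and rate ratios against the least-deprived quintile),
# with age and urban/rural stratification.

#' Prevalence as a percentage
#'
#' @param numerator count with the condition.
#' @param denominator total count (> 0).
#' @param digits decimals to report (default 1).
#' @return percentage, rounded.
#' @export
#' @examples
#' prevalence(1589, 5022)
prevalence <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("numerator must lie in [0, denominator]", call. = FALSE)
  }
  round(100 * numerator / denominator, digits)
}

#' Pearson chi-square test of independence
#'
#' Computes the Pearson statistic sum((O - E)^2 / E) with expected counts
#' from the margins, df = (rows - 1) (cols - 1), and the upper-tail
#' chi-square p-value.  No continuity correction is applied (set
#' `correct = TRUE` for the Yates-corrected 2x2 statistic).
#'
#' @param x contingency table: matrix, table, or data frame of
#'   non-negative counts with at least two rows and columns.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return list of class `pearson_chisq`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`.
#' @export
#' @examples
#' pearson_chi_square(matrix(c(30, 70, 50, 50), nrow = 2, byrow = TRUE))
pearson_chi_square <- function(x, correct = FALSE) {
  obs <- as.matrix(x)
  if (any(is.na(obs)) || any(obs < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (nrow(obs) < 2 || ncol(obs) < 2) {
    stop("table must be at least 2x2", call. = FALSE)
  }
  rs <- rowSums(obs)
  cs <- colSums(obs)
  if (any(rs == 0) || any(cs == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(obs)
  if (any(expected <= 0)) stop("expected counts must be > 0", call. = FALSE)
  dev <- abs(obs - expected)
  if (correct) {
    if (!all(dim(obs) == c(2, 2))) {
      stop("continuity correction applies to 2x2 tables only",
           call. = FALSE)
    }
    dev <- pmax(dev - 0.5, 0)
  }
  statistic <- sum(dev^2 / expected)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  structure(list(statistic = statistic, df = df,
                 p_value = pchisq(statistic, df, lower.tail = FALSE),
                 observed = obs, expected = expected),
            class = "pearson_chisq")
}

#' @export
print.pearson_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square = %.4g (%d df), p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Absolute and relative disparity against the least-deprived quintile
#'
#' For per-quintile prevalences, computes the simple difference (percentage
#' points, one decimal) and the disparity rate ratio (two decimals) against
#' the reference quintile.  The reference row is exactly (0, 1.00).
#'
#' @param prevalences numeric vector of quintile prevalences in percent,
#'   ordered from least (first) to most deprived.
#' @param reference index of the reference (best-rate) group; default 1,
#'   the least deprived.
#' @return `DisparityTable` tibble: `quintile`, `prevalence`,
#'   `simple_difference`, `rate_ratio`.
#' @export
#' @examples
#' disparity_measures(c(27.9, 36.6, 38.0, 39.6, 44.4))
disparity_measures <- function(prevalences, reference = 1) {
  if (length(prevalences) < 2) {
    stop("need at least two quintile prevalences", call. = FALSE)
  }
  ref <- prevalences[reference]
  if (is.na(ref) || ref <= 0) {
    stop("reference prevalence must be > 0", call. = FALSE)
  }
  tibble::tibble(
    quintile = seq_along(prevalences),
    prevalence = prevalences,
    simple_difference = round(prevalences - ref, 1),
    rate_ratio = round(prevalences / ref, 2))
}

#' Most- versus least-deprived quintile test
#'
#' One-df Pearson chi-square on the 2x2 obese/non-obese by Q1/Q5 table,
#' with the relative excess (percent) and absolute difference (percentage
#' points) of the most-deprived prevalence over the least-deprived.
#'
#' @param q1,q5 length-2 vectors `c(obese, total)` for the least- and
#'   most-deprived quintiles.
#' @param correct continuity correction flag, passed to
#'   [pearson_chi_square()].
#' @return list: `statistic`, `df` (1), `p_value`, `relative_pct`,
#'   `absolute_pp`.
#' @export
#' @examples
#' extreme_quintile_test(c(28, 100), c(38, 100))
extreme_quintile_test <- function(q1, q5, correct = FALSE) {
  stopifnot(length(q1) == 2, length(q5) == 2)
  if (q1[2] <= 0 || q5[2] <= 0) stop("totals must be > 0", call. = FALSE)
  ct <- pearson_chi_square(
    matrix(c(q1[1], q1[2] - q1[1], q5[1], q5[2] - q5[1]),
           nrow = 2, byrow = TRUE), correct = correct)
  p1 <- 100 * q1[1] / q1[2]
  p5 <- 100 * q5[1] / q5[2]
  list(statistic = ct$statistic, df = ct$df, p_value = ct$p_value,
       relative_pct = 100 * (p5 / p1 - 1),
       absolute_pp = p5 - p1)
}

#' Obesity-by-quintile analysis within strata
#'
#' Splits linked patients by age group or urban/rural status and, within
#' each stratum, tabulates obese patients by deprivation quintile.  Cell
#' percentages are each quintile's share of the stratum's obese patients
#' (cell / stratum obese total).  A within-stratum Pearson chi-square on
#' the quintile-by-obese/non-obese table gives the p-value; strata where
#' any expected cell falls below 5, or where fewer than two quintiles are
#' occupied (no test possible), are flagged as low power.
#'
#' @param patients `PatientYearRecord` tibble with `bmi_category` and
#'   `age_group`.
#' @param assignments quintile assignments from [assign_quintiles()].
#' @param stratify `"age"` or `"urbanrural"`.
#' @param index deprivation component: `"combined"`, `"material"` or
#'   `"social"`.
#' @return tibble, one row per stratum: `stratum`, `n`, `n_obese`, obese
#'   counts `q1`..`q5`, percentages `q1_pct`..`q5_pct`, `statistic`, `df`,
#'   `p_value`, `low_power`.
#' @export
stratified_analysis <- function(patients, assignments,
                                stratify = c("age", "urbanrural"),
                                index = c("combined", "material",
                                          "social")) {
  stratify <- match.arg(stratify)
  index <- match.arg(index)
  qcol <- paste0(index, "_q")
  dat <- dplyr::inner_join(patients, assignments, by = "patient_id")
  if (nrow(dat) == 0) stop("no linked patients", call. = FALSE)
  dat$obese <- dat$bmi_category == "obese"
  dat$quintile <- dat[[qcol]]
  dat$stratum <- if (stratify == "age") {
    as.character(dat$age_group)
  } else {
    ifelse(dat$urban, "urban", "rural")
  }
  expected_levels <- if (stratify == "age") AGE_GROUPS
                     else c("urban", "rural")
  missing_strata <- setdiff(expected_levels, unique(dat$stratum))
  if (length(missing_strata)) {
    warning("empty strata omitted: ",
            paste(missing_strata, collapse = ", "), call. = FALSE)
  }

  one_stratum <- function(d, label) {
    counts <- vapply(1:5, function(q) sum(d$obese & d$quintile == q),
                     integer(1))
    n_obese <- sum(counts)
    tab <- table(factor(d$quintile, levels = 1:5), d$obese)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    testable <- nrow(tab) >= 2 && ncol(tab) >= 2 && n_obese > 0
    ct <- if (testable) pearson_chi_square(tab) else NULL
    low_power <- !testable ||
      any(ct$expected < 5)
    out <- tibble::tibble(
      stratum = label, n = nrow(d), n_obese = n_obese,
      statistic = if (testable) ct$statistic else NA_real_,
      df = if (testable) ct$df else NA_integer_,
      p_value = if (testable) ct$p_value else NA_real_,
      low_power = low_power)
    for (q in 1:5) out[[paste0("q", q)]] <- counts[q]
    for (q in 1:5) {
      out[[paste0("q", q, "_pct")]] <-
        if (n_obese > 0) prevalence(counts[q], n_obese) else NA_real_
    }
    out
  }

  present <- intersect(expected_levels, unique(dat$stratum))
  rows <- lapply(present, function(s) {
    one_stratum(dat[dat$stratum == s, , drop = FALSE], s)
  })
  res <- dplyr::bind_rows(rows)
  res[, c("stratum", "n", "n_obese", paste0("q", 1:5),
          paste0("q", 1:5, "_pct"), "statistic", "df", "p_value",
          "low_power")]
}
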