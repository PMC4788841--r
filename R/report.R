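# Human-readable study outputs: sample-distribution table, stratified
# obesity tables, disparity tables, attrition narrative, and small-cell-
# suppressed per-area aggregates for external mapping.

#' Check cross-table consistency of study outputs
#'
#' Asserts that every printed margin is recomputable from its cells: BMI
#' category counts sum to the sample size, and each stratified table's
#' obese cells sum to the overall obese count.  Errors loudly on any
#' violation; silently returns `TRUE` otherwise.
#'
#' @param bmi_counts counts by BMI category (underweight, normal,
#'   overweight, obese).
#' @param sample_size total sample size the category counts must sum to.
#' @param stratified optional named list of matrices/vectors of per-stratum
#'   obese counts by quintile.
#' @param total_obese overall obese count every stratified table must sum
#'   to; defaults to the last element of `bmi_counts`.
#' @return `TRUE`, invisibly.
#' @export
#' @examples
#' validate_study_tables(c(91, 1700, 1642, 1589), 5022)
validate_study_tables <- function(bmi_counts, sample_size,
                                  stratified = NULL,
                                  total_obese = NULL) {
  if (sum(bmi_counts) != sample_size) {
    stop("BMI category counts (", sum(bmi_counts),
         ") do not sum to the sample size (", sample_size, ")",
         call. = FALSE)
  }
  if (is.null(total_obese)) total_obese <- bmi_counts[length(bmi_counts)]
  for (nm in names(stratified)) {
    s <- sum(stratified[[nm]])
    if (s != total_obese) {
      stop("stratified table '", nm, "' obese cells sum to ", s,
           " but the overall obese count is ", total_obese, call. = FALSE)
    }
  }
  invisible(TRUE)
}

count_pct <- function(x, levels, total) {
  counts <- vapply(levels, function(l) sum(x == l, na.rm = TRUE),
                   integer(1))
  tibble::tibble(category = as.character(levels), n = counts,
                 pct = prevalence(counts, total))
}

#' Assemble the study report
#'
#' Builds the report object backing the printed study tables: sample
#' distribution by sex, age band, deprivation quintile and BMI category;
#' the attrition narrative; the stratified obesity tables; per-index
#' disparity tables; and small-cell-suppressed per-area aggregates.
#' Cross-table consistency (category counts summing to the sample size,
#' stratified obese counts summing to the overall obese count) is asserted
#' on every build and fails loudly.
#'
#' @param patients `PatientYearRecord` tibble.
#' @param assignments quintile assignments from [assign_quintiles()];
#'   every assignment's patient id must appear in `patients`.
#' @param attrition optional attrition tibble from [run_cascade()].
#' @param stratified optional named list of [stratified_analysis()]
#'   results computed on the same patients.
#' @param k small-cell suppression threshold for the per-area aggregates;
#'   reuses the de-identification group-size threshold so the privacy
#'   contract holds end-to-end.
#' @return list of class `study_report`.
#' @export
build_report <- function(patients, assignments, attrition = NULL,
                         stratified = NULL, k = 5) {
  if (!all(assignments$patient_id %in% patients$patient_id)) {
    stop("assignments reference patient ids absent from patients",
         call. = FALSE)
  }
  linked <- dplyr::inner_join(patients, assignments, by = "patient_id")
  n <- nrow(linked)
  decade <- cut(linked$age, c(-Inf, 29, 39, 49, 59, 69, 79, Inf),
                labels = AGE_BANDS)

  bmi_tab <- count_pct(linked$bmi_category, BMI_CATEGORIES, n)
  distribution <- list(
    n = n,
    sex = count_pct(linked$sex, c("female", "male"), n),
    age_band = count_pct(decade, AGE_BANDS, n),
    material_quintile = count_pct(linked$material_q, 1:5, n),
    social_quintile = count_pct(linked$social_q, 1:5, n),
    combined_quintile = count_pct(linked$combined_q, 1:5, n),
    bmi_category = bmi_tab)

  strat_cells <- lapply(stratified, function(s) {
    as.matrix(s[, paste0("q", 1:5)])
  })
  validate_study_tables(bmi_tab$n, n, strat_cells,
                        total_obese = sum(linked$bmi_category == "obese"))

  disparity <- lapply(c(material = "material_q", social = "social_q",
                        combined = "combined_q"), function(qcol) {
    by_q <- vapply(1:5, function(q) {
      idx <- linked[[qcol]] == q
      if (!any(idx)) return(NA_real_)
      prevalence(sum(linked$bmi_category[idx] == "obese"), sum(idx))
    }, numeric(1))
    disparity_measures(by_q)
  })

  structure(list(distribution = distribution,
                 attrition = attrition,
                 stratified = stratified,
                 disparity = disparity,
                 area_aggregates =
                   export_area_aggregates(patients, assignments, k = k),
                 k = k),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  d <- x$distribution
  obese <- d$bmi_category[d$bmi_category$category == "obese", ]
  cat("<study_report> n = ", d$n,
      "; obese ", obese$n, " (", obese$pct, " %)\n", sep = "")
  cat("Combined-quintile obesity disparity:\n")
  print(x$disparity$combined)
  invisible(x)
}

#' Per-area obesity aggregates for external mapping
#'
#' One row per dissemination area with its patient count and obesity
#' percentage; areas with fewer than `k` patients are suppressed, reusing
#' the de-identification group-size threshold.
#'
#' @param patients `PatientYearRecord` tibble.
#' @param assignments quintile assignments carrying `area_id`.
#' @param k suppression threshold (>= 2).
#' @return tibble `area_id`, `n`, `n_obese`, `obese_pct` (one decimal);
#'   empty (with columns) when every area falls below `k`.
#' @export
export_area_aggregates <- function(patients, assignments, k = 5) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  linked <- dplyr::inner_join(patients, assignments, by = "patient_id")
  agg <- linked %>%
    dplyr::group_by(.data$area_id) %>%
    dplyr::summarise(n = dplyr::n(),
                     n_obese = sum(.data$bmi_category == "obese"),
                     .groups = "drop") %>%
    dplyr::filter(.data$n >= k) %>%
    dplyr::mutate(obese_pct = prevalence(.data$n_obese, .data$n)) %>%
    dplyr::arrange(.data$area_id)
  agg
}
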