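# End-to-end convenience wrapper: synthetic (or supplied) tables ->
# scrubbed notes -> cleaning cascade -> geographic linkage -> quintile
# assignment -> disparity analyses -> report.

#' Run the full linkage study
#'
#' Chains every pipeline stage on a synthetic bundle (or a configuration
#' from which one is generated): free-text scrubbing and a
#' re-identification audit, the BMI cleaning cascade, postal-code linkage
#' and regional quintile assignment, the quintile-by-BMI-category
#' chi-square (12 df for 5 quintiles by 4 categories), the most- versus
#' least-deprived test, per-index disparity tables, age and urban/rural
#' stratified analyses, and the assembled report.
#'
#' Quasi-identifier generalization ([generalize_until_k()]) is not applied
#' inside the analysis flow — the analysis runs on the full postal codes
#' held within the trusted repository, and generalization is for data
#' release — but the audit of the released patient-year table is included.
#'
#' @param x a [sim_config()] or a `synthetic_bundle`; equivalently, any
#'   list with `observations`, `conversion`, `deprivation` tibbles (a
#'   `truth` table, if present, is ignored here).
#' @param k group-size threshold reused for the audit and for small-cell
#'   suppression in the report.
#' @param ... passed on to [run_cascade()] (e.g. `year`, outlier bounds).
#' @return list of class `emr_study`: `cascade`, `audit`, `links`,
#'   `linkage` (assignments/losses/breaks), `chi12`, `extreme`,
#'   `disparity`, `stratified`, `report`, `config`.
#' @export
#' @examples
#' study <- run_study(sim_config(n_patients = 300, seed = 11))
#' study$report$disparity$combined
run_study <- function(x, k = 5, ...) {
  if (inherits(x, "sim_config")) x <- generate_bundle(x)
  config <- x$config
  year <- if (!is.null(config)) config$year else 2011

  obs <- x$observations
  policy <- anonymization_policy(k = k)
  if ("note" %in% names(obs)) {
    obs$note <- scrub_free_text(obs$note, policy)
  }

  cascade <- run_cascade(obs, year = year, ...)
  patients <- cascade$patients
  audit <- reidentification_audit(patients, policy)

  links <- link_postal_to_area(patients$postal_code, x$conversion)
  linkage <- assign_quintiles(patients, links, x$deprivation)
  assignments <- linkage$assignments
  linked <- dplyr::inner_join(patients, assignments, by = "patient_id")

  chi12 <- pearson_chi_square(table(linked$combined_q,
                                    linked$bmi_category))
  q1 <- linked[linked$combined_q == 1, ]
  q5 <- linked[linked$combined_q == 5, ]
  extreme <- extreme_quintile_test(
    c(sum(q1$bmi_category == "obese"), nrow(q1)),
    c(sum(q5$bmi_category == "obese"), nrow(q5)))

  stratified <- list(
    age = stratified_analysis(patients, assignments, "age", "combined"),
    urbanrural = stratified_analysis(patients, assignments, "urbanrural",
                                     "combined"))
  report <- build_report(patients, assignments,
                         attrition = cascade$attrition,
                         stratified = stratified, k = k)

  structure(list(cascade = cascade, audit = audit, links = links,
                 linkage = linkage, chi12 = chi12, extreme = extreme,
                 disparity = report$disparity, stratified = stratified,
                 report = report, config = config),
            class = "emr_study")
}

#' @export
print.emr_study <- function(x, ...) {
  d <- x$report$distribution
  obese <- d$bmi_category[d$bmi_category$category == "obese", ]
  cat("<emr_study> final sample n = ", d$n, "\n",
      "  obesity prevalence: ", obese$pct, " %\n", sep = "")
  cat(sprintf("  quintile x BMI-category chi-square = %.2f (%d df), p = %.3g\n",
              x$chi12$statistic, x$chi12$df, x$chi12$p_value))
  cat(sprintf("  most vs least deprived: chi-square = %.2f (1 df), %+.1f %% relative, %+.1f pp absolute\n",
              x$extreme$statistic, x$extreme$relative_pct,
              x$extreme$absolute_pp))
  invisible(x)
}
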