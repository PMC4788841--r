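# Postal-code linkage to census dissemination areas and regional
# deprivation quintiles.  Quintiles are computed over in-region areas
# (unweighted), rescaling the deprivation index to the study region's
# boundary: an area is "most deprived" relative to the region, not the
# province.

POSTAL_FULL_RE <- "^[A-Za-z][0-9][A-Za-z][0-9][A-Za-z][0-9]$"
POSTAL_PREFIX_RE <- c(
  "3" = "^[A-Za-z][0-9][A-Za-z]$",
  "4" = "^[A-Za-z][0-9][A-Za-z][0-9]$",
  "5" = "^[A-Za-z][0-9][A-Za-z][0-9][A-Za-z]$")

#' Link postal codes to dissemination areas
#'
#' Full 6-character codes are matched exactly against the conversion table.
#' Generalized codes (3-5 leading characters, as produced by
#' [generalize_until_k()]) are matched by prefix and resolve only when all
#' candidate codes agree on one area; otherwise they are ambiguous.
#' Malformed or missing codes are counted as erroneous, never raised.
#'
#' @param postal_code character vector of (possibly generalized) codes.
#' @param conversion conversion tibble with `postal_code`, `area_id`,
#'   `urban`, `in_region`.
#' @return tibble, one row per input code in order: `postal_code`,
#'   `area_id`, `urban`, `in_region`, and `status` in
#'   `linked` / `out_of_region` / `unmatched` / `ambiguous` / `erroneous`.
#' @export
link_postal_to_area <- function(postal_code, conversion) {
  lookup_one <- function(code) {
    unresolved <- tibble::tibble(area_id = NA_character_, urban = NA,
                                 in_region = NA, status = "erroneous")
    if (is.na(code) || !nzchar(code)) return(unresolved)
    nc <- nchar(code)
    if (nc == 6 && grepl(POSTAL_FULL_RE, code)) {
      hit <- conversion[conversion$postal_code == code, , drop = FALSE]
      if (nrow(hit) == 0) {
        return(tibble::tibble(area_id = NA_character_, urban = NA,
                              in_region = NA, status = "unmatched"))
      }
      return(tibble::tibble(
        area_id = hit$area_id[1], urban = hit$urban[1],
        in_region = hit$in_region[1],
        status = if (hit$in_region[1]) "linked" else "out_of_region"))
    }
    if (nc >= 3 && nc <= 5 &&
        grepl(POSTAL_PREFIX_RE[[as.character(nc)]], code)) {
      hit <- conversion[startsWith(conversion$postal_code, code), ,
                        drop = FALSE]
      if (nrow(hit) == 0) {
        return(tibble::tibble(area_id = NA_character_, urban = NA,
                              in_region = NA, status = "unmatched"))
      }
      if (length(unique(hit$area_id)) > 1) {
        return(tibble::tibble(area_id = NA_character_, urban = NA,
                              in_region = NA, status = "ambiguous"))
      }
      return(tibble::tibble(
        area_id = hit$area_id[1], urban = hit$urban[1],
        in_region = hit$in_region[1],
        status = if (hit$in_region[1]) "linked" else "out_of_region"))
    }
    unresolved
  }
  codes <- as.character(postal_code)
  uniq <- unique(codes)
  per_code <- dplyr::bind_rows(lapply(uniq, lookup_one))
  per_code$postal_code <- uniq
  out <- per_code[match(codes, uniq),
                  c("postal_code", "area_id", "urban", "in_region",
                    "status")]
  out$postal_code <- codes
  tibble::as_tibble(out)
}

#' Regional quintile breakpoints for a deprivation score
#'
#' Breakpoints at the 20/40/60/80th percentiles of the in-region area
#' scores, unweighted by population.  A score exactly equal to a breakpoint
#' falls in the lower quintile.
#'
#' @param scores per-area deprivation scores (in-region areas only).
#' @return numeric vector of 4 breakpoints.
#' @export
#' @examples
#' regional_quintiles(1:100)
regional_quintiles <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(unique(scores)) < 5) {
    stop("need at least 5 distinct in-region area scores", call. = FALSE)
  }
  unname(quantile(scores, c(0.2, 0.4, 0.6, 0.8)))
}

#' Assign quintiles from breakpoints
#'
#' Quintile 1 holds scores at or below the first breakpoint (ties at a
#' breakpoint take the lower quintile); quintile 5 holds scores strictly
#' above the fourth.
#'
#' @param x numeric scores.
#' @param breaks breakpoints from [regional_quintiles()].
#' @return integer quintiles 1-5 (1 least deprived, 5 most deprived).
#' @export
quintile_assign <- function(x, breaks) {
  stopifnot(length(breaks) == 4)
  1L + rowSums(outer(x, breaks, ">"))
}

#' Attach deprivation quintiles to linked patients
#'
#' Computes regional quintile breakpoints for the material, social and
#' combined scores over the in-region areas of the deprivation table, then
#' assigns each successfully linked patient the quintiles of their area.
#' Patients whose link failed, or whose area carries no deprivation score,
#' are excluded and counted.
#'
#' @param patients `PatientYearRecord` tibble (from [run_cascade()]).
#' @param links linkage tibble from [link_postal_to_area()], row-aligned
#'   with `patients`.
#' @param deprivation area table with `area_id`, `material_score`,
#'   `social_score`, `combined_score` (optionally `in_region`, used to
#'   restrict the breakpoint computation).
#' @return list with `assignments` (tibble `patient_id`, `area_id`,
#'   `urban`, `material_q`, `social_q`, `combined_q`), `losses` (tibble
#'   `reason`, `n` for every excluded patient), and `breaks` (list of the
#'   three breakpoint vectors).
#' @export
assign_quintiles <- function(patients, links, deprivation) {
  stopifnot(nrow(patients) == nrow(links))
  dep <- deprivation
  if ("in_region" %in% names(dep)) dep <- dep[as.logical(dep$in_region), ]
  breaks <- list(
    material = regional_quintiles(dep$material_score),
    social = regional_quintiles(dep$social_score),
    combined = regional_quintiles(dep$combined_score))

  joined <- tibble::tibble(patient_id = patients$patient_id,
                           area_id = links$area_id,
                           urban = links$urban,
                           status = links$status)
  linked <- joined[joined$status == "linked", , drop = FALSE]
  linked <- dplyr::left_join(linked, dep, by = "area_id",
                             suffix = c("", ".area"))
  unscored <- is.na(linked$material_score)

  losses <- dplyr::count(joined[joined$status != "linked", ], .data$status,
                         name = "n")
  losses <- tibble::tibble(reason = losses$status, n = losses$n)
  if (any(unscored)) {
    losses <- dplyr::bind_rows(
      losses, tibble::tibble(reason = "no_deprivation_score",
                             n = sum(unscored)))
  }

  scored <- linked[!unscored, , drop = FALSE]
  assignments <- tibble::tibble(
    patient_id = scored$patient_id,
    area_id = scored$area_id,
    urban = as.logical(scored$urban),
    material_q = quintile_assign(scored$material_score, breaks$material),
    social_q = quintile_assign(scored$social_score, breaks$social),
    combined_q = quintile_assign(scored$combined_score, breaks$combined))

  list(assignments = assignments, losses = losses, breaks = breaks)
}
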