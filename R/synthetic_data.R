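# Seeded synthetic versions of the three study tables: visit-level EMR
# observations, postal-code conversion, and dissemination-area deprivation
# scores.  A separate truth table records each patient's planted obesity
# status, deprivation quintile and injected defects; pipeline stages never
# see it.

DISEASE_FLAGS <- c("diabetes", "hypertension", "osteoarthritis", "depression",
                   "copd", "dementia", "parkinsons", "epilepsy")

AGE_BANDS <- c("20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80+")

#' Configuration for the synthetic study generator
#'
#' Defines the study conditions the generator emulates: cohort size and
#' demographics, visit intensity, the planted deprivation-to-obesity
#' prevalence gradient, and the rates at which realistic data defects
#' (duplicates, missing measures, outliers, pregnancy episodes, bad postal
#' codes) are injected.  Defaults follow the characteristics of a
#' single-site adult primary-care sample in 2011: 60 % female, the observed
#' adult age mix, roughly 4 visits per patient, 4 % pregnancy episodes,
#' 14 % of patients with missing heights or weights, 0.9 % implausible BMI
#' values, 9 % out-of-region/erroneous postal codes and a further 5 % of
#' codes that resolve to an area without a deprivation score.
#'
#' @param n_patients number of unique patients to simulate.
#' @param year calendar study year; all visits fall inside it.
#' @param seed integer seed; identical config + seed gives identical output.
#' @param sex_ratio proportion of patients who are female.
#' @param age_distribution proportions over the seven age bands
#'   20-29, 30-39, ..., 70-79, 80+; must sum to 1.
#' @param visits_per_patient mean number of visits (>= 1; 1 plus a Poisson).
#' @param quintile_obesity_prevalence length-5 vector of true obesity
#'   prevalence by combined-deprivation quintile (1 = least deprived).
#' @param missing_height_rate,missing_weight_rate proportion of patients
#'   whose height (resp. weight) is never recorded.
#' @param duplicate_rate proportion of observation rows duplicated verbatim.
#' @param outlier_rate proportion of patients whose BMI is implausible
#'   (outside the 15-50 kg/m2 plausibility bounds).
#' @param pregnancy_rate proportion of patients (taken among females) with a
#'   pregnancy episode whose exclusion window covers their in-year visits.
#' @param out_of_region_postal_rate proportion of patients whose postal code
#'   is outside the study region, malformed, or missing.
#' @param unmatched_da_rate proportion of patients whose (in-region) postal
#'   code resolves to a dissemination area with no deprivation score.
#' @param bmi_noise_sd within-patient, visit-to-visit BMI measurement noise
#'   (kg/m2).
#' @param n_dissemination_areas number of in-region, scored dissemination
#'   areas.
#' @param urban_fraction proportion of areas flagged urban.
#' @param mean_height,sd_height named (`female`, `male`) means and SDs of
#'   patient height in metres.
#' @param area_assignment_bias residential-clustering coefficient: 0 spreads
#'   patients uniformly over areas; positive values concentrate patients in
#'   more deprived areas (log-linear in the standardized combined score).
#'
#' @return A `sim_config` object (validated list).
#' @seealso [generate_bundle()]
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 200, seed = 42)
#' cfg$quintile_obesity_prevalence
sim_config <- function(n_patients = 1000,
                       year = 2011,
                       seed = 1L,
                       sex_ratio = 0.6,
                       age_distribution = prop.table(
                         c(10.5, 14.3, 19.2, 20.4, 18.0, 11.7, 6.0)),
                       visits_per_patient = 4.2,
                       quintile_obesity_prevalence =
                         c(0.279, 0.366, 0.380, 0.396, 0.444),
                       missing_height_rate = 0.07,
                       missing_weight_rate = 0.07,
                       duplicate_rate = 0.05,
                       outlier_rate = 0.009,
                       pregnancy_rate = 0.04,
                       out_of_region_postal_rate = 0.09,
                       unmatched_da_rate = 0.05,
                       bmi_noise_sd = 0.5,
                       n_dissemination_areas = 200,
                       urban_fraction = 0.8,
                       mean_height = c(female = 1.62, male = 1.76),
                       sd_height = c(female = 0.065, male = 0.07),
                       area_assignment_bias = 0) {
  cfg <- list(
    n_patients = as.integer(n_patients), year = as.integer(year),
    seed = as.integer(seed), sex_ratio = sex_ratio,
    age_distribution = unname(age_distribution),
    visits_per_patient = visits_per_patient,
    quintile_obesity_prevalence = unname(quintile_obesity_prevalence),
    missing_height_rate = missing_height_rate,
    missing_weight_rate = missing_weight_rate,
    duplicate_rate = duplicate_rate, outlier_rate = outlier_rate,
    pregnancy_rate = pregnancy_rate,
    out_of_region_postal_rate = out_of_region_postal_rate,
    unmatched_da_rate = unmatched_da_rate,
    bmi_noise_sd = bmi_noise_sd,
    n_dissemination_areas = as.integer(n_dissemination_areas),
    urban_fraction = urban_fraction,
    mean_height = mean_height, sd_height = sd_height,
    area_assignment_bias = area_assignment_bias)

  props <- c(sex_ratio = cfg$sex_ratio,
             missing_height_rate = cfg$missing_height_rate,
             missing_weight_rate = cfg$missing_weight_rate,
             duplicate_rate = cfg$duplicate_rate,
             outlier_rate = cfg$outlier_rate,
             pregnancy_rate = cfg$pregnancy_rate,
             out_of_region_postal_rate = cfg$out_of_region_postal_rate,
             unmatched_da_rate = cfg$unmatched_da_rate,
             urban_fraction = cfg$urban_fraction)
  bad <- props < 0 | props > 1 | !is.finite(props)
  if (any(bad)) {
    stop("proportions must lie in [0, 1]: ",
         paste(names(props)[bad], collapse = ", "), call. = FALSE)
  }
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (length(cfg$age_distribution) != length(AGE_BANDS) ||
      abs(sum(cfg$age_distribution) - 1) > 1e-9 ||
      any(cfg$age_distribution < 0)) {
    stop("age_distribution must be ", length(AGE_BANDS),
         " non-negative proportions summing to 1", call. = FALSE)
  }
  if (length(cfg$quintile_obesity_prevalence) != 5 ||
      any(cfg$quintile_obesity_prevalence <= 0) ||
      any(cfg$quintile_obesity_prevalence >= 1)) {
    stop("quintile_obesity_prevalence must be 5 values in (0, 1)",
         call. = FALSE)
  }
  if (cfg$visits_per_patient < 1) {
    stop("visits_per_patient must be >= 1", call. = FALSE)
  }
  if (cfg$bmi_noise_sd < 0) stop("bmi_noise_sd must be >= 0", call. = FALSE)
  if (cfg$n_dissemination_areas < 5L) {
    stop("need at least 5 dissemination areas", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_patients, " patients, study year ", x$year,
      ", seed ", x$seed, "\n", sep = "")
  cat("  planted obesity prevalence by quintile: ",
      paste(format(x$quintile_obesity_prevalence), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

# Truncated-normal draws via inverse-CDF; used for base BMI so the planted
# obese / non-obese classes stay clear of the 30 kg/m2 cut.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

# sample() without its scalar-x surprise
resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, prob = prob)]
}

fsa_for_area <- function(index, urban) {
  l1 <- LETTERS[((index - 1L) %/% 26L) %% 26L + 1L]
  l2 <- LETTERS[(index - 1L) %% 26L + 1L]
  digit <- ifelse(urban, (index - 1L) %% 9L + 1L, 0L)
  paste0(l1, digit, l2)
}

#' Generate a synthetic Canadian-format postal code for an area
#'
#' Codes follow the letter-digit-letter digit-letter-digit shape.  The
#' forward sortation area (first three characters) is a deterministic
#' function of the area id, and its second character is `0` for rural areas
#' and a non-zero digit for urban ones, so the code is consistent with the
#' conversion table's urban flag by construction.
#'
#' @param area area id (e.g. `"DA00012"`) or integer area index.
#' @param urban logical urban flag (recycled).
#' @param serial optional integer serial for the local delivery unit; random
#'   when `NULL`.  Serials 1..k give k distinct codes within an area.
#' @return character vector of 6-character postal codes.
#' @export
#' @examples
#' generate_postal_code("DA00003", urban = TRUE, serial = 1)
generate_postal_code <- function(area, urban, serial = NULL) {
  index <- if (is.character(area)) {
    as.integer(gsub("\\D", "", area))
  } else {
    as.integer(area)
  }
  if (any(is.na(index)) || any(index < 1L)) {
    stop("area must carry a positive integer index", call. = FALSE)
  }
  n <- max(length(index), length(urban))
  index <- rep_len(index, n)
  urban <- rep_len(as.logical(urban), n)
  if (is.null(serial)) serial <- sample.int(1000L, n, replace = TRUE)
  serial <- rep_len(as.integer(serial), n)
  d1 <- (serial * 3L + 1L) %% 10L
  l3 <- LETTERS[(index + serial) %% 26L + 1L]
  d2 <- (index + 7L * serial) %% 10L
  paste0(fsa_for_area(index, urban), d1, l3, d2)
}

# In-region scored areas, a small pool of in-region areas missing deprivation
# scores, and a pool of out-of-region areas.  Three postal codes per area.
make_geography <- function(config) {
  n_scored <- config$n_dissemination_areas
  n_unscored <- max(2L, round(0.05 * n_scored))
  n_outside <- max(2L, round(0.10 * n_scored))
  n_total <- n_scored + n_unscored + n_outside

  areas <- tibble::tibble(
    area_index = seq_len(n_total),
    area_id = sprintf("DA%05d", seq_len(n_total)),
    kind = rep(c("scored", "unscored", "outside"),
               c(n_scored, n_unscored, n_outside)),
    in_region = rep(c(TRUE, TRUE, FALSE), c(n_scored, n_unscored, n_outside)),
    urban = runif(n_total) < config$urban_fraction,
    material_score = rnorm(n_total),
    social_score = rnorm(n_total))
  areas$combined_score <- (areas$material_score + areas$social_score) / sqrt(2)

  codes_per_area <- 3L
  conversion <- tibble::tibble(
    area_index = rep(areas$area_index, each = codes_per_area),
    serial = rep(seq_len(codes_per_area), times = n_total))
  conversion$postal_code <- generate_postal_code(
    conversion$area_index, areas$urban[conversion$area_index],
    serial = conversion$serial)
  conversion <- tibble::tibble(
    postal_code = conversion$postal_code,
    area_id = areas$area_id[conversion$area_index],
    urban = areas$urban[conversion$area_index],
    in_region = areas$in_region[conversion$area_index])

  deprivation <- areas[areas$kind == "scored",
                       c("area_id", "material_score", "social_score",
                         "combined_score", "in_region", "urban")]

  list(areas = areas, conversion = conversion,
       deprivation = tibble::as_tibble(deprivation),
       codes_per_area = codes_per_area)
}

#' Generate a synthetic study bundle
#'
#' Draws a full synthetic study dataset: a visit-level observation table, a
#' postal-code conversion table, a dissemination-area deprivation table, and
#' a truth table holding each patient's planted obesity status, deprivation
#' quintile and injected defect labels.  Obesity status is drawn per the
#' planted quintile prevalence gradient; heights are sex-specific normals
#' and weights are back-solved from the visit BMI (base BMI plus measurement
#' noise) so the BMI structure is exact.  Defects — exact-duplicate rows,
#' never-recorded heights/weights, implausible BMI values, pregnancy
#' episodes with an estimated date of birth, and out-of-region / malformed /
#' missing / unmatched postal codes — are injected in disjoint patient sets
#' at the configured rates.
#'
#' @param config a [sim_config()] object.
#' @return A `synthetic_bundle`: list with tibbles `observations`,
#'   `conversion`, `deprivation`, `truth`, plus the `config`.
#' @export
#' @examples
#' b <- generate_bundle(sim_config(n_patients = 50, seed = 7))
#' names(b)
#' head(b$observations)
generate_bundle <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be created by sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  geo <- make_geography(config)
  scored <- geo$areas[geo$areas$kind == "scored", ]
  n <- config$n_patients
  year <- config$year

  # demographics -----------------------------------------------------------
  patient_id <- sprintf("PT%06d", seq_len(n))
  sex <- ifelse(runif(n) < config$sex_ratio, "female", "male")
  band <- sample.int(length(AGE_BANDS), n, replace = TRUE,
                     prob = config$age_distribution)
  lo <- c(20, 30, 40, 50, 60, 70, 80)[band]
  hi <- c(29, 39, 49, 59, 69, 79, 94)[band]
  age <- lo + floor(runif(n) * (hi - lo + 1))   # age at Dec 31 of study year
  birth_year <- year - age
  birth_date <- as.Date(sprintf("%d-01-01", birth_year)) +
    floor(runif(n) * 365)

  # residence and planted deprivation gradient -----------------------------
  w <- if (config$area_assignment_bias == 0) {
    NULL
  } else {
    z <- as.numeric(scale(scored$combined_score))
    exp(config$area_assignment_bias * z)
  }
  area_row <- sample.int(nrow(scored), n, replace = TRUE, prob = w)
  breaks <- quantile(scored$combined_score, c(0.2, 0.4, 0.6, 0.8))
  true_quintile <- quintile_assign(scored$combined_score[area_row], breaks)
  postal_code <- generate_postal_code(
    scored$area_index[area_row], scored$urban[area_row],
    serial = sample.int(geo$codes_per_area, n, replace = TRUE))

  obese <- runif(n) < config$quintile_obesity_prevalence[true_quintile]
  # keep planted classes a 3-sigma noise margin away from the 30 kg/m2 cut
  margin <- 3 * config$bmi_noise_sd
  base_bmi <- numeric(n)
  base_bmi[obese] <- rtrunc_norm(sum(obese), 34, 3, 30 + margin, 48)
  base_bmi[!obese] <- rtrunc_norm(sum(!obese), 25.5, 3.5,
                                  15 + margin, 30 - margin)
  height <- rnorm(n, config$mean_height[sex], config$sd_height[sex])

  # defect assignment (disjoint patient sets) ------------------------------
  ids <- seq_len(n)
  preg <- resample(which(sex == "female"),
                   min(round(config$pregnancy_rate * n), sum(sex == "female")))
  pool <- setdiff(ids, preg)
  miss_h <- resample(pool, min(round(config$missing_height_rate * n),
                               length(pool)))
  pool <- setdiff(pool, miss_h)
  miss_w <- resample(pool, min(round(config$missing_weight_rate * n),
                               length(pool)))
  pool <- setdiff(pool, miss_w)
  outl <- resample(pool, min(round(config$outlier_rate * n), length(pool)))
  pool <- setdiff(pool, outl)
  oor <- resample(pool, min(round(config$out_of_region_postal_rate * n),
                            length(pool)))
  pool2 <- setdiff(pool, oor)
  unm <- resample(pool2, min(round(config$unmatched_da_rate * n),
                             length(pool2)))

  # implausible BMI: outside 15-50 by at least the noise margin
  if (length(outl)) {
    low <- runif(length(outl)) < 0.5
    base_bmi[outl] <- ifelse(low,
                             runif(length(outl), 8, 15 - margin - 0.1),
                             runif(length(outl), 50 + margin + 0.1, 60))
  }

  pregnancy_edb <- as.Date(rep(NA, n))
  pregnancy_edb[preg] <- as.Date(sprintf("%d-06-15", year))

  # postal-code defects
  postal_defect <- rep("none", n)
  postal_defect[unm] <- "unmatched"
  if (length(oor)) {
    kind <- sample(c("out_of_region", "erroneous", "missing"), length(oor),
                   replace = TRUE, prob = c(0.6, 0.25, 0.15))
    postal_defect[oor] <- kind
  }
  outside <- geo$areas[geo$areas$kind == "outside", ]
  unscored <- geo$areas[geo$areas$kind == "unscored", ]
  take <- postal_defect == "out_of_region"
  if (any(take)) {
    j <- sample.int(nrow(outside), sum(take), replace = TRUE)
    postal_code[take] <- generate_postal_code(
      outside$area_index[j], outside$urban[j],
      serial = sample.int(geo$codes_per_area, sum(take), replace = TRUE))
  }
  postal_code[postal_defect == "erroneous"] <- "999999"
  postal_code[postal_defect == "missing"] <- NA_character_
  take <- postal_defect == "unmatched"
  if (any(take)) {
    j <- sample.int(nrow(unscored), sum(take), replace = TRUE)
    postal_code[take] <- generate_postal_code(
      unscored$area_index[j], unscored$urban[j],
      serial = sample.int(geo$codes_per_area, sum(take), replace = TRUE))
  }

  measure_defect <- rep("none", n)
  measure_defect[preg] <- "pregnancy"
  measure_defect[miss_h] <- "missing_height"
  measure_defect[miss_w] <- "missing_weight"
  measure_defect[outl] <- "outlier"

  # chronic-disease flags (patient-level)
  flag_prev <- c(diabetes = 0.12, hypertension = 0.25, osteoarthritis = 0.11,
                 depression = 0.15, copd = 0.18, dementia = 0.03,
                 parkinsons = 0.01, epilepsy = 0.015)
  flags <- tibble::as_tibble(
    lapply(flag_prev, function(p) as.integer(runif(n) < p)))

  # visit rows --------------------------------------------------------------
  n_visits <- 1L + rpois(n, config$visits_per_patient - 1)
  idx <- rep(ids, n_visits)
  total <- length(idx)
  start <- as.Date(sprintf("%d-01-01", year))
  obs_date <- start + (sample.int(365L, total, replace = TRUE) - 1L)
  visit_bmi <- base_bmi[idx] + rnorm(total, 0, config$bmi_noise_sd)
  weight <- round(visit_bmi * height[idx]^2, 1)

  obs <- tibble::tibble(
    patient_id = patient_id[idx],
    sex = sex[idx],
    birth_date = birth_date[idx],
    postal_code = postal_code[idx],
    height = round(height[idx], 3),
    weight = weight,
    observation_date = obs_date)
  obs <- dplyr::bind_cols(obs, flags[idx, ])

  surnames <- c("Smith", "Tremblay", "Lee", "Martin", "Roy", "Wilson",
                "Gagnon", "Chen", "Campbell", "Singh")
  note <- rep("", total)
  noted <- runif(total) < 0.05
  if (any(noted)) {
    note[noted] <- paste0(
      "seen by Dr. ", sample(surnames, sum(noted), replace = TRUE),
      ", HC ", sprintf("%04d-%03d-%03d",
                       sample.int(9999L, sum(noted), replace = TRUE),
                       sample.int(999L, sum(noted), replace = TRUE),
                       sample.int(999L, sum(noted), replace = TRUE)))
  }
  obs$note <- note
  obs$pregnancy_edb <- pregnancy_edb[idx]

  # record height only intermittently (first visit always), so the
  # last-height carry-forward rule has work to do
  obs <- obs %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::arrange(.data$observation_date, .by_group = TRUE) %>%
    dplyr::mutate(height = ifelse(
      dplyr::row_number() == 1L | runif(dplyr::n()) < 0.3,
      .data$height, NA_real_)) %>%
    dplyr::ungroup()

  obs$height[obs$patient_id %in% patient_id[miss_h]] <- NA_real_
  obs$weight[obs$patient_id %in% patient_id[miss_w]] <- NA_real_

  # exact-duplicate rows
  n_dup <- round(config$duplicate_rate * nrow(obs))
  if (n_dup > 0) {
    obs <- dplyr::bind_rows(obs, obs[sample.int(nrow(obs), n_dup), ])
  }
  obs <- dplyr::arrange(obs, .data$patient_id, .data$observation_date)

  truth <- tibble::tibble(
    patient_id = patient_id,
    true_obese = obese,
    true_bmi = base_bmi,
    true_quintile = true_quintile,
    true_area_id = scored$area_id[area_row],
    measure_defect = measure_defect,
    postal_defect = postal_defect)

  structure(list(observations = obs,
                 conversion = geo$conversion,
                 deprivation = geo$deprivation,
                 truth = truth,
                 config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> ", nrow(x$observations), " observations / ",
      nrow(x$truth), " patients, ", nrow(x$deprivation),
      " scored areas, study year ", x$config$year, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic bundle to CSV files
#'
#' Writes `observations.csv`, `conversion.csv`, `deprivation.csv` and
#' `truth.csv` into `dir`.  Column meanings are documented in the data
#' dictionary shipped at `system.file("extdata", "data_dictionary.csv",
#' package = "emrlink")`.
#'
#' @param bundle a `synthetic_bundle` from [generate_bundle()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("observations.csv", "conversion.csv",
                            "deprivation.csv", "truth.csv"))
  readr::write_csv(bundle$observations, paths[1])
  readr::write_csv(bundle$conversion, paths[2])
  readr::write_csv(bundle$deprivation, paths[3])
  readr::write_csv(bundle$truth, paths[4])
  invisible(paths)
}
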