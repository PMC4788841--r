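Package: emrlink
Title: Privacy-Preserving Linkage of Primary-Care EMR Data with Census Deprivation Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning visit-level primary-care electronic medical
    records into an analysable, de-identified patient-year dataset linked to
    area-level socioeconomic deprivation. Implements free-text identifier
    scrubbing and k-anonymity generalization of quasi-identifiers (postal
    code, date of birth), a body-mass-index cleaning cascade with attrition
    reporting (pregnancy exclusion windows, height carry-forward, outlier
    bounds, within-patient variation screening), postal-code linkage to
    census dissemination areas with deprivation quintiles rescaled to a
    regional boundary, and disparity statistics (prevalences, Pearson
    chi-square tests, absolute differences and rate ratios against the
    least-deprived quintile, age and urban/rural stratification). A seeded
    synthetic-data generator emulates the EMR, postal-conversion and census
    deprivation tables, with plantable deprivation-obesity gradients for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
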