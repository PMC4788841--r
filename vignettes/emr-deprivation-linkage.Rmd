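---
title: "Methods: linking primary-care EMR data to area-level deprivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking primary-care EMR data to area-level deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emrlink)
```

## The problem

Primary-care electronic medical records (EMRs) hold objectively measured
heights and weights for large patient populations, but carry no information
about the socioeconomic environment patients live in. Canadian censuses
publish area-level material and social deprivation scores at the
dissemination-area (DA) level, reachable from a patient's postal code
through a conversion table. `emrlink` implements the full path between the
two: rendering the extracted records anonymized, cleaning visit-level
height/weight data into one body-mass-index (BMI) record per patient-year,
linking postal codes to DA deprivation quintiles rescaled to a regional
boundary, and summarising the obesity-deprivation gradient with disparity
statistics.

Because real EMR extracts cannot be shipped, the package includes a seeded
synthetic generator that emulates the three input tables with plantable
parameters, so every stage is testable end to end and parameter recovery
can be verified against known truth.

## De-identification

Two mechanisms, applied at different points:

* **Free-text scrubbing** (`scrub_free_text()`): direct identifiers that
  leak into note fields — person-name tokens following an honorific and
  health-card-number shapes — are replaced by `[REDACTED]`. The
  replacement preserves nothing about the match, so it is irreversible.
* **k-anonymity generalization** (`generalize_until_k()`): the
  quasi-identifiers postal code, birth date and sex must not isolate
  groups smaller than `k` (default 5). We use *global recoding*: a single
  generalization level per field for the whole table, walked level by
  level — postal code `6 chars -> 5 -> 4 -> 3-char FSA -> suppressed`,
  then birth date `full -> year-month -> year -> 5-year band ->
  suppressed` — stopping at the least-coarse combination whose smallest
  equivalence class reaches `k`. Records still below `k` at maximal
  generalization are suppressed and counted. Postal code is coarsened
  before birth date because positional digits degrade gracefully for
  linkage (a 3-character FSA can still resolve to a DA when unambiguous),
  while birth date drives age-group analyses; the order is configurable.

Equivalence classes count *distinct patients* when a `patient_id` column
is present — a patient's own repeat visits must not satisfy `k` for them.
The same `k` is reused for small-cell suppression in per-area exports, so
the privacy contract holds from extraction to the last output.

Within `run_study()` the analysis itself operates on full postal codes
inside the trusted repository; generalization is for released tables. The
released patient-year table is audited (`reidentification_audit()`), and a
test verifies it passes its own audit after generalization.

## The cleaning cascade

`run_cascade()` applies, in this fixed order:

1. **Eligibility**: observations in the study year from patients aged
   ≥ 20. Age is computed at December 31 of the study year (everyone has
   had their birthday by then, so age is simply study year minus birth
   year, which stays computable for generalized birth dates down to the
   5-year band).
2. **Exact-duplicate removal** (same-day duplicate matching is available
   by deduplicating on a date key upstream; exact-row matching is the
   default because repeated identical rows are the extraction artefact
   being targeted).
3. **Pregnancy window**: measurements from 9 months before to 12 months
   after the estimated date of birth of the infant, endpoints inclusive,
   are dropped (calendar-month arithmetic, so the window starts on the
   same day-of-month where it exists).
4. **Height carry-forward**: a weight-only visit uses the most recent
   prior height; visits before any height use the patient's most recent
   height overall. Adult height is effectively constant over a study
   year, so this recovers BMI for weight-only visits without imputation.
5. **Missing measures**: rows still lacking height or weight are dropped;
   patients with no complete row leave the cohort here.
6. **Plausibility bounds**: per-row BMI outside 15-50 kg/m² is excluded.
   The inequalities are strict — 15.0 and 50.0 are retained.
7. **Within-patient variation screen**: see below.
8. **Final selection**: the latest in-year measure per patient becomes
   the `PatientYearRecord`.

The attrition report telescopes (each step's remaining count equals the
previous minus its removals) and this invariant is property-tested. The
order matters — a pregnant patient with an implausible BMI is attributed
to the pregnancy filter, not the outlier filter — and a regression test
pins the order down.

### The variation screen

Repeat measures that swing wildly within a year (unit errors, data-entry
slips) should remove the patient. The screen computes each multi-measure
patient's in-year BMI range (max − min) and flags ranges exceeding 2
standard deviations. Two choices of the SD scale are provided:

* `cohort_bmi_sd` (default): the SD of all in-year BMI measurements. A
  flagged patient's measures span more than two cohort-SDs of BMI itself
  (roughly 8-10 kg/m² in an adult cohort) — the data-error scale. Under
  ordinary measurement noise this flags essentially nobody, matching the
  rarity such a screen is meant to have.
* `range_sd`: 2 SDs of the per-patient ranges themselves. We implemented
  this first and found it unusable as a default: with independent
  visit-level noise, ranges concentrate tightly around their mean, the
  threshold falls *below* the typical range, and half a synthetic cohort
  gets flagged. It is retained as an explicit strategy for comparison.

Degenerate inputs are defined: fewer than two multi-measure patients, or
an all-zero range distribution, flag nothing (the threshold comparison is
strict).

### Missing-data comparison

`compare_missingness_cohorts()` contrasts patients with and without a
usable BMI: per chronic-disease flag a 2×2 Pearson chi-square, for age a
Welch (unequal-variance) t-test. The zero-variance degenerate case is
handled explicitly (t = 0, p = 1 for identical constant cohorts).

## Geographic linkage and regional quintiles

`link_postal_to_area()` matches full six-character codes exactly;
generalized codes (3-5 leading characters) match by prefix and resolve
only if every candidate agrees on one DA, otherwise they are ambiguous.
Malformed or missing codes are counted as erroneous rather than raised:
linkage loss is an outcome of the pipeline, not an exception.

Deprivation quintiles are computed **over areas, not patients**:
breakpoints at the 20/40/60/80th percentiles of in-region area scores,
unweighted by population. Each quintile then holds 20 % of *areas* (± one
area), while the *patient* distribution over quintiles is free to be
unequal — which is exactly what one observes when a practice draws
disproportionately from deprived neighbourhoods. Population-weighted
breakpoints would be a defensible alternative; unweighted percentiles are
the simplest reproducible rule and the generator controls patient
clustering separately (`area_assignment_bias`). A score exactly equal to
a breakpoint takes the lower quintile, a fixed tie-break that keeps
assignment deterministic and order-invariant.

The combined quintile is computed from a single combined score rather
than by crossing material × social quintiles; crossing produces 25 cells
with no canonical ordering back to 5 groups, while a combined score keeps
the quintile machinery identical across all three indices.

## Disparity statistics

All tests are Pearson chi-squares computed from first principles
(`sum((O - E)^2 / E)`, expected counts from margins, upper-tail p), with
no continuity correction by default — the Yates correction is available
by flag for the 2×2 case. The implementation is verified against a
brute-force double-loop oracle and against `stats::chisq.test()` on
random tables, and its null calibration (type-I error at the nominal 5 %)
is checked by simulation.

* The overall association uses the 5 quintile × 4 BMI-category table:
  12 degrees of freedom.
* `extreme_quintile_test()` contrasts the most against the least deprived
  quintile (1 df) and reports the relative excess
  `100 * (p5/p1 - 1)` and the absolute difference `p5 - p1` in
  percentage points.
* `disparity_measures()` produces, per quintile, the simple difference
  (one decimal, percentage points) and the disparity rate ratio (two
  decimals) against the least-deprived reference, whose row is exactly
  (0, 1.00).
* `stratified_analysis()` repeats the quintile table within age groups
  (20-39, 40-59, 60-79, 80+) or urban/rural strata. Cell percentages are
  each quintile's share of the *stratum's obese patients*. Strata with
  any expected cell below 5, or with a single occupied quintile (no test
  possible), are flagged low-power. No multiple-testing adjustment is
  applied across strata; p-values are reported unadjusted at 0.05.

## The synthetic generator

`sim_config()` fixes the study conditions; `generate_bundle()` draws the
three tables plus a truth table the pipeline never sees.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| `year` | 2011 | study year; all visits fall inside it |
| `sex_ratio` | 0.60 female | adult primary-care attenders skew female |
| `age_distribution` | 10.5/14.3/19.2/20.4/18.0/11.7/6.0 % over decades 20-29 … 80+ | adult practice age mix |
| `visits_per_patient` | 4.2 | ~30 000 observations per ~7 000 patients |
| `quintile_obesity_prevalence` | 27.9 → 44.4 % | a realistic deprivation gradient; the planted truth for recovery tests |
| `pregnancy_rate` | 4 % | pregnancy episodes among the cohort |
| `missing_height_rate` + `missing_weight_rate` | 7 % + 7 % | 14 % of patients with no usable measure |
| `outlier_rate` | 0.9 % | implausible BMI values |
| `out_of_region_postal_rate` | 9 % | outside-region, malformed or missing codes (60/25/15 split) |
| `unmatched_da_rate` | 5 % | in-region codes whose DA has no deprivation score |
| `bmi_noise_sd` | 0.5 kg/m² | visit-to-visit measurement noise |
| `n_dissemination_areas` | 200 | small health-unit geography |
| `urban_fraction` | 0.8 | urban-centre practice with rural surroundings |

Design choices that make the planted parameters identifiable:

* Heights are sex-specific normals (means 1.62/1.76 m, SDs 0.065/0.07)
  and weight is back-solved as `BMI × height²`, so the BMI structure is
  exact — BMI is the analysed quantity, heights/weights are carriers.
  The published source gives no distributional detail for heights or
  weights; these defaults are stated as assumptions, not facts.
* A patient's base BMI is drawn *conditional on the planted obesity
  status*, truncated 3 × `bmi_noise_sd` away from the 30 kg/m² cut, so
  visit noise cannot flip the planted class. Without the margin the
  planted prevalences would be attenuated by boundary misclassification
  and the recovery tests would be testing noise, not the pipeline.
* Defect patients are drawn as disjoint sets, so injected counts equal
  `round(rate × n)` exactly and attrition calibration is sharp.
* Pregnancy episodes carry an explicit estimated date of birth
  (mid-year), placing every in-year measurement inside the exclusion
  window — the boundary behaviour of the window itself is tested with
  handcrafted dates.
* The truth table (planted status, quintile, defect labels) is emitted
  separately and consumed only by tests.

What the generator does **not** emulate: real postal-code geography or an
actual region, physician practice patterns beyond visit counts,
correlation between missingness and demographics, secular BMI trends, or
within-year weight trajectories. Passing recovery tests therefore shows
the pipeline estimates what was planted under these stylized conditions —
not that any real cohort satisfies them.

## Validation problem sizes

The shipped tests run the full pipeline at 300-5 000 patients.
Parameter recovery uses 20 independent seeds at n = 5 000 through the
complete generate → clean → link → analyze path, requiring the
most-vs-least-deprived rate ratio to recover the planted 0.444/0.279 ≈
1.59 within 3 standard errors of the mean, and the most-deprived
prevalence to land within 3 percentage points of 44.4 %. The 12-df
test's type-I error is calibrated on 1 000 simulated null cohorts of
n = 5 000 drawn directly under quintile/category independence. The
handcrafted attrition fixture removes exactly one known patient per
filter.

## Known limitations

* Global recoding generalizes every record to the same level; local
  (per-record) recoding would preserve more utility but weakens the
  simple "one level per field" release statement.
* Quintile breakpoints use `stats::quantile()` type 7; other quantile
  definitions shift breakpoints by fractions of an area.
* The pipeline deliberately fits no regression and adjusts for no
  confounders; it quantifies crude gradients, stratified at most one
  variable at a time.
* Linkage assumes the conversion table is authoritative; real postal
  files carry retired and split codes the synthetic geography does not
  model.
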