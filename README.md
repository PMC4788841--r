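# emrlink

Privacy-preserving linkage of primary-care electronic medical records
(EMRs) with census-based area-level deprivation, for studying
socioeconomic gradients in chronic-disease risk factors — obesity being
the worked case throughout.

EMRs hold measured heights and weights; censuses hold material and social
deprivation scores at the dissemination-area level; a postal-code
conversion table connects the two. `emrlink` implements the whole path
for an epidemiologist or public-health analyst:

* **De-identification** — irreversible scrubbing of direct identifiers
  from free text, and *k*-anonymity generalization of the
  quasi-identifiers (postal code `6 → 5 → 4 → FSA → suppressed`, birth
  date `full → year-month → year → 5-year band → suppressed`) until every
  equivalence class holds at least *k* patients, with a re-identification
  audit.
* **BMI cleaning cascade** — study-year/adult eligibility, duplicate
  removal, pregnancy exclusion window (9 months before to 12 months after
  the estimated date of birth), last-height carry-forward,
  missing-measure removal, 15–50 kg/m² plausibility bounds,
  within-patient variation screen, latest-measure selection; all with a
  telescoping attrition report. BMI = weight (kg) / height (m)², WHO
  adult categories (underweight < 18.5, normal 18.5–24.9, overweight
  25–29.9, obese ≥ 30).
* **Geographic linkage** — postal code → dissemination area (exact or
  unambiguous-prefix match), deprivation quintiles rescaled to the
  regional boundary: breakpoints at the 20/40/60/80th percentiles of
  in-region area scores, quintile 1 least deprived, 5 most deprived.
* **Disparity statistics** — prevalences; Pearson chi-square tests
  (5 quintiles × 4 BMI categories = 12 df; most- vs least-deprived 2×2,
  1 df); simple differences p<sub>i</sub> − p<sub>1</sub> and disparity
  rate ratios p<sub>i</sub> / p<sub>1</sub> against the least-deprived
  reference; age-group and urban/rural stratification.
* **Synthetic data** — a seeded generator for all three input tables with
  a plantable deprivation → obesity prevalence gradient and configurable
  defect rates (duplicates, missing measures, outliers, pregnancies, bad
  postal codes), plus a truth table for honest parameter-recovery
  testing.

## Worked example

```r
library(emrlink)

study <- run_study(sim_config(n_patients = 2000, seed = 42))
study
#> <emr_study> final sample n = 1342
#>   obesity prevalence: 39 %
#>   quintile x BMI-category chi-square = 17.12 (12 df), p = 0.145
#>   most vs least deprived: chi-square = 8.82 (1 df), +38.1 % relative, +12.6 pp absolute

study$cascade$attrition
#> # A tibble: 7 x 4
#>   step             patients_removed patients_remaining rows_removed
#> 1 extracted                       0               2000            0
#> 2 eligibility                     0               2000            0
#> 3 duplicates                      0               2000          417
#> 4 pregnancy_window               80               1920          348
#> 5 missing_measures              280               1640         1120
#> 6 bmi_outliers                   18               1622           73
#> 7 bmi_variation                   0               1622            0

study$disparity$combined
#> # A tibble: 5 x 4
#>   quintile prevalence simple_difference rate_ratio
#> 1        1       33.1               0         1
#> 2        2       35.1               2         1.06
#> 3        3       39.3               6.2       1.19
#> 4        4       41.3               8.2       1.25
#> 5        5       45.7              12.6       1.38
```

Reading the output: of 2000 simulated patients, 80 (4 %) fall to the
pregnancy window, 280 (14 %) have no usable height/weight pair and 18
(0.9 %) only implausible BMI values; postal-code losses during linkage
bring the final analysable sample to 1342. Obesity prevalence climbs
monotonically across combined-deprivation quintiles — patients in the
most deprived fifth of areas are 38 % more likely to be obese than those
in the least deprived fifth (rate ratio 1.38 at this seed and size, a
12.6 percentage-point absolute gap), while the gradient planted by the
generator rises from 27.9 % to 44.4 % (true ratio ≈ 1.59); single-seed
estimates scatter around that truth and the test suite checks recovery
across 20 seeds at n = 5000.

A thin command-line wrapper over the same functions ships at
`inst/cli/emrlink.R` (`generate`, `deidentify`, `clean`, `link`,
`analyze`, `pipeline` subcommands). Column layouts of the four CSV tables
are documented in `inst/extdata/data_dictionary.csv`, and the methods —
including every cleaning rule, tie-break and generator assumption — in
`vignettes/emr-deprivation-linkage.Rmd`.

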