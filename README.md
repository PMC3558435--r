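# remotepop

Rapid, remote estimation of displaced populations from very high resolution
satellite imagery.

## The problem

Knowing how many people live in a refugee or IDP settlement is the
denominator behind almost every humanitarian indicator — death rates,
malnutrition prevalence, vaccine and food needs — yet in the acute phase of
displacement reliable figures are rarely available and the site is often
inaccessible. When individual dwellings are distinguishable on sub-metre
satellite imagery, a remote analyst team can estimate the population without
setting foot on site. `remotepop` implements that estimation chain for
analysts and epidemiologists who have (a) manual point annotations of
assumed structures from one or more independent counters and (b) a registry
of literature reports of household size or structure occupancy.

## The estimator

The population estimate for a site is

```
N_hat = C_bar x o
```

where `C_bar` is the consensus residential structure count — the arithmetic
mean of the independent analysts' counts, rounded half away from zero — and
`o` is the mean number of people per residential structure. `o` is pooled
from the `n` available occupancy reports by a weighted mean

```
o = sum(w_i * x_i) / sum(w_i),    i = 1..n
```

with `x_i` the occupancy value of report `i` and `w_i` its *information
score*: the product of three points values from a hierarchy of evidence
grading (1) how representative the report is of this site and time-point,
(2) how robust its data-collection method is, and (3) whether it counts
people per residential structure rather than per loosely-defined household.
Each attribute awards at most 10 points, so a score is at most 1000; the sum
of scores over a site's reports is its *amount-of-information index*. Where
reports are per household but structures hold several households (e.g. long
multi-household sheds), a households-per-structure multiplier converts units.
Estimates are validated against reference ("gold standard") census or
registration figures and banded as good (<10% relative difference),
moderate (10–30%) or poor (>30%).

Inter-analyst agreement on duplicate counts is reported as
`|a - b| (100 |a - b| / max(a, b) %)`.

## Worked example

Two analysts counted 5,423 and 6,208 residential structures in a camp; the
registry holds three occupancy reports of differing quality:

```r
library(remotepop)

reports <- data.frame(
  report_id       = c("unhcr_reg_2005", "msf_survey_2004", "predisp_survey_2001"),
  occupancy_value = c(6.2, 5.6, 5.1),
  unit            = c("per_structure",
                      "per_household_consistent_with_structure",
                      "per_household_other"),
  provenance      = c("site_current", "region_current", "pre_displacement"),
  method          = c("census_registration_surveillance", "large_survey",
                      "other_survey"),
  collection_date = c("2005-06-30", "2004-03-15", "2001-01-01"))

fit <- popest(c(5423, 6208), reports,
              site_config("Breidjing", "2006-01-30",
                          reference_population = 26770))
fit
#> Remote imagery-based population estimate -- Breidjing
#>   Consensus residential structure count: 5,816 (2 analyst counts)
#>   Structure occupancy (weighted mean of 3 reports): 6.026
#>   Estimated population: 35,044
#>   Amount-of-information index: 1396 (3 reports)
#>   vs reference: +8,274 (+30.9%) -- poor precision
```

The consensus count is (5423 + 6208)/2 = 5815.5, rounded to 5,816. The
current-crisis registration report scores 10 x 10 x 10 = 1000 and dominates
the pooled occupancy of 6.026 people per structure; the pre-displacement
household estimate scores only 2 x 6 x 1 = 12 and barely moves it
(`summary(fit)` prints the per-report breakdown). The product, 35,044
people, overshoots the registration reference by 30.9%. `coef(fit)` returns
the three headline numbers and `confint(fit)` gives an optional
report-resampling interval.

The synthetic simulator quantifies how counting errors propagate — for
example, analysts who each miss 20% of structures:

```r
spec <- site_spec(c(hut = 400), occupancy_mean = 5, occupancy_dispersion = 0.3)
rep_model <- report_model(data.frame(
  provenance = "site_current", method = "other_survey",
  unit = "per_household_consistent_with_structure",
  bias = 1, noise = 0.05, n = 3))
run_recovery_experiment(spec, analyst_model(detection = 0.8), rep_model,
                        n_reps = 100, seed = 42)
#> Recovery experiment (100 replicates): mean relative error -20.18%, RMSE 20.33%
```

Packaged fixtures (`site_fixtures()`, `load_site_fixture("Breidjing")`)
carry the published duplicate counts, occupancy pools, estimates and
reference figures for eleven validated study sites, and `run_pipeline()`
plus the `inst/cli/remotepop.R` script drive the whole chain from files
(marks GeoJSON/CSV, registry CSV/JSON, JSON config) to JSON/CSV records.

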