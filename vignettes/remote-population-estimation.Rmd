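---
title: "Remote population estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Remote population estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remotepop)
```

## The method

`remotepop` implements a deliberately simple, three-step estimator of the
population of a displaced settlement, designed so that a small remote team
with modest GIS skills can produce a defensible figure in days:

1. **Count.** One or more analysts independently mark every assumed
   residential structure visible on a sub-metre satellite image, sweeping a
   200 m grid cell by cell. The consensus count is the arithmetic mean of
   the analysts' residential counts, rounded half away from zero.
2. **Pool occupancy evidence.** Published and grey-literature reports of
   mean structure occupancy or household size are screened for eligibility
   and scored under a hierarchy of evidence; eligible values are pooled by a
   weighted mean with the scores as weights.
3. **Multiply.** Population = consensus count × people per residential
   structure, rounded half away from zero.

The estimator makes strong assumptions: that residential structures are
individually distinguishable on the image (it degrades badly for connected
roofs, multi-storey buildings and dense slum layouts); that the occupancy
literature, however sparse, brackets the true occupancy; and that the
category-to-residential mapping agreed before counting is sound. It
deliberately produces no confidence interval by default — occupancy
evidence is typically one to eleven reports per site, too sparse for a
meaningful interval — though `confint()` offers a clearly-flagged
nonparametric report-resampling interval as an extension.

## The hierarchy of evidence

Each occupancy report is scored on three attributes, and the information
score is the product of the three point values (maximum 10 × 10 × 10 =
1000):

* **Representativeness** — the site itself within 3 years of the analysis
  date (10); a similar site in the same crisis region within 3 years (8);
  either, 3–10 years before (4); the same population before displacement,
  within 10 years (2).
* **Method robustness** — census, registration or demographic surveillance
  (10); a large, technically sound sample survey (8); any other survey (6);
  rapid assessment or programmatic review (4); anecdote (1). "Large" is
  strict: >200 households for simple/systematic sampling, or >400
  households *and* >20 clusters for cluster sampling, so a 20-cluster
  survey scores 6.
* **Unit congruence** — occupancy per residential structure (10); household
  size under a definition consistent with one structure or compound (6);
  household size with an unclear or incongruous definition (1).

The point values are data, not code: they load from a versioned JSON rubric
(`load_rubric()`), so the hierarchy can be refined — for instance by expert
consensus — without touching the scoring logic. The site-level sum of
scores, the amount-of-information index, is reported alongside every
estimate as a caveat on how much evidence supports it; it is *not* a
measure of accuracy.

Two scoring decisions were genuinely open and are worth recording. First,
the 3- and 10-year windows use whole-day calendar arithmetic with inclusive
boundaries: data collected exactly three years before the analysis date
still counts as current, which matches the plain reading of "within".
Second, the representativeness classifier is date-driven where the declared
provenance and the date disagree: a report labelled current but dated five
years back scores 4, the previous-period level. Encoding the judgment in
the registry (provenance level + date) rather than inferring geography
keeps the scoring auditable. Undated reports are excluded outright with an
`"undated"` reason — the eligibility window cannot be verified without a
date — rather than guessed at.

## Counting, agreement and rounding

Duplicate-count agreement is reported as the absolute difference and as a
percentage of the **larger** of the two counts, which keeps the relative
difference in [0, 100] (a count pair of 70 vs 0 is 100%, not undefined or
infinite). The denominator is not stated in most field protocols;
max(a, b) is adopted here because it reproduces the published agreement
cells of the packaged study sites in every case but one — a single
total-structures cell consistent with division by the *smaller* count,
treated as a typo and flagged `known_discrepancy` in the fixtures, as are
the comparable-area-adjusted cells of the largest camp, whose adjustment is
undocumented. For such partial-coverage comparisons, `site_config()`
accepts a `count_override` that replaces the consensus mean.

All integer reporting rounds **half away from zero**. Banker's rounding is
ruled out by the packaged tables themselves: a duplicate pair averaging
1418.5 is published as 1419, and an estimate of 12,057.5 as 12,058. The
consensus count is rounded *before* the multiplication; both orders
reproduce the published estimates, but rounding first matches the printed
mean counts exactly and keeps the printed table self-consistent.
`popest(compat = TRUE)` additionally rounds the pooled occupancy to one
decimal before multiplying, reproducing hand arithmetic from tabulated
(1-decimal) occupancies bit-exactly; the default carries full precision.

Grid cells are half-open `[edge, edge + cell_size)` and zero-based from the
grid origin, so every in-extent mark lands in exactly one cell and per-cell
counts sum to the total — a mark exactly on an interior gridline belongs to
the higher-index cell, never to two.

## Validation and precision bands

Validation is always referenced-denominated: relative difference =
100 × (estimate − reference) / reference, reported signed at one decimal.
Bands are good (<10%), moderate (10–30%), poor (>30%), applied to the
**integer-rounded** absolute percent. The integer rounding resolves an
ambiguity between the verbal band edges and 1-decimal cells: a site at
+30.4% is moderate (30.4 rounds to 30, inside 10–30), while +30.5% is
poor. The raw 1-decimal value is always reported next to the band.

## The synthetic-settlement simulator

The simulator exists so the whole pipeline can be exercised, and estimator
bias studied, without imagery. It emulates three things:

* **Settlements** (`site_spec()`, `generate_site()`): per-category structure
  counts placed uniformly, on a jittered block grid, or in clusters —
  caricatures of stand-alone dwellings, planned camps and dense slum
  pockets. Per-structure occupancy is drawn from a gamma distribution
  parameterised by mean and dispersion (coefficient of variation),
  discretized half-away and floored at one occupant: positive,
  right-skewed, and degenerate at dispersion 0 so exact-recovery tests are
  possible. Default mean 5, dispersion 0.3 — a typical displaced-household
  size with realistic spread.
* **Analysts** (`analyst_model()`): independent per-structure detection
  (default 1), Poisson false positives at a per-true-structure rate placed
  uniformly in the bounding box (emulating straw bales or debris marked as
  dwellings; default category = the site's first residential category so
  they enter the count), and a row-stochastic category-confusion matrix
  (emulating tent/house disagreement).
* **Occupancy reports** (`report_model()`): per evidence tier, `n` reports
  equal to the true occupancy (converted to per-household units where the
  tier reports households) times a multiplicative bias and a noise factor
  `1 + N(0, noise)` truncated below at 0.05, so noise 0 is exact.

Seeds are explicit arguments everywhere and the global RNG state is left
untouched; identical seeds give identical sites, marks, registries and
experiment summaries end to end. `run_recovery_experiment()` runs the full
generate → count → score → pool → estimate chain per replicate and reports
the mean signed relative error and RMSE against the known truth. Under an
imperfect analyst with detection probability p, no false positives and
unbiased reports, the expected relative error is p − 1; with false-positive
rate f and report bias b it is p(1 + f)b − 1 (identity confusion). The test
suite checks these at desk scale — sites of 250–1000 structures, 20–200
replicates — sizes chosen so Monte-Carlo standard errors are a few tenths
of a percent while the whole suite runs in seconds.

What passing these tests does **not** show: the simulator draws structures
as points with independent detection, so it cannot reproduce the spatially
correlated failure modes that dominate real urban imagery — connected
roofs counted as one structure, collapsed buildings, vegetation occlusion —
nor analyst learning over a count. Simulator-validated accuracy is
therefore a statement about the estimator's arithmetic under stylised
error, not about real-image counting accuracy.

## Degenerate inputs and edge behaviour

Empty mark sets tabulate to a zero-row count table; an empty analyst count
vector is an error (no consensus without a count). A registry with no
eligible reports fails with "no occupancy information" rather than
defaulting an occupancy. Zero structures estimate a population of zero.
Both-zero duplicate counts agree at 0%. A households-per-structure
multiplier below 1 is rejected; a registry consisting entirely of
per-structure reports ignores the multiplier, since its unit conversion
would not apply.

## Known limitations

* The information-score points are ordinal judgments; the weighted mean
  treats them as ratio-scale weights. A site whose only report is
  implausible will be confidently wrong — the index flags evidence
  quantity, not truth.
* Occupancy fluctuates over protracted crises; pooling decade-old reports
  can add bias that no weighting can remove.
* The package consumes analyst marks; it neither renders imagery nor
  detects structures, and offers no help where dwellings are not
  individually distinguishable.
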