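---
title: "Multi-scale ensemble SDMs with satellite seasonal-dynamics predictors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale ensemble SDMs with satellite seasonal-dynamics predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(efasdm)
```

## The scientific problem

Species distribution models (SDMs) are usually calibrated with interpolated
climate grids and thematic land-cover maps. Satellite-derived Ecosystem
Functional Attributes (EFAs) — summary metrics of the seasonal dynamics of
vegetation greenness (EVI), land-surface temperature (LST) and albedo —
offer an alternative predictor family that integrates the ecosystem's
functional response to both climate and land use, can be updated every
composite period, and is observed rather than interpolated. The question
this package addresses is whether EFA-based ensemble SDMs match
climate/land-cover-based ones, and how the answer depends on spatial scale
(grain and extent).

Because real MODIS/WorldClim/CORINE/GBIF inputs are large, access-restricted
and uncontrolled, the package replaces them with a **virtual landscape and
virtual species whose truth is known**. Every downstream claim — that
screening recovers the true drivers, that importance ranks them first, that
EFA ensembles match climate ensembles when ecosystem functioning is
climate-driven — is then a testable statement about a known generative
model, not an unfalsifiable description of one data set.

## The synthetic landscape

`generate_landscape()` builds, from one seed:

* **Terrain.** A smoothed Gaussian random field rescaled to 0–2200 m,
  emulating an oceanic mountain region.
* **Monthly climate normals.** Sea-level temperature follows an annual
  harmonic (13 °C mean, 6.5 °C amplitude, July peak) with a −6.5 °C/km
  elevation lapse; precipitation follows a winter-wet harmonic
  (900 mm/yr at sea level) plus +50 mm/yr per 100 m of elevation and
  multiplicative noise. The resulting ranges (≈5–15 °C annual mean outside
  the summits, ≈600–3000 mm/yr) match a NW-Iberian profile. Monthly maxima
  and minima are the mean ± a nonnegative half-range, so
  `tmax ≥ tmean ≥ tmin` holds cellwise by construction.
* **Land cover.** A second Gaussian field, generated on a sub-grid four
  times finer than the analysis grain (250 m under a 1 km grain) and
  thresholded at quantiles into agriculture / forest / scrubland / bare
  soil (30/35/25/10%). The smoothing length is the patchiness knob. The
  sub-grid resolution exists because landscape metrics (class fractions,
  SHDI, mean patch area) are only meaningful when the cover map is strictly
  finer than the analysis cell.
* **Satellite series.** Sixteen-day composites starting on day-of-year 1
  (23 per year — the cadence of MODIS-like products, without their actual
  acquisition calendars). Each cell's EVI is a seasonal harmonic
  whose level, amplitude and peak day depend on the land-cover class, with
  the level additionally coupled to standardized annual precipitation
  (+0.08/sd) and temperature (+0.04/sd) — the "ecosystem functioning is
  climate-driven at regional scales" premise, made literal. LST follows
  annual air temperature plus an offset and a 9 °C seasonal harmonic;
  albedo is class-dependent with weak seasonality. All three series get
  i.i.d. Gaussian noise and are clipped to their physical ranges
  (EVI ∈ [−1, 1], LST ∈ [−25, 45] °C, albedo ∈ [0, 1]).

What the generator does **not** emulate: cloud/QA gaps, spatially
correlated sensor error, interannual climate anomalies, land-cover change,
topographic aspect effects, and observer bias in occurrences (an optional
bias raster exists but defaults to unbiased). Tests passing on this
landscape therefore certify the pipeline's statistical machinery, not its
robustness to real-data artefacts.

## Virtual species and presence-only sampling

True suitability is `plogis(b0 + Σ bj · zj)` over standardized predictor
rasters; `define_virtual_species()` can solve the intercept for a target
prevalence. Presence cells are drawn **without replacement with probability
proportional to truth** and deduplicated to grid cells; no true absences
are ever emitted, matching the presence-only reality of rare-species
records. Default record counts per extent × grain combination (30, 30, 91,
62) mirror the narrow-ranged test species of the motivating study design.

## EFA metrics

For each dimension (EVI, LST, ALB), `compute_efa_stack()` derives eight
per-year metrics per cell — mean, maximum, minimum, standard deviation, and
sine and cosine of the days of maximum and minimum — then averages them
across years: 24 candidate predictors. Conventions, chosen where the
construction is underdetermined:

* Phenology angle `θ = 2π · doy / 365`, leap days folded into day 365.
  This anchors sine ≈ +1 to late March/early April and cosine ≈ +1 to
  around New Year.
* Argmax/argmin ties break to the **earliest** day (determinism).
* The interannual mean of phenology averages each year's **sine/cosine
  components** (vector averaging), not the dates: two years with opposed
  peaks (days 91 and 274) average to ≈ 0, i.e. "no consistent phenology",
  which is the ecologically meaningful answer; averaging the dates would
  instead invent a mid-year peak.
* The "sine of the date of maximum" metric uses the date of the annual
  maximum of the series itself; no green-up detection is attempted.

Layer codes extend the printed convention (`EVImx`, `EVImn`, `EVIdmxs`,
`LSTsd`, `LSTmn`, `ALBmx`) with `av` for the annual mean and `dmxc`,
`dmns`, `dmnc` for the remaining phenology components.

## Climate and landscape predictors

`derive_bioclim()` computes the six climate predictors from monthly
normals. Quarters are all twelve wrap-around windows of three consecutive
months (December–February allowed, as in the standard bioclim
construction), ties broken to the earliest-starting window. `TAR` is the
**mean monthly** temperature range, following the printed definition of the
variable, not the WorldClim annual-extreme version. `PS` is
100 × sd/mean of monthly precipitation. Temperatures are plain °C
throughout; the °C×10 storage convention of some distributed rasters is an
input-decoding concern, not a modelling one.

`landscape_metrics()` computes, per analysis cell: class-area fractions
(relative to the whole cell, so nodata keeps their sum below 1), the
Shannon diversity index −Σ p ln p over the classes present, and the mean
area of 8-neighbour-connected same-class patches clipped at the analysis
cell boundary. Patch clipping makes the computation local and
deterministic; regionally defined patch metrics would couple every cell to
the whole map.

## Screening

Candidates are ranked by a preliminary score — the 4-fold cross-validated
AUC of a single-predictor logistic regression on the presence/first
pseudo-absence data — then selected greedily: a candidate is skipped if its
|Spearman ρ| with an already selected one is ≥ 0.8; survivors pass an
iterative VIF filter (drop the largest until all < 4); the set is truncated
at `floor(m/5)` predictors for `m` presence records and at most six, the
final-set size of the study design (30 records being the smallest sample,
`floor(30/5) = 6`). An expert-override list can pin predictors into the
selection. Screening statistics are computed on the presence plus
first-pseudo-absence cells — the data the models actually see — rather
than on whole rasters.

## Ensemble modelling

Pseudo-absences: as many as presences, never on presence cells, pairwise
cell-center distances at least one grain apart, drawn independently per
set (default 5 sets at desk scale, 30 by configuration). Each model run
splits records 80/20, fits one learner, and is scored on the held-out 20%:
rank-formulation (Mann–Whitney) AUC; threshold τ minimizing the distance
between the ROC curve and the (0,1) corner, searched over midpoints of
sorted unique scores with ties to the lower threshold; TSS at τ.

The learner registry holds ten families echoing the usual ensemble-SDM
toolbox (quadratic-term logistic GLM, ridge logistic, spline additive
logistic, tree, random forest, gradient boosting, single-hidden-layer
network, discriminant on a quadratic basis, hinge-basis adaptive-spline
logistic, and a from-scratch surface range envelope that predicts presence
iff every predictor lies within its central 95% presence quantiles). The
desk-scale default uses four of them (GLM, ridge, random forest, envelope)
— fast, robust on 30–180-record samples, and spanning parametric,
tree-based and envelope families.

Ensembles keep members with held-out AUC ≥ 0.7, summarize scores as
median ± IQR, take the **cellwise median** of member probability maps (a
mean is available behind a flag), and binarize at the ROC-corner threshold
of the pooled-calibration ensemble scores. Two AUC summaries are reported
where truth is available: the median of member AUCs, and the ensemble
map's own AUC against fresh virtual presences (`evaluate_on_truth()`),
because "the ensemble's AUC" is genuinely ambiguous between the two.

Variable importance is permutation-based on the ensemble prediction: mean
over permutations of 1 − |Pearson r| between reference predictions and
predictions with one column shuffled, normalized to contributions summing
to 1; only contributions > 0.1 are reported. Response curves sweep one
predictor over its observed range with the others at their medians.

## Map agreement

* **Fuzzy kappa** (categorical maps): cell memberships decay as
  `2^(−d/2)` within a radius of 4 cells (the conventional tool defaults;
  the method's description names the tool, not the parameters); cell
  similarity is the minimum of the two one-way crisp-against-fuzzy
  similarities; the expectation under random relocation uses the original
  category-proportion form with ordered neighbourhood weights. At radius 0
  this reduces exactly to Cohen's kappa. The "improved" variant's
  autocorrelation-aware expectation is documented but not implemented;
  report headers note the difference.
* **Moran's I**: global, queen contiguity, row-standardized weights, on
  continuous suitability by default (binary behind a flag — the source
  does not state which was used).
* **Spearman ρ** with a large-sample p-value for continuous maps.
* **Overlay accounting**: A-only / B-only / overlaid / union areas in km²
  with percentages of the union at two decimals (round-half-even). The
  three parts sum to the union exactly, by construction.

## The experiment matrix

`run_experiment()` nests three extents (full, quarter, 1/16 windows of the
80 × 80 km landscape — a logarithmic approximation of a
sub-continental : regional : park area ratio that cannot be matched
literally at desk scale) and two grains (1, 5 km) into four combinations,
crosses them with four predictor groups (CLI, LC, CLI+LC, EFAs), and runs
the full pseudo-absence × run × learner matrix per group —
5 × 5 × 4 = 100 models per group and combination, 1600 in total at desk
scale; the 30 × 30 × 10 design of the full-scale study is reachable by
configuration. Every stage derives its seed from the master seed by a
stable label hash, so a master seed reproduces the CSV reports
byte-for-byte. One combination failing aborts only that combination.

Problem sizes used by the shipped analyses and harnesses: the default
80 × 80 km landscape with 2 years of composites for the experiment; 40 × 40
landscapes, 3 pseudo-absence sets × 2 runs × 2 learners for the 20-replicate
driver-recovery and 10-replicate equivalence harnesses. These sizes give
stable statistics while keeping a full reproduction of all analyses in the
tens of minutes on a laptop core.

## Design choices in the harnesses

The driver-recovery species uses the two EVI phenology-cosine metrics as
drivers (coefficients ±4, prevalence 0.1). Drivers were chosen so that
**recovery is identifiable**: level metrics of one dimension are near-perfect
mutual proxies in this generator (ρ ≈ 1 among LST mean/max/min), and no
screening rule can distinguish a driver from a ρ ≈ 1 twin; the phenology
metrics' strongest correlates stay below the 0.8 screening cutoff. The low
prevalence mirrors a narrow-ranged species and also matters statistically:
fresh-presence AUC is evaluated against uniform background, so the
suitable fraction of the landscape bounds the attainable AUC from above.

The equivalence harness (EFA vs CLI+LC) uses a cool-wet montane species
(−2 · TmDQ + 2 · PpWM) on the default climate-coupled generator, so the
satellite dynamics carry the climate signal that drives the species — the
condition under which the two predictor families should tie.

## Numerical conventions and degenerate inputs

Ties: argmax/argmin to the earliest day; wettest/driest quarter to the
earliest window; ROC threshold to the lowest midpoint. Degenerate cases
are errors, not silent values: constant columns in correlation matrices,
all-equal scores at thresholding, single-class splits after bounded
resampling, constant maps in Moran's I, infeasible pseudo-absence
constraints (the error names the binding constraint). Exceptions that
propagate as values: all-nodata cells yield nodata metrics; constant
prediction vectors yield importance 0 with a warning; a held-out score
vector with no discriminating threshold falls back to τ = 0.5 inside
`fit_and_evaluate()` so a degenerate member (typically the range envelope)
is scored rather than fatal.

## Known limitations

* The fuzzy-kappa expectation ignores spatial autocorrelation of the maps,
  so kappa under strong autocorrelation is slightly optimistic relative to
  the improved variant.
* Landscape metrics clip patches at analysis-cell boundaries; cross-cell
  patch structure is invisible.
* The generator's noise is spatially white; real composite errors are
  correlated, so real-data screening will face friendlier-looking
  correlation matrices than it should.
* All grids live in a single planar km CRS; no reprojection, no
  geographic coordinates.
* Pseudo-absence spacing at exactly one grain is nearly vacuous on a
  regular grid (distinct cell centers are already ≥ one grain apart
  orthogonally); the constraint only binds when configured larger.
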