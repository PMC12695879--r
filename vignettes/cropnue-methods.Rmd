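---
title: "Methods: difference-based nutrient use efficiency accounting, trends and mapping"
author: "cropnue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: difference-based nutrient use efficiency accounting, trends and mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nitrogen (N) and phosphorus (P) use efficiency — NUE and PUE — measure the
share of applied fertilizer nutrient that ends up in incremental crop
uptake. The *difference method* compares a fertilized plot with an
unfertilized control:

$$NUE = 100\,\frac{U - U_0}{Input}$$

where $U$ and $U_0$ are whole-plant nutrient uptakes (kg ha$^{-1}$) with
and without fertilization and $Input$ is the fertilizer nutrient applied.
Unlike national nutrient-balance accounting, this isolates the marginal
recovery of the applied inorganic fertilizer. `cropnue` implements a full
analysis pipeline around this statistic for the four major crops (rice,
wheat, maize, soybean): per-record accounting and screening of field
trials, reconstruction of historical country-by-crop-by-year efficiency
series from fertilizer and production panels, breakpoint trend analysis,
random-forest mapping with geostatistical correction, driver analysis,
and surplus assessment — all exercised end-to-end on a synthetic-data
generator with known ground truth.

## Per-record accounting

`efficiency_diff()` returns the raw difference-method efficiency without
clipping: negative values, which arise when the control outyields the
fertilized plot, are physically impossible as recoveries and are excluded
by `screen_observations()` with the reason code `"negative efficiency"`
rather than silently dropped. Efficiencies above 100% are retained (they
can occur legitimately through priming and residual effects) but are
visible to downstream consumers. Screening applies five inclusion
criteria (efficiency or uptake reported; a complete crop cycle; a
location; field-condition paired treatments; crop and input reported),
each with a machine-readable reason code, and prefers efficiencies
recomputed from uptake over reported values when both exist.

Whole-plant uptake from biomass uses $U = G\,c_G + S\,c_S$ with grain and
residue masses and nutrient contents; contents are carried as mass
fractions internally (a single representation, converters at the I/O
boundary) to avoid double percent conversions. The soil-derived share of
uptake,

$$\mathrm{soil\ fraction} = 100\,\frac{U - E \cdot Input}{U},$$

with $E$ the efficiency as a fraction, is clipped to $[0, 100]$ because
noisy inputs can push it out of range; clip events are counted on the
returned object so they can be audited.

The aridity index defaults to the conventional MAP/PET. An as-printed
MAT/PET variant is available (`strict` argument, `strict_paper` pipeline
flag) because some compilations print the temperature form; we do not
guess the intent, we expose both and document the default.

## Historical reconstruction

National fertilizer totals (tonnes, per year) and baseline per-hectare
input intensities (for reference years 1990, 1999, 2018) are reconciled
by a single global scalar per year and nutrient:

$$Input_{co,cr,yr} = Input^{base}_{co,cr} \cdot
  \frac{T_{yr}}{\sum_{co}\sum_{cr} Input^{base}_{co,cr}\,A_{co,cr,yr}}$$

so that the aggregate of adjusted intensity times harvested area equals
the reported total exactly. Years map to baselines by fixed period
divisions (1961–1994 → 1990, 1995–2006 → 1999, 2007–2018 → 2018). Missing
baseline cells are filled in priority order: nearest adjacent baseline
year for the same country and crop, then a planted-area-weighted regional
mean (the "regional correlation" step is not defined precisely in the
source methodology; an area-weighted mean over the configured region is
the transparent choice), then the global crop mean.

Annual series then follow: per-crop fertilizer input
$F = \sum_{co} Input_{co,cr,yr} A_{co,cr,yr}$; uptake
$U = Q\,(c_G + R\,c_S)$ from production $Q$ and the residue–grain ratio
$R$; soil-only uptake $U_0 = U \cdot sf/100$ with $sf$ the soil-derived
fraction predicted per country, crop and year; and
$NUE = 100\,(U - U_0)/F$. Soil fractions are predicted with each year's
climate and input covariates but time-invariant soil properties, because
no defensible interannual soil dataset exists at this scale. A regression
of the annual series on the area-weighted mean input intensity is
reported as a diagnostic (`efficiency_intensity_regression()`) but plays
no role in the reconstruction itself.

## Soil-fraction and efficiency models

Random forests predict (a) the soil-derived uptake fraction used in the
reconstruction and (b) point-scale NUE/PUE for mapping. The feature set
for the soil-fraction task is fixed: MAT, MAP, BD, sand, silt, clay, TC,
TN, TP, AP, pH, Input N, Input P. Training uses a stratified 80/20
train/holdout split and an exhaustive grid search over `ntree`, `mtry`
and `nodesize` scored by 10-fold cross-validated RMSE on the natural
(percentage) scale; the full RMSE surface is retained for inspection.
Default grid axes are `ntree` {250, 500, 1000}, `mtry`
{⌊p/3⌋, ⌊√p⌋, p/2} and `nodesize` {1, 5, 10}; the orchestrated pipeline
uses a single moderate combination (ntree 300, mtry 4, nodesize 5) as its
default because the tuning surface on the synthetic system is flat and
the grid is exercised separately. Categorical management covariates are
one-hot encoded. Missing covariates are imputed from the covariate grid
(nearest cell) before modelling, never inside CV folds' targets.

Per-cell uncertainty is the standard deviation across the individual
trees; the mean equals the ordinary forest prediction. Between-tree
spread is informative where prediction difficulty varies (sparse regions,
heteroscedastic noise) and carries little signal when difficulty is
uniform — the tests exercise it on a heteroscedastic fixture for this
reason. Soil-fraction models are fitted per crop where at least 100
records exist, with a pooled fallback.

## Mapping and geostatistical correction

Surfaces are predicted on a regular lon/lat grid (cell-centre
registration, half-open cells), masked to cells with positive planted
area. The grid container is a plain data frame of cell centres plus named
layers; at desk scale (domains of a few tens of degrees) distances are
Euclidean on degrees, a documented limitation for global runs where
great-circle distances would be needed.

Model residuals (observed minus predicted at trial locations) are
interpolated by ordinary kriging under a variogram fitted by weighted
least squares (Cressie weights) on 15 lag bins; the spherical model is
the default for its boundedness, with the exponential available. The
kriged residual field is added to the predicted surface. Kriging is exact
at observation locations when the nugget is zero; a leave-one-out report
compares residual RMSE before and after correction. If the variogram
degenerates to pure nugget the surface is returned uncorrected with a
warning. Residuals are kriged separately per crop-nutrient surface.

Zonal comparisons (5-class simplified climate zones, or countries) use
Kruskal–Wallis followed by Dunn's pairwise z tests with tie correction;
pairwise p values are unadjusted by default (BH available by flag).
Compact letters are the maximal cliques of the "not significantly
different" graph, which guarantees that two groups share a letter exactly
when their difference is not significant.

## Drivers

Spearman rank correlations relate NUE/PUE to climate, soil, management
and socio-economic covariates, with Benjamini–Hochberg adjustment within
each target-by-group comparison family; constant covariates are reported
as missing, not zero.

The path model is classical PLS-PM: manifests are z-scored, outer
estimation is mode A, the inner scheme is factorial (centroid available;
the factorial scheme is the default because it uses the magnitude of
inter-latent correlations rather than only their sign), iterated until
the outer weights change by less than 1e-6 (300-iteration cap, error on
failure). Manifests with loadings below 0.7 are excluded in a single
pass — not iterated to a fixed point, which keeps the filter
deterministic — and the model refit once; single-indicator blocks are
exempt. Path coefficients are OLS on the unit-variance latent scores;
bootstrap resampling at the observation level (n = 100, seeded) gives
standard errors and two-sided normal-approximation p values; the
goodness of fit is $\sqrt{\overline{\mathrm{communality}} \times
\overline{R^2}}$. Categorical manifests are coded as ordinal integers by
default.

## Assessment

Cells are classified against a 50% threshold into four NUE/PUE quadrants.
The source definitions use strict inequalities on both sides, leaving
exact equality unassigned; cells exactly at the threshold are classified
"low", a deterministic documented tie rule. Planted-area proportions per
category sum to one. Surplus loads follow
$\sum_i A_i \cdot input_i \cdot (1 - E_i)$ per reporting unit, surplus
intensity is the load per unit area, and the intensity SD is the
unweighted sample SD (n−1) of per-cell surplus intensities as printed in
the source formulas — inconsistent in spirit with the area-weighted
intensity, so an area-weighted SD is available behind a flag and labelled
as a departure. Country shares of global surplus are computed from loads,
not intensities. Surplus per unit yield (kg surplus per tonne grain)
joins the pollution and food-security views. Scenario re-prediction
applies labelled climate perturbations (additive MAT, multiplicative MAP)
to the covariate grid and reports per-scenario efficiency deltas.

## The synthetic generator

Every pipeline input is generated with known ground truth so each stage
is testable without downloads:

* **Field trials.** Sites are drawn over a 20°×20° domain; covariates are
  smooth deterministic surfaces plus site noise. The true soil-derived
  fraction is a smooth monotone logistic function of MAT, MAP, pH, TN and
  input intensity (coefficients configurable); the true efficiency is
  100 × (uptake/input ratio) × (1 − soil fraction). Observed efficiencies
  add Gaussian noise (default SD 5 percentage points, a realistic
  field-trial repeatability) truncated below at zero, mirroring the
  exclusion of negative efficiencies at source. Per-nutrient availability
  rates default to the compiled-database imbalance (2354 N and 1006 P of
  2919 records). Ten percent of covariate cells are blanked completely at
  random to exercise grid-based imputation.
* **Panel.** True input intensities are a per-country baseline times a
  global year scalar whose growth decelerates at year 25, renormalised so
  baseline-year intensities equal the baseline table exactly; national
  totals are their aggregate by construction, so the reconciliation
  identity has a known answer. Production is backed out from piecewise-
  linear target efficiency trajectories with a configurable kink (default
  year index 15, i.e. mid-1970s) and 2% multiplicative noise; the
  efficiency series implied by the final noisy panel is stored as ground
  truth. Trial input intensities share the panel's crop base rates
  (lognormal spread) so the soil-fraction model never extrapolates far
  outside its training support — as in reality, where compiled trials
  span historical application rates.
* **Grid.** Covariate surfaces on a 0.5° grid by default (resolution is
  configurable; finer grids are a runtime choice, not a methods change),
  per-crop nonnegative planted-area layers, a 5-class climate-zone
  raster, nearest-centroid country raster, and a spatially autocorrelated
  residual field (exponential covariance, default range 5°, SD 3 pp)
  added to the true efficiency so kriging has signal to recover.
* **Latent-structure data.** `generate_latent_data()` draws from an
  explicit latent-variable model (three indicators per block, loading
  0.9) with configured structural signs — negative climate, positive
  management — used to verify sign recovery of the path model.

What the generator does *not* emulate: real geographic crop
distributions, Köppen classes beyond 5 synthetic bands, reporting-unit
politics (countries are atomic; no EU-style aggregation), measurement
error correlated with covariates, and temporal soil change. Passing tests
therefore demonstrate that the machinery is correct and well-calibrated
under known conditions, not that the substantive global estimates of any
particular compilation are right.

## Numerical choices and degenerate inputs

* Segmented fits initialise the breakpoint at the median of the regressor
  and iterate the linearisation update with the breakpoint clamped to the
  observed interior; convergence is a breakpoint change below 1e-4 (100
  iterations). The iteration is restarted from the best integer-grid
  candidate and the result is never worse than that candidate, guarding
  against local minima on short series. The breakpoint SE is the delta-
  method ratio of the gap-term SE to the slope change. Per-segment slopes
  are tested by separate OLS before/after the break; the break-year
  observation belongs to the later segment.
* Wilcoxon comparisons are exact (enumeration) when both groups have ≤ 10
  observations and no ties, otherwise tie-corrected normal with
  continuity correction.
* Zero fertilizer totals make the efficiency undefined for that year;
  rows are emitted as missing with a warning, not dropped.
* Zero-variance forest targets return a constant model with a warning.
* Kriging adds 1e-10 to the diagonal for numerical stability; the
  variogram fit falls back to pure nugget (no correction) on failure.
* Quadrant threshold ties go to "low"; letters are deterministic given
  the pairwise p values.

## Problem sizes and runtimes

The default end-to-end run uses 2919 trial records, 24 countries × 4
crops × 58 years, and a 40×40 grid; it completes in about 1.5 minutes on
one CPU. The validation suite uses 200 simulated series for breakpoint
recovery, 2000 points for soil-fraction recovery, 100 seeded datasets for
path-sign recovery and 20 seeded fields (300 points each) for the kriging
leave-one-out experiment. These sizes were chosen so that recovery
experiments have tight Monte-Carlo error while the whole suite stays
desk-scale.

## Known limitations

Euclidean-on-degrees distances restrict kriging to regional domains; the
variogram is fitted per surface with no anisotropy; PLS-PM treats
categorical manifests as ordinal; the compact-letter clique enumeration
is exponential in the number of groups (fine up to ~15); and the
reconstruction inherits any bias of the soil-fraction model in regions of
covariate space without trial support.
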