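---
title: "Modelling the relative probability of wild pig occurrence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the relative probability of wild pig occurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Wild pigs (*Sus scrofa*) are among the most damaging invasive vertebrates in
North America. Managers need to know not only where established populations
are, but which unoccupied regions could support them if animals arrive —
whether by natural dispersal or by translocation for hunting. `swinescape`
implements a national-scale species distribution analysis for this problem:
occurrence polygons drawn by wildlife professionals are aggregated to
watershed units, contrasted with a random background sample of watersheds
through a logistic discrimination function, and the fitted model is averaged
over all covariate subsets and mapped as a relative probability of
occurrence.

Because the real survey data are a managed archive, the package ships a
synthetic-landscape generator that reproduces the *statistical structure* of
the inputs — spatially autocorrelated habitat rasters, weather-station
records, contiguous watershed units, and a multi-year contagious occupancy
process with rare long-distance human introductions — with known ground
truth, so every stage of the pipeline is testable end to end.

## The model

Let $z_j$ be the standardized watershed covariates. The estimation data
stack presence watersheds ($y = 1$: every watershed with a retained
occurrence record) over a background sample ($y = 0$: a uniform draw of
twice as many watersheds from *all* watersheds, presences included —
background units are not pseudo-absences). The global model is the logistic
regression

$$\mathrm{logit}\, P(y = 1 \mid z) = \beta_0 + \sum_j \beta_j z_j + \beta_{q} z_{\mathrm{hot}}^2,$$

with seven linear terms — days above 35 °C, days below −4 °C, April-1 snow
depth (m), mean distance to perennial water (km), forest cover (%), forage
cover (%), and a 0–3 habitat-heterogeneity index — plus one quadratic term
for hot days, reflecting the hypothesis that occurrence rises with warm
climate up to a physiological threshold.

Rather than selecting one best model, all additive subsets of the global
model are fitted (192 subsets under marginality, which admits the quadratic
only alongside its linear term) and combined by AICc weights
$w_i \propto \exp(-\Delta_i / 2)$. Coefficients are averaged with
*shrinkage* — a term absent from a subset contributes zero — and their
unconditional standard errors combine within-model variance and
between-model spread:

$$\bar\beta_j = \sum_i w_i \beta_{ij}, \qquad
\widehat{\mathrm{SE}}_j = \sum_i w_i \sqrt{se_{ij}^2 + (\beta_{ij} - \bar\beta_j)^2}.$$

95% intervals use the exact normal multiplier 1.959964 (the printed
intervals of the original analysis reproduce under this multiplier, not
under 2.0). The cumulative weight of the subsets containing a term is its
importance. Predictions use the exponential form $\exp(\sum_j \bar\beta_j
z_j)$ without the intercept — the resource-selection convention, since only
relative values are mapped — or the logistic form with the intercept when a
bounded score is wanted; the two forms rank watersheds identically.

## Covariate engineering

* **Temperature day counts.** For each watershed, the 10 closest stations
  within 250 km of the centroid are selected (ties broken by station id).
  Daily values are transferred to the centroid elevation with the mean
  adiabatic lapse rate, 6.49 °C per 1000 m, *before* thresholding — the
  threshold is nonlinear, so adjusting counts would not be equivalent. Days
  with adjusted maximum above 35 °C and adjusted minimum below −4 °C are
  counted per year, averaged over available years (partial years contribute
  the days they have), then across stations. Stations are de-duplicated by id before selection, and daily records are
  keyed by day-of-year and year, so repeating a station's record cannot
  shift the mean.
* **Snow depth.** April-1 depth grids are averaged cell-wise over years and
  then within watersheds.
* **Distance to water.** Streams below 3 cubic feet per second of average
  annual flow are removed as ephemeral; an exact Euclidean distance
  transform (cell centre to cell centre, water cells at 0) is averaged per
  watershed.
* **Cover fractions.** Percent of watershed cells in the forest class set
  and in the forage (crop + hard mast) set. Two forest presets are shipped
  because land-cover practice is ambiguous about woody wetlands; the default
  counts them as forest.
* **Heterogeneity.** For each focal cell, the number of the three key
  resources (water, cover, forage) present within a circular window whose
  area is the 9 km² average sounder home range (radius
  $\sqrt{9/\pi} \approx 1.69$ km); per-watershed means give a continuous 0–3
  index. The disk uses the true radius in cell units with boundary ties
  included — rounding the radius to whole cells would change the kernel and
  break the exhaustive-scan equivalence the tests enforce. Windows are
  truncated at grid edges.
* **Standardization.** Covariates are centred and scaled (sample SD, n−1) on
  a *stated* sample, kept as metadata for back-transformation. The default
  is the estimation sample (presence + background rows, duplicates
  included), so the fitted scale matches the estimation data; the
  recovery and calibration studies instead standardize over all watersheds,
  the scale on which their true coefficients are defined. Both choices are
  exposed because the original analysis does not state which it used.

## Occurrence ingestion

A population polygon marks a watershed present in a year only if the
polygon's total area exceeds 13 km² (three times the mean U.S. home range)
*and* it covers more than 2.5% of the watershed. First-occupancy records
whose centroid lies farther than a dispersal threshold from every watershed
occupied the previous year are flagged as likely human introductions;
year-1 founders are never flagged. A flagged watershed re-enters the
presence data from the first later year it is re-reported or an adjacent
watershed becomes occupied. The threshold is a required parameter: when not
configured it defaults to the 95th percentile of observed first-occupancy
distances, mirroring the use of the observed distance distribution; the
resolved value is echoed in every report. Watershed-to-watershed distance is
centroid-to-centroid Euclidean distance, and "adjacent" means sharing a
partition boundary edge.

## Validation

Discrimination metrics (AUC and kin) are inappropriate for presence versus
*background* labels, so validation uses the RSF plot index: the data are
split into 4 folds (following the square-root allocation rule for
discriminant problems), each set of three folds is model-averaged in full
and predicts the withheld fold, the pooled withheld scores of an iteration
are binned, and the Pearson correlation between bin midpoints of the
predicted scores and the observed fraction of presences per bin measures
proportionality. One hundred random re-allocations are averaged. Both
quantile and equal-interval binning are computed; the bin count (default
10) is unstated in the original analysis, so it is exposed and reported in
all outputs. For equal-interval bins the midpoint is the interval centre;
for quantile bins it is the median score in the bin, which avoids
empty-interval artifacts. Withheld predictions are pooled across folds
within an iteration (one r per iteration per method); per-fold binning also
exists in the code path via `rsf_plot_index()` on a single fold's
predictions. Folds are drawn over the union of presence and background
records with labels preserved.

## The synthetic generator

All randomness flows from one root seed through a documented splitting
scheme (`derive_seed()`), so every artifact is bit-reproducible. Continuous
fields are Gaussian random fields (white noise smoothed by FFT with a
Gaussian kernel whose SD is the correlation length, default 30 km).
Watersheds are contiguous cell clusters grown from random seeds — a
partition with areas, centroids, and adjacency, not hydrological units,
which is all the analysis consumes. Station elevations are anchored to the
elevation raster and daily temperatures are generated from
latitude/elevation climatologies tied through the same 6.49 °C/km lapse
rate, so the lapse correction is exercised for real; summer-heat and
winter-cold climatologies use separate fields so the two day-count
covariates are correlated (as in real climate) but not collinear.

Occupancy starts in the top 1% of watersheds by true linear predictor (the
colonization origin is not documented in the source analysis; a
suitability-based seed is the neutral choice), spreads each year to
adjacent watersheds with probability $\mathrm{logit}^{-1}(\beta_0^{\mathrm{true}} +
\beta^{\mathrm{true}\prime} z)$, stays occupied forever, and receives
Poisson-rare introductions placed beyond the dispersal threshold. The
default true intercept (−4) yields roughly a quarter to a third of
watersheds occupied after 31 years, matching the occupied fraction of the
real record. Each occupied population (connected component) emits a yearly
polygon covering 60% of each member watershed's cells, grown around the
watershed centroid — the real polygons are drawn by hand, so this emission
rule is a stand-in whose coverage fraction is configurable to exercise both
aggregation criteria.

What the generator does *not* emulate: real hydrology and stream topology,
demographic population dynamics, observation effort varying across states
and years, and the hand-drawn character of survey polygons (e.g. single
polygons spanning an entire state). Passing tests therefore show that the
*method* recovers known structure under the stated sampling assumptions,
not that the original survey data satisfy those assumptions.

## Recovery and calibration study designs

Parameter recovery and cross-validation calibration need data for which the
logistic discrimination function is *exactly* well specified, which
contagious spread is not. `sample_presence_background()` draws presence
watersheds i.i.d. with probability proportional to $\exp(\beta' z)$ and
background watersheds uniformly; the log odds of the label given $z$ is
then exactly linear in the model terms with slopes $\beta$. The recovery
suite uses 50 replicates (5 landscapes × 10 draws) of 1500 presence + 3000
background draws and checks that each true coefficient is covered by its
averaged 95% interval in at least 90% of replicates and that active terms
carry more cumulative weight than inactive ones; the calibration suite runs
the full 4-fold averaging procedure for 10 iterations on 500 + 1000 draws
and expects mean RSF-plot correlations above 0.9 under both binning methods
with a small inter-method gap. These problem sizes keep the whole suite to
a few minutes on one CPU while leaving the statistical conclusions stable.

## Numerical choices and degenerate inputs

* Logistic fits use iteratively reweighted least squares
  (`stats::glm.fit`) with a tightened deviance tolerance; convergence is
  verified against the score equations (gradient max-norm < 1e−8). Apparent
  separation or non-convergence is recorded as a warning state on the fit,
  and such subsets keep their ledger entry with their computed likelihood —
  dropping them would bias the weights.
* A singular design reports infinite VIF rather than failing; the
  collinearity screen flags terms but never drops them (exclusion is the
  analyst's decision, and the screen's report is written to the run log).
* Akaike weights are normalized over the complete ledger and checked to sum
  to one within 1e−10; `AICc` refuses `n ≤ k + 1`.
* Degenerate binning (constant predictions, or fewer than two non-empty
  bins) is an explicit error, not a silent NA.
* Distance ties in station selection are broken by station id; ties at the
  heterogeneity disk boundary are included.

## Limitations

The synthetic landscape is a torus-stationary Gaussian world with
rectangular geometry; absolute covariate values (e.g. day counts) are
plausible but not calibrated to any real region. The natural-scale optimum
of the hot-days response is reported from the model's own standardization
metadata; it is sensitive to the standardization sample and should not be
read as a portable physiological constant. Model averaging with shrinkage
trades a small coverage loss on weakly supported terms for reduced
selection bias — the recovery suite quantifies exactly this. Spatial
autocorrelation of residuals is not modelled, matching the original
analysis; neither are observation effort or detection error.
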