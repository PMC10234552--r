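---
title: "Methods: hybrid near-road data fusion, RAMP correction, and equity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid near-road data fusion, RAMP correction, and equity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadfusion)
```

## The problem

Chemical transport models (CTMs) report cell-average concentrations on
coarse grids (typically 12 km), which averages away the sharp concentration
gradients of traffic-related pollutants: near-road PM2.5 and NO2 decay to
background levels within roughly 150–200 m of a major road. Exposure
assessment on the coarse grid therefore misclassifies the exposure of the
population living near roads — a population with a systematically higher
Minority share. Dispersion models resolve the near-road gradient but miss
secondary pollutants and regional background, and both model families carry
biases that vary in space and with concentration.

`roadfusion` implements a three-stage remedy at census-block resolution:

1. **Hybrid fusion** — combine the coarse CTM field with a fine-scale
   near-road dispersion field so the fused estimate keeps the regional
   background *and* the near-road gradient.
2. **RAMP correction** — calibrate the fused field against monitor
   observations with per-cell decile-bin curves, correcting bias that is
   *nonhomogeneous* (varies across cells) and *nonlinear* (varies with
   concentration).
3. **Assessment** — convert block-level annual exposures into attributable
   premature mortality (with confidence intervals) and race-stratified
   exposure inequity ratios, aggregated by county, administrative unit and
   distance from road.

Because the national inputs behind such an analysis (CTM runs, dispersion
runs for millions of road segments, the monitor network, census and
mortality data) are not desk-scale, the package ships a seeded synthetic
world generator with the statistical structure the method assumes. All
statements below about what the pipeline achieves are statements about this
synthetic world, computed by the test suite and the acceptance script.

## Hybrid fusion

For a block centroid $p$ in coarse cell $G(p)$, with $C_{tot}$ the coarse
cell total, $R_{gavg}$ the dispersion field averaged over the cell's
receptor lattice (144 receptors per cell by default), and $R_{cbc}$ the
dispersion estimate at the centroid itself:

$$\mathrm{HYB}(p) = \big[(C_{tot} - R_{gavg})\ \text{interpolated to } p\big]_+ + R_{cbc}(p)$$

Subtracting $R_{gavg}$ removes the on-road contribution already contained
in the cell average, avoiding double counting; the road-free remainder is
bilinearly interpolated to the centroid; the fine-scale on-road field is
added back. Where the interpolated remainder is negative (the two models'
biases can produce this) the fused value falls back to the on-road term
alone — the *zero-out rule*. Two consequences hold by construction and are
property-tested: the fused value never falls below the on-road term, and
with no roads anywhere the fused field is exactly the interpolated coarse
field.

Design choices the interface exposes:

* **Interpolation dialect.** "Linear interpolation" on a regular grid is
  implemented as bilinear interpolation among the four surrounding cell
  centres, with coordinates clamped to the centre hull at the domain rim.
  It is the simplest scheme consistent with linearity on a regular grid.
* **Zero-out at the point, not the cell.** The negativity test applies to
  the interpolated difference at each point, matching the order of
  operations in the fusion formula (the bracket is interpolated first).
* **NOx pathway for NO2.** Dispersion models predict NOx; NO2 is obtained
  by a degree-4 polynomial yield fitted to near-road (NOx, NO2/NOx) pairs
  (`fit_no2_yield()`). The fitted polynomial is evaluated with the input
  clamped to the fitted NOx range and its value clipped to $[0, 1]$, so
  NO2 always lies in $[0, \mathrm{NOx}]$ — a quartic extrapolated outside
  its data is otherwise unbounded. No default coefficients are shipped:
  the yield curve is data-set specific, so it is fitted or user-supplied.

## RAMP correction

For each coarse cell, the `n_sites` monitors nearest the cell centroid are
selected (ties broken by site id), and daily model values are paired with
daily observations over the year — one pair per (site, day) present on both
sides. The pairs are sorted by predicted value and split into 10 contiguous
rank-based bins of near-equal size (remainder to the lowest bins; stable
sort keeps ties in rank order). Each bin contributes a node: mean predicted
value (abscissa) and mean observed value $\lambda_1$ (ordinate). The grand
observed mean $\lambda_{1,M}$ anchors the curve's centre.

The monotonicity safeguard works centre-out: the 5th node is capped at
$\lambda_{1,M}$ and the 6th floored at it; then each node left of centre is
clamped from above by its right neighbour (k = 5..2), and each node right
of centre from below by its left neighbour (k = 7..10). The result is
non-decreasing with $\lambda_1(\tilde z_5) \le \lambda_{1,M} \le
\lambda_1(\tilde z_6)$, which guarantees the correction preserves the
ordering of estimates within a cell (ordinality). Correction is
piecewise-linear interpolation through the nodes, extending the terminal
segments' slopes beyond the outer nodes, floored at zero.

Numerical and degenerate-input choices:

* **Bin abscissa** is the mean predicted value within the bin (the curve is
  anchored where the data actually sit, not at bin edges).
* **Degenerate cells** (all predictions identical) collapse to the constant
  $\lambda_{1,M}$.
* **Sparse cells** falling below `min_pairs` (default 100) fall back to a
  single pooled curve fitted on all sites' pairs.
* **Duplicate-x nodes** are merged into one node at their mean value before
  interpolation.
* **Daily vs annual.** Correction is applied to daily values and the annual
  mean taken afterwards (`ramp$mode = "daily"`), consistent with the daily
  pairing; an `"annual"` mode is available as a configuration switch.
* **Identity recovery caveat.** If observations equal predictions exactly,
  the fitted curve has identity nodes and the correction is the identity
  map inside the node range — *provided* the grand mean lies between the
  two central bin means. That bracketing holds asymptotically but can fail
  for small skewed samples, in which case the centre anchor (correctly,
  per its definition) adjusts even an identity curve. The property tests
  use sample sizes where bracketing holds with overwhelming margin.

The stated inequality form of the safeguard in the method's description is
contradictory as printed (a "monotonically increasing" goal with a
decreasing comparison); the implementation enforces non-decreasing node
values, which matches the stated goal and the $\lambda_{1,M}$ anchoring.

## Model evaluation

`evaluate_model()` computes the standard paired-annual suite: FAC2
(inclusive factor-of-two percentage), ME, SDE, RMSE, MZ, SDZ, MO, SDO,
squared Pearson correlation and squared Spearman rank correlation. All
moments are population moments, so $\mathrm{RMSE}^2 = \mathrm{ME}^2 +
\mathrm{SDE}^2$ holds exactly — a decomposition the test suite asserts on
10,000 random vectors.

## Health impact

Attributable deaths per block use the log-linear attributable fraction
$\mathrm{AF} = 1 - e^{-\beta (C - C_0)}$ with $\beta = \ln(\mathrm{RR})/10$
for a relative risk RR per 10 µg/m³, floored at zero below the
counterfactual $C_0$ (default 0: burden attributable to all sources):

$$\Delta M = \mathrm{Pop} \times f_{25+} \times r_{county} \times \mathrm{AF}(C)$$

Defaults: RR 1.0129 [1.0109, 1.0150] per 10 µg/m³ for PM2.5; hazard ratio
1.04 [1.02, 1.06] per 10 µg/m³ for NO2. Confidence bounds scale the central
estimate by the excess-risk ratios $(\mathrm{RR}_{bound} - 1) /
(\mathrm{RR}_{central} - 1)$ — for the NO2 CRF exactly 0.5× and 1.5×. This
proportional slope-ratio convention reproduces published total-burden CIs
to the printed integer, which a per-bound recomputation of the log-linear
form does not; `consistency_checks()` verifies this at run time. NO2 fields
in ppb are converted at 1.88 µg/m³ per ppb (25 °C, 1 atm; configurable)
before the CRF is applied.

Two-model difference accounting (`compare_models()`) works at county level:
the per-county difference is split into the summed positive part (regions
where model a exceeds), summed negative part, and their net — applied
component-wise to CI bounds. Distance profiles use half-open 25-m bins with
bin and cumulative population.

## Exposure inequity

The exposure inequity ratio (EIR) is the Minority (all non-White groups
combined) population-weighted exposure divided by the White
population-weighted exposure. It is computed nationally, per county / tract
/ block group (with count, mean, sd and 50/95/99/99.9 percentiles across
units, linear interpolation between order statistics), and in half-open
10-m distance-from-road bins. Units where either group has zero population
are excluded from distributions and counted; distance bins beyond 2 km are
flagged low-confidence (few blocks, small populations, noisy ratios). EIR
is invariant to multiplicative rescaling of the concentration field, and an
additive shift moves it toward 1 — both property-tested.

## The synthetic world

The generator emulates the statistical structure the method assumes, on a
planar Cartesian domain in metres (no geodesy — real inputs must be
pre-projected):

* **Truth** = smooth regional background + near-road increment. The
  background is a constant plus two low-spatial-frequency plane waves plus
  a seasonal sinusoid (gradient bounded by $\sum_k A_k 2\pi/\lambda_k$).
  The increment uses an exponential line-source kernel
  $\sum_j \alpha E_j e^{-d_j/L}$ with decay length $L = 150$ m, matching
  the 150–200 m near-road decay premise; full plume physics is deliberately
  out of scope — the method under test only needs a field with the correct
  gradient structure.
* **Coarse model** = subgrid truth mean (12×12 points per cell, mirroring
  the 144-receptor lattice) distorted by
  $g_c(x) = a_c + b_c x + s_c x^2/(x+h)$ with coefficients varying smoothly
  across cells — a nonhomogeneous, nonlinear bias by construction.
* **Dispersion model** = road increment × lognormal multiplicative error
  (median 1.2, log-sd 0.25 by default; dispersion models typically carry
  multiplicative bias). The realisation is a counter-based hash of (rounded
  location, day, seed), so a given point/day always sees the same error
  regardless of call batching.
* **Monitors** = truth + additive Gaussian noise (sd 0.5), floored at 0; a
  configurable fraction observes one-in-three days (the PM2.5 filter
  cadence), the rest daily. A quarter of monitors are sited near roads;
  real networks' siting is not documented, so this is an exposed parameter
  rather than a guess.
* **Population**: block totals are lognormal; race groups are a multinomial
  split (so group counts sum exactly to the total) with Minority share
  $\mathrm{logit}^{-1}(b_0 + \theta e^{-d/200})$ — $\theta$ is the
  near-road segregation dial, $\theta = 0$ makes race independent of road
  proximity. The 25+ fraction is drawn per tract and copied to its blocks.
  Counties, tracts and block groups are nested regular partitions of the
  domain.
* **Seeds.** One master seed; each stage (roads, monitors, blocks,
  population, tract fractions, observation noise, dispersion error,
  baseline rates) draws from its own derived stream, so stages can be
  regenerated independently and worlds are bit-identical given
  (config, seed).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: chemistry and meteorology, emission factors and fleet
mix, monitor siting bias, spatially correlated observation error, census
undercount, or migration/commuting exposure. The synthetic world validates
the *method's mechanics* (fusion exactness, bias recovery, accounting
identities), not national-scale magnitudes.

## Study configuration and problem sizes

`study_config()` fixes the end-to-end operating point: a 4×4 grid of 12-km
cells, 12 road chords, 40 monitors, 5,000 blocks, 365 days. Unit tests use
a 3×3 grid with 300 blocks and a 30-day year. Calibration in the study
configuration uses the 10 monitors nearest each cell: the published
operating points (50 sites for PM2.5, 10 for NO2 — kept as the package
defaults) select a comparably small fraction of their monitor network, and
with only 40 sites selecting 50 would saturate to the whole network, making
every cell's curve identical and disabling the regional correction the
method exists for.

On this configuration the corrected field robustly beats the fused field
against truth (RMSE roughly an order of magnitude lower; Pearson R²
strictly higher across seeds), the no-segregation world gives a national
EIR within 0.05 of 1, and the segregated world gives EIR above 1 within
200 m of roads — the acceptance script recomputes all of these.

```{r example, eval = FALSE}
res <- run_pipeline(study_config(), seed = 1)
evaluate_model(res$annual$truth, res$annual$ramp_hyb)
res$equity$national$eir
```

## Known limitations

* Bilinear interpolation under-resolves background harmonics shorter than
  about two cell widths; the fused field inherits that error (it is the
  coarse model's information limit, not the fusion's).
* The pooled fallback for sparse cells removes the regional component of
  the correction in those cells.
* CI propagation by slope-ratio scaling treats the CRF slope as the only
  uncertainty source; baseline rates and populations are taken as fixed.
* The non-homoscedastic extension of the calibration (assigning a variance
  to each corrected value) and full Bayesian data fusion are out of scope.
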