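---
title: "Gridded population estimation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gridded population estimation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpop)
```

## The problem

Census population counts exist only for administrative units, but many
applications — exposure assessment, epidemiological denominators, service
allocation — need population on a fine regular grid. `gridpop` implements
two complementary estimators that turn building covariates (density, height
and type at 10 m resolution) into persons per cell, plus the validation
machinery to judge the results against census data at several aggregation
scales.

**Top-down dasymetric redistribution.** A zone's known census total
$pop_{total}$ is spread over its cells proportionally to a nonnegative
weight layer:

$$pop_{ij} = \frac{w_{ij}}{\sum_{(i,j) \in z} w_{ij}} \; pop_{total}(z).$$

Binary weights ($w_{ij} = inh_{ij} \in \{0,1\}$) give every admissible cell
an equal share; continuous weights refine this. The scheme is
volume-preserving by construction — per-zone cell sums reproduce the census
— and invariant to rescaling the weights. Five weighting layers form a
gradient of covariate complexity:

| tag | weight |
|------------|----------------------------------------------------------|
| BD-BUILD | 1 on cells with building density > 25 % |
| BD-RESI | 1 on residential (SF/MF) cells of that mask |
| WD-DENS | building density on residential cells |
| WD-VOL | building volume (density × height) on residential cells |
| WD-VOLADJ | volume with multi-family cells scaled by a factor (1.6) |

The *best product* redistributes the finest census level (municipal
analogue) with WD-VOLADJ weights.

**Bottom-up floor-area estimation (BU-LFA).** With no a-priori total,
persons per cell are living floor area divided by living floor area per
capita:

$$pop_{ij} = \frac{\max\!\big((bHeight_{ij} - rHeight)/fHeight,\; 1\big)
  \cdot bResDens_{ij} \cdot 0.8}{LFA/cap_{t,s}},$$

on single- and multi-family cells only; industrial/commercial and
lightweight-structure cells carry no de jure population.

## Tunable parameters

* `floor_model()`: roof height 3.00 m (uninhabited roof space is
  subtracted before counting floors), floor height 4.50 m (empirical
  residential range is roughly 4.00–5.55 m), exclusion of buildings below
  2.00 m, floor count clamped below at 1.00, habitable factor 0.8 (walls,
  staircases). All are configurable so floor-height sensitivity can be
  explored. The exclusion is tested on raw height *before* the roof
  subtraction; the clamp applies *after* it — the conversion reads
  naturally in that order, and the alternative order would let a 4 m
  building be excluded by its post-roof height.
* `building_mask()` threshold: 25 % building density, strict (`>`), so a
  cell at exactly 25 % is not built-up. Configurable.
* `mf_factor` (default 1.6): multi-family housing offers less floor area
  per person, so MF volume is up-weighted. `mf_factor_sweep()` re-runs
  WD-VOLADJ over a factor grid and flags the MAPE argmin.
* `min_density` in `bu_population()` (default 0): the 25 % threshold is a
  top-down masking rule; the bottom-up estimator uses every residential
  cell with positive density, because low-density residential cells still
  hold real floor area. Configurable for users who prefer symmetry with
  the mask.

## Validation metrics

Per validation unit the signed relative estimation error is
$REE = 100\,(est - ref)/ref$; MAPE is the unweighted mean of $|REE|$
across units. MAE, RMSE, the slope and $R^2$ of an ordinary least-squares
fit of estimate on reference (free intercept; switchable to
through-origin) complete the aggregate picture. The REE histogram uses ten
signed bins (0–10, 10–25, 25–50, 50–100, > 100 % on each side), tallying
both units and their reference population; tallies are conserved. Three
conventions the metric definitions leave open are fixed as follows: units
with zero reference are excluded from REE/MAPE and reported separately; an
REE of exactly 0 counts as a (nonnegative) 0–10 % case; bin edges are
closed on the side away from zero. Slope and $R^2$ come from a regression
because scatterplot-style validation motivates a regression reading; the
unweighted MAPE treats every unit equally regardless of size.

The average spatial resolution $ASR = \sqrt{A/n}$ (km) summarises a
level's granularity; the ASR ratio between census-input and validation
levels quantifies the scale offset of a disaggregation experiment. For a
single input unit the ratio is exactly $\sqrt{n_{validation}}$.

## The synthetic landscape generator

Real covariate rasters and census tables are large external products, so
the package generates landscapes with the same statistical structure and a
*known* per-cell truth:

* settlement patches around random seeds with an urban–rural density
  gradient, density in [0, 100] concentrated in patch cores;
* heights positively correlated with density at a configurable target
  (default 0.7). The height field mixes the standardised density signal
  with spatially smoothed Gaussian noise; the 50 m mean smoothing that
  observed height products carry is applied to the stochastic component
  rather than to the finished layer, because post-hoc smoothing of the
  mixture would shift the realised correlation by a config-dependent
  amount and the correlation target could no longer be honoured;
* types along the gradient: multi-family in dense cores (density ≥ 60 %),
  single-family at fringes, industrial/commercial as separate patches
  (a share of seeds), scattered lightweight structures on low-density
  cells;
* a nested zone hierarchy from recursive alternating-axis jittered median
  splits — contiguous, irregular, exactly nested zones at counts
  (1, 4, 16, 64) by default, giving a national unit above state /
  district / municipality analogues;
* truth population from the floor-area forward model itself, times
  multiplicative lognormal noise (sigma 0.25 by default), integerised
  hierarchically by largest remainder: leaf-zone totals are rounded
  against the rounded global total, then cells against their zone target.
  Every cell stays within one person of the raw model, the grand total
  moves by less than one person, and census tables at every level are
  exact integer aggregates of the truth grid.

Because the truth *is* the forward model, noise-free scenes admit exact
parameter-recovery tests: the bottom-up estimator must reproduce the truth
up to rounding, and a scene whose LFA/cap table encodes a 1.6-fold MF
inflation must return 1.6 from the factor sweep. For the sweep check the
scene uses a proportional floor model (roof height 0, no exclusion, no
clamp): under the default model floors are an *affine* function of height,
so truth per unit volume would not carry the constructed factor exactly
and the argmin would drift upward for reasons unrelated to the sweep
logic.

Every leaf zone is guaranteed a small single-family hamlet
(`populate_all_zones`, default on). Administrative units are drawn around
settlements — municipalities with zero population are essentially
nonexistent — and without the guarantee a synthetic leaf zone can consist
purely of industrial or lightweight cells, have zero census, be excluded
from MAPE by the zero-reference rule, and thereby let the coarsest binary
scheme park estimate mass in excluded zones at no cost. That is an
artifact of the generator, not a property of real hierarchies, so the
generator removes it.

What the generator does **not** emulate: satellite-derived measurement
error in the covariates (heights and densities are internally consistent
by construction), classification error in building types, road networks
and OSM-style corrections, or realistic city-size distributions. Passing
tests therefore demonstrate the correctness and internal consistency of
the estimators and metrics, and the qualitative covariate-complexity
gradient — not the absolute accuracy achievable on real imagery-derived
inputs.

## Numerical and degenerate-input choices

* Density construction clamps negative imperviousness-minus-infrastructure
  differences to 0 (a physical share cannot be negative).
* Zones with positive census and all-zero weights: the default fallback
  spreads that zone's census uniformly over its cells with a warning
  (mass is preserved, the data inconsistency is flagged); `"strict"`
  raises instead.
* Population grids stay real-valued; `integerize_population()` offers
  largest-remainder export, globally or balanced per zone.
* Geographic-CRS rasters are rejected rather than silently reprojected;
  all grids must share shape, cell size, origin and CRS note exactly.
* Cell-centre containment with lowest-id tie-break is the rasterisation
  convention for any polygon-derived zone input.

## Problem sizes

The default scene is 128 × 128 cells (1.64 km² at 10 m) with four zone
levels; conservation and ordering properties are checked over 5–10 seeds,
and oracle-equivalence checks run on 100 random 8–16-cell grids against
literal per-cell loop implementations. These sizes give stable statistics
for every property the package asserts while keeping a full run of the
suite in seconds.

## Known limitations

* MAPE on desk-scale scenes is dominated by small-population zones; its
  absolute values are not comparable to values computed over units with
  thousands of inhabitants, though orderings across methods are.
* The generator's distributions (seed counts, density gamma, height mean
  and spread, LFA/cap around 45/35 m² per person) are plausible stand-ins
  chosen once, not calibrated fits to any national building stock.
* The ASR ratio printed for one input unit assumes both levels span the
  same total area; partial coverage is not modelled.
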