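# gridpop

Fine-scale gridded *de jure* population estimation from building
covariates, for spatial demographers, epidemiologists and anyone who needs
a population denominator on a regular grid rather than on administrative
polygons.

Census counts exist per administrative unit; `gridpop` moves them onto
10 m grid cells (top-down) or estimates cell populations with no census
total at all (bottom-up), and quantifies how good the result is.

**Top-down dasymetric redistribution.** Each zone's census total is spread
over its cells proportionally to a nonnegative weight layer,

```
pop_ij = w_ij * pop_total(z) / sum_{cells in z} w_ij ,
```

with five weighting schemes of increasing covariate complexity: binary
building presence (BD-BUILD), binary residential presence (BD-RESI),
building density (WD-DENS), building volume = density × height (WD-VOL),
and volume with multi-family cells up-weighted by a factor, 1.6 by default
(WD-VOLADJ). Redistribution is volume-preserving: zone aggregates of the
output reproduce the census exactly. The *best product* redistributes the
finest census level with WD-VOLADJ weights.

**Bottom-up floor-area estimation (BU-LFA).** Persons per cell are living
floor area divided by living floor area per capita (LFA/cap, by region and
residential type):

```
pop_ij = max((bHeight_ij - 3.00) / 4.50, 1.00) * bResDens_ij * 0.8
         / (LFA/cap)_{type, region} ,
```

with buildings below 2.00 m excluded, on single- and multi-family cells
only.

**Validation suite.** Signed relative estimation error (REE) per unit,
MAPE, MAE, RMSE, regression slope and R², ten-bin REE histograms (units
and population per bin), average spatial resolution ASR = sqrt(area / n)
and ASR ratios between census-input and validation levels, plus
sensitivity harnesses: an MF-factor sweep and temporal/spatial LFA/cap
transfer experiments.

**Synthetic landscapes.** `generate_landscape()` builds scenes with the
statistical structure the estimators assume — settlement patches,
density-correlated heights, type gradients, nested admin zones — and a
known per-cell ground-truth population whose census tables are exact
integer aggregates, enabling end-to-end correctness and recovery tests.

## Worked example

```r
library(gridpop)

scene <- generate_landscape(scene_config(seed = 42))
scene
#> <synth_scene> 128 x 128 cells at 10 m (seed 42)
#>   built cells: 3409 (20.8%), truth population 5347
#>   types: NONE=12975 SF=1467 MF=1400 IC=444 LS=98
#> <zone_hierarchy> 4 level(s), total area 1.64 km2
#>   L1               1 zones, ASR 1.280 km, census total 5347
#>   L2               4 zones, ASR 0.640 km, census total 5347
#>   L3              16 zones, ASR 0.320 km, census total 5347
#>   L4              64 zones, ASR 0.160 km, census total 5347

# redistribute the national census with adjusted-volume weights,
# validate against the municipal level
pop <- redistribute(scene$zones,
                    make_weights("WD-VOLADJ", scene$covariates),
                    which_level = 1)
validate_grid(pop, scene$zones, which_level = 4)
#> <pop_validation> WD-VOLADJ at level L4 (input level L1)
#>   units: 64 validated, 0 excluded (zero reference)
#>   MAPE 16.65%  MAE 9.45  RMSE 20.46  R2 0.9816  slope 1.0330
#>   ASR: input 1.280 km, validation 0.160 km, ratio 8.00

# bottom-up estimate, no census input
bu <- bu_population(scene$covariates, scene$region_map, scene$lfa_table)
total_population(bu)
#> [1] 5170.1   # truth is 5347
```

Reading the numbers: redistributing a *single national* census count down
to 10 m cells and re-aggregating to the 64 municipal-analogue zones leaves
a mean absolute percentage error of ~17 % with slope ≈ 1 and R² ≈ 0.98 —
the weights place population in the right zones with modest local error.
The bottom-up total (5170) deviates from the truth (5347) because the
truth carries multiplicative noise the estimator cannot see; with
`noise_sd = 0` it recovers the truth to rounding.

Plot methods exist for scenes, grids and validation reports
(`plot(scene)`, `plot(pop)`, `plot(report)`), and `run_pipeline()` drives
simulate → redistribute (all methods) → bottom-up → validate end to end,
writing ASCII-grid rasters, CSV/JSON reports and a run manifest.

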