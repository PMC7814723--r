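---
title: "Methods: raster accessibility, hotspot and equity modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raster accessibility, hotspot and equity modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hfaccess` implements a country-scale geographic accessibility and equity
analysis for tiered health-facility systems: friction (speed) surfaces per
transport scenario, least-cost travel-time rasters to the nearest eligible
facility, population coverage within travel-time thresholds, bicycle-versus
-walking time-savings layers, Getis-Ord Gi* hotspot detection on zonal
travel times under higher-order queen contiguity, and a covariate-modeling
workflow relating access to poverty and population density. A synthetic
landscape generator supplies inputs with known structure so every stage is
testable without external data.

All geometry is planar (meters). Rasters are plain matrices on a shared
`grid_spec`; administrative zones are raster label fields; roads are
segment tables; protected-area barriers are rectangles. Real-data adapters
are expected to reproject and rasterize upstream of this package.

# The accessibility model

## Friction surfaces

Each transport scenario (`walk`, `bicycle`, `drive`) maps every surface
class to a speed in km/h. The shipped default table assigns roads 6/12/100
km/h (primary), 6/12/50 (secondary) and 6/12/30 (tertiary) for the three
modes respectively, and landcover speeds between 0 and 12 km/h; open water
and regularly flooded areas carry speed 0 and are impassable. Within a
cell, a road's speed *strictly overrides* the landcover speed (no
averaging): this is the simplest testable merge rule and matches the
merge-order convention of raster cost-distance tools. Cells inside
protected-area polygons are impassable unless a *major public road*
transects them; we interpret "major public" as primary or secondary (the
inter-town network), exposed as `barrier_road_classes` so tertiary can be
included if a user's road taxonomy differs.

Speed uncertainty is modeled by a uniform multiplier: 0.8 and 1.2 bracket
the central run at 1.0 (a −20%/+20% band standing in for travel delays).
The multiplier scales friction exactly, so travel times scale exactly by
its inverse — a property the test suite asserts to 1e−9.

Roads are rasterized with a supercover line traversal: every cell the
segment passes through is burned, and both side cells are kept at exact
corner crossings. A plain Bresenham line can leave diagonal gaps that an
8-connected shortest path would "jump" through; supercover prevents this.

## Travel time

Travel time to the nearest eligible facility is an exact multi-source
Dijkstra on the 8-connected grid graph. The cost of the step between
adjacent cells $a$ and $b$ is

$$t_{ab} = \frac{d/2}{v_a} + \frac{d/2}{v_b},$$

with $d$ the cell size for orthogonal moves and $d\sqrt2$ for diagonal
moves: half the step is traversed at each cell's speed. This rule is
symmetric ($t_{ab}=t_{ba}$) and is the convention used by raster
cost-distance implementations. The same rule is used by the independent
shortest-path oracles in the test suite, so the tests check the solver,
not the cost convention.

Facility tiers follow a strict order HC2 < HC3 < HC4 < GH < RRH < NRH, and
a level-$L$ analysis admits every facility of tier $\ge L$, because any
service offered at $L$ is also offered further up the referral chain.
Facilities whose coordinates fall on impassable cells snap to the nearest
passable cell within 3 cells (configurable); real facility coordinates
routinely fall on masked pixels. Unreachable cells carry `+Inf`, written
to files as a declared NODATA value.

Slope-corrected (DEM-based) walking speeds are deliberately *not* applied:
the speed model is a flat per-class table, and the package does not
generate terrain (a non-goal of the synthetic scenes).

## Coverage

Coverage is the population-weighted share of cells within a threshold
(default 60 minutes), with a *closed* comparison (`minutes <= threshold`):
"within one hour" includes cells exactly at the boundary, which matters on
coarse grids. The denominator is the total study-area population,
including people on unreachable or impassable cells — coverage is a share
of the whole population, not of the reachable one. `coverage_matrix()`
reports, per tier level and mode, the central value at multiplier 1.0 and
a (low, high) interval from the 0.8/1.2 runs.

Two orderings follow from the speed model and are asserted per run rather
than assumed: bicycling speed is at least walking speed for every class,
so bicycle coverage dominates walking coverage; and the eligible facility
set shrinks as the tier level rises, so coverage is non-increasing from
HC2 to NRH within a mode. Driving dominance over bicycling is *not*
guaranteed cell-wise (off-road driving can be slower than bicycling on
bare and built-up surfaces), but holds on generated scenes because the
road network dominates long-range movement; it is checked empirically.

# Hotspot detection

Zonal travel time is the unweighted mean of finite cell minutes per parish
(the analysis aggregates the access raster by zone with no population
weighting); zones with no finite cells are excluded from inference with a
warning.

The Gi* statistic includes the self term ($w_{ii}=1$) under binary
weights:

$$z_i = \frac{\sum_j w_{ij} x_j - \bar x W_i}
{S\sqrt{\left(n W_i - W_i^2\right)/(n-1)}},$$

with $W_i$ the count of weighted zones (neighbors + self), $\bar x$ the
global mean and $S$ the global population standard deviation. If a zone's
neighborhood spans every zone the denominator vanishes and the statistic
is undefined; such zones get `NA` (this arises only on very small
lattices at high orders).

Queen contiguity at order $k$ is cumulative: all zones reachable within
$k$ adjacency steps, excluding self — matching the "critical distance"
framing of multi-order analyses. An exclusive-order variant is available
but non-default. For raster-derived zones, order-1 queen adjacency is
8-adjacency of any pair of member cells.

Significance uses conditional permutation: zone $i$'s value is held fixed
and the remaining values are reassigned at random among the other zones;
$p_i = (1 + \#\{|z^{perm}| \ge |z^{obs}|\})/(1 + n_{perm})$. Because a
conditional permutation preserves the value multiset, the global mean and
SD — hence the Gi* denominator — are unchanged, so the permutation engine
(compiled code driven by R's RNG) only needs neighbor sums. The default
`n_perm = 9999` is the smallest round count at which $p \le 0.001$ is
resolvable with headroom; 999 would bottom out at exactly 0.001. An
analytic-normal p-value is deliberately not the default: zonal travel
times are strongly skewed.

The multi-order rule labels a zone at order $k$ only when $p \le \alpha$
at $k$ *and* $|z(k)| > |z(j)|$ for every $j < k$; the reported order is
the highest at which this holds. The magnitude comparison (rather than a
signed one) makes the rule symmetric for cold spots, which a signed
reading would make undetectable at higher orders. High labels (long travel
times) are *low-access* clusters.

# Covariate modeling

`sample_points()` draws uniform points in the study area and extracts 15
layers: density (persons/km²), poverty, subregion, walking minutes to all
six levels, and minutes-saved-by-bicycling to all six levels (walk − bike,
derived at extraction). Points on missing or unreachable cells are
resampled and counted. The default 5000 points split 85/15 into 4250
training and 750 test samples, deterministically per seed.

Collinearity is screened by iterative VIF removal at the conventional
threshold of 10 ($\mathrm{VIF}_j = 1/(1-R_j^2)$).

The forest learner is a 500-tree random forest (`ranger`) with predictors
density, poverty and subregion (nominal, unordered partition splits);
`mtry` is tuned over {1, 2, 3} by out-of-bag MAE. Variable importance is
permutation importance — the increase in out-of-bag MSE when a predictor's
column is permuted — averaged over `n_iter` (default 20) independent
permutations, which demonstrably reduces the score variance. Partial
dependence marginalizes the remaining predictors over a training
subsample, on a grid trimmed to the boxplot fences
$[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ of the training
values so outliers do not stretch the curve.

For the mixed models, poverty and density are first transformed by
Tukey's ladder of powers: $\lambda$ is selected on a grid from −2 to 2 in
steps of 0.025 to maximize the Shapiro–Wilk $W$ of the transformed values
(computed on an evenly spaced order-statistic subsample capped at 5000,
the test's maximum); the transform is $x^\lambda$ ($\lambda>0$),
$\log x$ ($\lambda=0$) or $-x^\lambda$ ($\lambda<0$), all monotone
increasing so coefficient signs are interpretable; non-positive inputs
are shifted up first (logged via a message); outputs are centered. Five
candidate fixed-effect sets are enumerated — null, poverty, density,
poverty + density, and poverty + density + interaction — each with a
subregion random intercept; the interaction (product of the transformed,
centered mains) never enters without both mains. A null model is fit
first so the grouping variable's ICC
($\tau_{00}/(\tau_{00}+\sigma^2)$) is always reported. Models are fit by
maximum likelihood (not REML) so BICs are comparable across fixed-effect
sets; singular non-null candidates are dropped with a warning. Test-set
accuracy uses MAE, RMSE and *predictive* $R^2 = 1 - SS_{res}/SS_{tot}$
(which can be negative), the same metrics for both families, and
`compare_models()` reports forest-minus-mixed deltas per (level,
scenario) pair.

# The synthetic landscape generator

The generator's defaults define the study conditions:

* **Population** is a mixture of 12 Gaussian clusters with log-normal
  weights and multiplicative log-normal cell noise, scaled to a total of
  10⁶ people — clustered, heavy-tailed settlement on a 100 × 100 km grid
  at 1 km resolution (the default experimental geometry).
* **Poverty** is `plogis(−b·z + noise)`, with `z` the standardized
  Gaussian-smoothed log density and a smooth noise field of matched scale;
  `b` is calibrated by root-finding so the realized Pearson correlation
  between poverty and `log(1 + density)` hits the target (default −0.5) —
  the rural-poor structure the analysis assumes. No quantitative spatial
  covariance for the poverty surface is available to emulate, so the
  coupling strength is a free parameter, not an estimate.
* **Facilities** per tier default to counts (40, 20, 8, 4, 2, 1),
  decreasing with level. Siting weights are `catchment^γ · (1 −
  poverty)^wealth_bias`, where *catchment* is the smoothed population
  field (facilities serve areas, not single cells), γ rises with tier
  (0.6 → 3.2: referral hospitals are far more urban-biased than village
  clinics), and `facility_wealth_bias` (default 2) encodes the
  urban/wealth bias of placement. The wealth bias is what makes the
  poverty→access coupling *structural*: poorer areas get fewer nearby
  facilities even at equal catchment population, so recovery tests of the
  poverty effect are meaningful and sign-stable across seeds. Setting it
  to 0 yields scenes where density alone is the generated driver — the
  configuration used to check that density then ranks first in
  importance. Tiers are distinct point sets; eligibility unioning happens
  in the travel-time stage.
* **Roads**: a minimum spanning tree over cluster centers (primary),
  towns connected to their nearest cluster center (secondary), and local
  fill segments toward the network (tertiary).
* **Barriers**: rectangles placed preferentially in sparsely populated
  country until ~5% of the area is covered.
* **Admin zones**: 150 parishes as a Voronoi tessellation of random
  seeds, nested exactly into 8 subregions by nearest-subregion-seed
  assignment.

One integer seed controls all randomness through an RNG-state-preserving
wrapper; no global state leaks.

What the scenes do *not* emulate: real geography and terrain, seasonal or
wet-road friction, network-only (vector) routing, transit wait times, and
any particular country's facility inventory. Passing tests therefore
demonstrate that the *methods* behave correctly under known structure —
not that any real country's coverage numbers are reproduced.

# Numerical choices and degenerate inputs

* Shortest-path equality against oracles is asserted at 1e−9 (the solver
  is exact; tolerance covers float associativity).
* Facility snapping ties break deterministically (row-major).
* Gi* with all-equal values errors (zero variance); whole-study
  neighborhoods give `NA`.
* Zero-population coverage denominators error rather than return NaN.
* Travel-time rasters store minutes as doubles; `+Inf` is the in-memory
  unreachable sentinel and a declared NODATA value on disk.
* Problem sizes in the shipped tests and acceptance script — 100 × 100
  cells, 5000 points, 9999 permutations, 200 calibration replicates —
  were chosen as the smallest sizes at which every property is
  comfortably resolvable; all are parameters, not limits.

# Known limitations

* Zones, barriers and masks are raster-native; true vector polygon
  topology (shared borders thinner than a cell) is approximated at cell
  resolution.
* The forest learner is a random forest with permutation importance, not
  a conditional-inference forest; importance of highly correlated
  predictors can be shared rather than attributed conditionally.
* The permutation p-value floor is $1/(1+n_{perm})$; claims below it
  require more permutations.
* Driving-versus-bicycling coverage dominance is an empirical property of
  road-bearing scenes, not a theorem of the speed table.
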