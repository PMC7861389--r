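---
title: "Methods: behavioral states, co-occurrence and rule mining in trackmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral states, co-occurrence and rule mining in trackmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmine)
```

`trackmine` analyzes GPS-collar relocation tables in three stages —
individual behavioral states, pairwise spatiotemporal interaction, and
behavior-by-environment association — and ships a movement simulator that
provides ground truth for all of them. This vignette records the models,
the tunable parameters, the numerical conventions, and the design choices
made where the design was genuinely open.

## Relocation data model

A *fix* is one row `(animal_id, timestamp, lat, lon)` in WGS84 decimal
degrees. All timestamps are interpreted in a single configured time zone
(UTC by default); collar exports rarely state their zone, so the zone is an
explicit input rather than a guess. Rows that fail to parse or fall outside
coordinate ranges are counted and reported, never silently dropped;
duplicated `(animal, timestamp)` rows keep their first occurrence. Monthly
summaries use half-open calendar intervals: an instant exactly at a month
boundary belongs to the month whose date it carries.

## Geodesic distances

Between-animal distances use the iterative Vincenty inverse solution on
the WGS84 ellipsoid (a = 6378137 m, f = 1/298.257223563), converged to
1e-12 rad. Vincenty's iteration famously fails to converge for
near-antipodal pairs; these are irrelevant at telemetry scales, so the
implementation falls back to the spherical great-circle distance there,
warns, and flags the affected indices. Arguments are put in a canonical
order before iterating, which makes `d(a, b)` and `d(b, a)` identical to
the last bit. The test suite checks agreement with an independent
high-precision geodesic implementation to under a millimeter on random
pairs up to 1000 km.

## Behavioral states from residence values

Around each trajectory point a circle of radius `r` is constructed. The
*residence distance* RD is the summed length of all path segments inside
the circle, clipped exactly at the circle boundary (the clipping fractions
come from the quadratic segment–circle intersection; time is interpolated
linearly with distance along a segment, i.e. constant speed per segment).
The *residence time* RT is the summed time of those clipped portions. Both
are normalized by their per-track maxima and the residual
`RD* − RT*` ∈ [−1, 1] drives a three-way rule: rest below `−ε`, forage
above `+ε`, transit inside the band.

Geometry is computed in a local equirectangular projection about the
track centroid; for tracks under ~50 km the projection error is orders of
magnitude below any sensible circle radius. The direction of the residual
is fixed so that a point where the animal spends long time but covers
little path (rest) is negative.

Two parameters matter:

* **Circle radius `r`** (meters). Default: the track's median step length,
  which adapts the residence scale to the sampling regime and is
  reproducible without tuning. Any fixed biological scale can be passed
  instead; the analyses in the test suite use `r = 200` m, matching the
  proximity scale of the interaction stage.
* **Transit tolerance `ε`** (unitless, default 0.05). An exact
  zero-residual rule classifies transit on a measure-zero set, so a
  symmetric band around zero is required for real data. The band width
  should reflect how strongly the regimes are separated: a fix passed
  through in transit still accrues RD ≈ 2r inside its own circle, so its
  normalized residual sits near `2r / max(RD)` rather than at zero, and ε
  must sit above that floor but below the smallest foraging residual. For
  the simulator's default regimes this floor is ≈ 0.1 and foraging
  residuals exceed ≈ 0.2, so the recovery analyses use `ε = 0.15`.

A *bout* is a maximal run of equal consecutive states. Its duration is
closed on the nominal sampling interval (`last − first + interval`), so a
single-fix bout lasts one sampling step and per-state durations add up to
the track span plus one interval; the same convention feeds the mean
durations and the day/night tabulations. The day window is 06:00–18:00
local by default; a bout is "day" if it starts and ends inside the window,
"night" if both endpoints are outside (including bouts that span an entire
night), "day/night" if it crosses the boundary. Hour-by-day state matrices
take the modal state per hour cell, ties resolved to the first observed
state — deterministic and order-stable.

The residual rule here follows the direct normalized-difference
formulation; the residence-time literature also contains a variant that
takes residuals from a fitted RD–RT relationship. The direct rule is what
this package implements; the divergence is deliberate and documented.

## Co-occurrence events and transactions

For every unordered animal pair, fix pairs with `|Δt| ≤ time_window`
(default 3600 s — one hourly fix) and Vincenty distance strictly below the
radius are candidate events; the strict `<` makes the radius an exclusive
limit. Candidates are deduplicated to at most one event per pair per
deduplication interval (default: the time window), keeping the minimum
distance, so a prolonged encounter is reported once per interval instead
of once per fix pair. Two radius presets, 200 m (a separation consistent
with direct sociability) and 400 m (the doubled sensitivity scale), cover
the standard analyses; event counts are monotone non-decreasing in the
radius.

The transaction unit for mining is **one transaction per co-occurrence
event**, whose items are the two animal ids, grouped by calendar month;
the monthly transaction count `D` is therefore the monthly event count.
This is the construction under which marginal supports are the fraction
of a month's events involving an animal, and it reproduces the worked
February example exactly (8 events split 3/3/2 over three pairs gives the
shared animal SupA = 5/8 = 0.625). For the environment stage the
transaction is one classified fix with items `{state, land-cover class}`,
one set per animal, with off-grid fixes dropped and counted.

## Rule mining and interestingness measures

Apriori is implemented from scratch: level-wise candidate generation with
the downward-closure prune, exact rational supports `count / D`. Rules are
restricted to single antecedent and consequent (the reported tables are
pairs); higher-order frequent itemsets are still enumerated. Measures:

* `Sup = n(A∩B)/D`, `Conf = Sup/SupA`, `Lift = Conf/SupB`. Lift is a
  ratio: above 1 the animals co-occur more than independence predicts,
  below 1 less, exactly 1 at independence (`Sup = SupA·SupB`).
* `Phi = (Sup − SupA·SupB) / sqrt(SupA·SupB·(1−SupA)(1−SupB))` — the 2×2
  correlation between the two presence indicators. Phi is **undefined**
  (NA) exactly when the denominator vanishes, i.e. when a marginal support
  is 0 or 1: an item present in every transaction has a constant
  indicator, and no correlation is measurable. This is why single-pair
  months show `Conf = 100%` with `Phi = NA` and `Lift = 1` — the measures
  saturate, and the contingency/home-range validation layers matter.
* Phi bands: exact ±1 "perfect"; `|phi| ≥ 0.68` strong; `0.36 ≤ |phi| <
  0.68` moderate; `|phi| < 0.36` weak or none. The band edges are
  half-open toward the stronger class (0.67 is moderate, 0.68 strong) and
  exact ±1 takes the perfect label with precedence.

Cramér's V validates the rule correlations on the monthly animal-pair
contingency table: `V = sqrt(chi² / (n (min(r,c) − 1)))` with the Pearson
chi-square (no continuity correction). Tables with fewer than two distinct
rows or columns — a single observed pair — are flagged degenerate and V is
NA with a warning rather than a number.

Mining thresholds default to `minSup = 0.01`, `minConf = 0.5`; the grid
`{0.01, 0.5, 0.9}` spans the usual sensitivity analysis. Rule tables print
at the conventional display precision (3 decimals, truncated) in the
acceptance outputs.

## Kernel home ranges

The utilization distribution is the average of circular bivariate normal
kernels (sd = bandwidth `h`) centered on the fixes, evaluated on a regular
grid in the local metric projection and renormalized to integrate to one.
Defaults: the ad-hoc reference bandwidth `h = σ n^(−1/6)` (σ = mean of the
coordinate standard deviations), a 100×100 grid with a 4h margin beyond
the fix extent. The p-isopleth is the smallest set of highest-density
cells reaching mass p (ties broken in row-major order); p = 0.95 is the
home range, p = 0.50 the core area. For an exact Gaussian UD the 95%
isopleth area equals `π χ²₂(0.95) h²`, which the tests verify to 5% on the
default grid. Overlap between two UDs on a shared grid is either the
directional isopleth area overlap (HR: fraction of A's isopleth inside
B's, and vice versa) or the symmetric volume intersection
`Σ min(UD_A, UD_B)·cell_area` (VI). UDs on different grids are bilinearly
resampled onto a union grid first; bilinear resampling conserves mass to
about 1e-3 without renormalization, which the tests check directly.

## Land cover

Categorical rasters are consumed as ESRI ASCII grids in geographic
coordinates with a code→name legend; codes without a legend entry resolve
to `"unknown"` with a warning. Point lookup is half-open point-in-cell:
each cell owns its west and north edges, so shared edges belong to exactly
one cell and the lookup is total over the extent; off-grid points and
nodata cells return NA and are counted when building transactions. Land
cover is sampled at the fix point (no buffer averaging).

## The synthetic generator

The simulator emulates the study conditions the package is designed for:
hourly fixes, three regimes with distinct step/dwell structure, pairwise
attraction, and a categorical landscape.

* **rest** — steps 10 ± 5 m with uncorrelated headings, bouts of mean 50
  fixes: a stationary cluster a few tens of meters across.
* **forage** — steps 100 ± 20 m with a persistent ~80° turn per step
  (direction drawn per bout): the path orbits within ~80 m of a center,
  accumulating path length in a confined area, bouts of mean 20 fixes.
* **transit** — steps 1500 ± 300 m aimed within a few degrees of a
  per-track azimuth, bouts of mean 4 fixes: fast directed legs that carry
  the animal to a new activity site without re-crossing old ones.

State switching is semi-Markov: dwells are `1 + Poisson(mean − 1)` and the
next state comes from the transition-matrix row with the self-transition
removed (a one-hot diagonal row is absorbing). The matrix-plus-dwell
parameterization keeps bout lengths concentrated near their means — a
plain per-step Markov chain yields geometric dwells whose mass at 1–2 fix
bouts is not a "well-separated regimes" condition. Steps between fixes of
different states are drawn from the faster of the two regimes: a regime
change is a relocation, so activity sites stay separated from travel legs
(without this, each new rest cluster would form on top of the last transit
fix and the boundary fixes would be unclassifiable by any rule). Pair
simulation places animal B within half the encounter radius of A during
scripted, evenly spaced encounter windows, guaranteeing recoverable
co-occurrences; with no windows the tracks start 50 km apart and stay
separated. Landscapes are nearest-center Voronoi mosaics of seeded random
centers. Everything is deterministic given the mandatory seed.

What the generator does **not** emulate: GPS position error, missed fixes
and irregular schedules, habitat-dependent movement, attraction that
emerges from behavior rather than a script, and home-range fidelity
(transit is directional, so long simulated tracks range rather than
revisit). Passing tests therefore demonstrate that the estimators recover
a known, cleanly separated structure — not that real collar data are this
clean.

## Problem sizes and verification

The test suite checks state recovery on ten independent 2000-fix tracks
(accuracy ≥ 70% of true labels and per-state mean bout durations within
25% of generator truth; the realized margins are far inside both), event
detection against a quadratic all-pairs oracle at both radius presets,
Apriori against exhaustive powerset enumeration on 200 random transaction
sets of up to 12 items and 64 transactions, geodesics against an
independent high-precision oracle on 1000 random pairs, and the kernel
estimator against closed-form Gaussian results. Oracles are deliberately
naive re-derivations kept separate from the implementation.

## Known limitations

* The residual rule is the direct normalized difference; it is sensitive
  to the per-track maxima (a single extreme foraging excursion rescales
  every residual in the track).
* The transit band floor `2r / max(RD)` means transit cannot be separated
  at all when foraging path accumulation is comparable to one circle
  diameter; choose the radius below the scale of area-restricted search.
* No projected-CRS support: inputs are WGS84 geographic, internal meters
  come from local equirectangular projections, suitable below ~50 km
  extents.
* Near-antipodal distances use the spherical fallback (flagged), which is
  never exercised by telemetry-scale data.
* Rasters are point-sampled; no buffer or area-weighted cover extraction.
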