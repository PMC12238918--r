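---
title: "Methods: from catchment greening to lake oligotrophication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from catchment greening to lake oligotrophication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenlakes)
```

## The model

The package operationalizes a simple causal chain for high-latitude clear
lakes: terrestrial vegetation in a lake's drainage area binds phosphorus and
nitrogen as it expands; peak-season greenness (NDVI~max~) proxies that
above-ground biomass; a linear plot-scale calibration converts greenness to
areal nutrient density; and the resulting increase in terrestrial
sequestration is mirrored by declining nutrient concentrations in the
downstream lake. Each link is a separate module with its own contract, so
any link can be replaced or audited in isolation.

Assumptions worth keeping in mind:

* NDVI~max~ is a linear proxy for above-ground nutrient stock over the
  observed range (roughly 0.25–0.75). NDVI saturates above ~0.7, so dense
  forest is underestimated; the calibration is fitted on tundra plots and
  extrapolated to whole drainage areas.
* Only above-ground, green biomass is counted. Below-ground stocks (root:
  shoot ratios of 2.7–8.2 for tundra plant types) are excluded, making all
  sequestration estimates conservative.
* The chemistry link is treated as monotone; the mixed smooth makes no
  functional-form claim beyond smoothness.

## Watershed delineation

Depression filling uses an epsilon-free priority flood: valid edge cells
(and cells bordering nodata holes) seed a min-heap keyed by elevation with
a FIFO tie-break; popping cells in that order yields, for every cell, the
lowest spill level connecting it to the edge. Elevations are never
perturbed beyond the minimal raise, so spill surfaces are genuinely flat.
Flats are made drainable by the *dequeue order*: a flat cell flows to the
equal-elevation neighbor processed earliest, which is a breadth-first
distance-to-outlet ordering. One visible consequence: on a flat grid edge
the flow runs along the edge to a single code-0 outlet cell rather than
exiting everywhere; this is deterministic, acyclic and conserves
accumulation, which is what the downstream operations need.

D8 codes use the fixed neighbor order E, SE, S, SW, W, NW, N, NE (codes
1–8, 0 = sink/outlet), steepest descent measured as drop over
center-to-center distance (diagonals `cell_size * sqrt(2)`), ties broken by
the first neighbor in that order. Accumulation is computed in topological
order and errors loudly (naming a cell) on cycles, which cannot arise from
our own filling but can from user-supplied flow fields. Outlet snapping
maximizes accumulation within a radius (default 250 m — a configuration
choice, not a published value), tie-breaking by distance then scan order.

Every one of these operations is tested against brute-force oracles
(relaxation filling, per-cell path following) on random grids; the
delineation oracle comparison runs on 200 random DEMs in the acceptance
suite.

## NDVI extraction

The two aggregation orders are deliberately different and order matters
(mean-then-max ≤ max-then-mean, which the tests verify by brute force):

* **Drainage scale**: discard scenes acquired before 07:00 local time,
  take each pixel's annual maximum, drop pixels whose maximum is ≤ 0.2,
  and average the rest. The `> 0.2` screen is the operative snow/bare-rock
  filter; an optional `low_pixels_as_zero` flag instead counts failing
  pixels as zero, and the hour threshold is a parameter. Whether the
  original analysis used mean-of-pixel-maxima or max-of-scene-means is not
  fully determined; we implement the literal mean-of-maxima reading here.
* **Plot scale**: average the 4–8 pixels covering a plot per scene, then
  take the maximum over scenes. No hour filter by default (plot-scale
  imagery is mid-morning).

A year with no qualifying pixel yields a missing value, not an error.

## Calibration

Areal density uses the unit identity 1 g m⁻² = 1 ton km⁻²:
`density = (dry_mass / plot_area) * conc / 1000` with `plot_area` 0.25 m².
QC first: a snow-covered or incompletely harvested plot invalidates its
*site* (the site mean of three plots is no longer defined), so `qc_filter()`
drops whole sites — with 38 sites and 5 + 4 flagged plots on distinct
sites, 29 usable sites remain. This site-level reading is the only one
consistent with the published site counts, and is the package's chosen
semantics. Regression is OLS of density on NDVI~max~ at site level
(plot level available via a flag); constant NDVI designs and n < 3 are
explicit failures. Negative predicted densities are clamped to zero with a
logged count; on the synthetic default NDVI range the clamp never fires
(tested).

## Sequestration and upscaling

Annual stocks are `density × drainage_km2`; the 3-y centered moving
average is presentation-only — period statistics always use raw annual
values. Period contrasts use Welch's unequal-variance *t*-test (the
published analysis says only "Student t-tests"; Welch is the safer default)
over configurable per-lake periods (one lake's early window ends in 1992
because its greening started early; overrides are plain arguments, so they
cannot leak across lakes). Cross-lake summaries are unweighted means with
SE = SD/√n — the convention that reproduces the published ±0.10.

Upscaling multiplies the mean per-lake density difference by the ecoregion
area (46 528 km²) and the tundra share (33 935 km², 73%). The ground-truth
unit is tons; the published figures quote the same numerals at a
thousandth of that ("12.0 ± 1.7" against our 12 046 ± 1 709 tons), so
`upscale()` also reports a `printed_scale` field (= tons/1000) and the
discrepancy is documented rather than silently adopted. The 22.5-y
interval between period midpoints is used as printed (strict midpoint
arithmetic gives 22.0) and is configurable. One published value resisted
reproduction: the late-period P standard error prints 0.07 while SD/√9 of
the printed two-decimal means is 0.0763 (→ 0.08); the acceptance test
holds that single value to one unit in the last printed digit.

## Trend statistics

Mann–Kendall uses `S = Σ_{i<j} sign(x_j − x_i)`, tie-corrected variance
`[n(n−1)(2n+5) − Σ_t t(t−1)(2t+5)]/18`, the continuity-corrected normal
deviate, and tau-b. An exact permutation p-value (n ≤ 10) is provided as an
oracle for the approximation. Sen's slope is the median of pairwise slopes
with duplicate timestamps excluded. Percent-per-year declines use the
*inclusive*-year denominator `(year_end − year_start + 1)` — the only
simple convention reproducing both published examples (3.1 and 2.5 %/y).

The additive mixed model is approximated, not delegated: a cubic B-spline
basis (k = 10 by default; k < 4 falls back to a polynomial, so k = 2 is a
straight line) with a second-difference penalty, smoothing parameter chosen
by GCV `n·RSS/(n − edf)²` on a 30-point log grid spanning 10⁻⁶–10⁸, plus
lake random intercepts `b_l = n_l·r̄_l / (n_l + σ̂²/τ̂²)` (moment estimates,
centered to sum to zero), iterated until the relative change in fitted
values is below 10⁻⁸ (error with diagnostics after 200 iterations). Because
linear functions lie in the penalty null space, a noiseless linear signal
plus offsets is fitted exactly at any λ — the basis of the noiseless-limit
tests. Equivalence with mgcv's GAMM is *not* claimed; correctness is
established through noiseless limits, null behavior, and recovery of
planted monotone structure.

## Cover estimation

The Hájek ratio form `Σ(c_i/π_i)/Σ(1/π_i)` is the default because the
target is a mean cover fraction; the pure Horvitz–Thompson total is
available via `type = "total"`. With equal inclusion probabilities the
ratio reduces exactly to the arithmetic mean. The 5-y moving average is
centered (alignment is unstated in the source; centered is the symmetric
choice), shrinks at the edges and skips missing years, recording how many
years entered each window. Design-unbiasedness is checked by simulation
under Poisson sampling (2000 replicates), allowing for the estimator's
O(1/n) ratio bias.

## The synthetic world

The generator emulates the statistical structure of the real inputs, not
their physics. Stated world (all in `synth_config()`, chosen once):

| Parameter | Default | Why |
|---|---|---|
| years | 1983–2020 | length of the NDVI record |
| scenes/year | 12 | monthly compositing cadence |
| greening ramp | logistic, center 1995, width 3 y | a 1990s surge plateauing after ~2001; the source gives no functional form, the logistic is the simplest saturating one |
| ramp amplitude | 0.10 NDVI | places period deltas in the observed 12–33% band |
| base NDVI | 0.45 ± 0.075 by elevation | tundra peak-season values below the 0.7 saturation zone |
| snow | day-of-year logistic (melt 150, onset 280) | snow scenes carry NDVI ≤ 0.2 so the `> 0.2` screen is the operative filter |
| morning scenes | 10% before 07:00 | exercises the hour filter |
| calibration truth | P: 2.2·NDVI − 0.1; N: 28·NDVI − 1 (ton/km²) | N an order of magnitude above P, as observed; noise sd 0.15 / 1.5 |
| plots | 38 sites × 3 × 0.25 m², 5 + 4 QC flags | the published survey layout |
| chemistry | log C = α_lake − γ·(NDVI−0.45)+ε; γ_P = 10, γ_N = 8, α sd 0.3, ε sd 0.15 | yields 1.5–3.6 %/y Total-P declines; log-linear is the simplest monotone form the smooth can recover |
| cover survey | 59 sites × 9 plots, 5 panels, 15%→22% over 2003–2020, π ∈ (0.4, 1] | ≈531 plots against the published 507; the published 7-point rise |

One lake (index 3 by default, toggleable) greens 15 years late, mirroring
the observed high-elevation laggard. Each product draws from its own child
RNG stream of the root seed (a deterministic hash of the stream name), so
adding a product never perturbs the others; identical configurations give
byte-identical bundles, and generation neither reads nor disturbs the
ambient RNG state.

What the generator does **not** emulate: sensor radiometry, clouds,
cross-sensor harmonization, geodetic coordinates, within-lake chemistry
seasonality, or spatially correlated NDVI noise. A green end-to-end test
therefore establishes that the pipeline recovers planted structure of the
assumed form — not that the form is right for any particular real
landscape.

Terrain note: lake depressions are carved as paraboloid bowls clamped below
the minimum elevation of their rim. A naive Gaussian pit superposed on
slope and hills can fail to produce any closed depression (the gradient
washes it out); the clamped bowl guarantees one, and the lake mask is then
the flooded component grown from the deepest water cell near the carved
center.

## Numerical choices and degenerate inputs

* Filling is epsilon-free; flats are resolved by ordering, never by
  perturbing elevations. Filling is idempotent (tested).
* All tie-breaks are documented constants: D8 neighbor order for descent
  ties, fill order for flats, distance-then-scan-order for snapping.
* All-tied Mann-Kendall series give S = 0, p = 1 (not an error); Welch's
  test on zero-variance periods returns p = NA rather than failing the
  contrast.
* Missing years propagate as missing records everywhere (NDVI extraction,
  sequestration, moving averages) with counts recorded.
* Moving averages shrink at the series edges instead of dropping years.

## Known limitations

* Pure-R watershed code targets the grid sizes used here (≤ ~10⁴–10⁵
  cells); it is not a replacement for compiled hydrology tools on national
  DEMs.
* The mixed smooth supports one smooth term plus random intercepts only —
  exactly what the analysis needs, nothing more.
* ESRI ASCII is the only raster format (no GeoTIFF reader is available in
  the offline dependency set), and coordinates are planar meters without a
  CRS.
* The calibration is strictly linear; saturating NDVI–biomass forms are out
  of scope.

## Reproducing the published chain

```{r chain}
tbl <- lake_sequestration_table()
summarize_lakes(data.frame(mean_a = tbl$p_mean_a, mean_b = tbl$p_mean_b))
upscale(tbl$p_mean_b - tbl$p_mean_a)
percent_decline(5.3, 1.2, 1996, 2020)
```

Every number shown by this vignette or the README is computed by the code
at run time; the acceptance suite (`tests/testthat/test-acceptance.R`)
asserts the full chain at printed precision.
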