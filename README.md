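# greenlakes

Subarctic and Arctic/alpine lakes in Scandinavia are becoming markedly more
nutrient-poor while their catchments green up. `greenlakes` implements the
full analysis chain that links the two processes, for freshwater ecologists
and biogeochemists working with long-term monitoring data:

1. **Watershed delineation** from an elevation raster: epsilon-free
   priority-flood depression filling, D8 steepest-descent flow routing
   (neighbor order E, SE, S, SW, W, NW, N, NE), flow accumulation, pour-point
   snapping, and upstream basin traversal. Drainage area = catchment − lake
   surface.
2. **Annual maximum NDVI** (NDVI<sub>max</sub>, the annual peak of
   (NIR − red)/(NIR + red), a proxy for peak green biomass): per drainage
   pixel the annual maximum over scenes acquired at or after 07:00, keeping
   pixels whose maximum exceeds 0.2 (the snow/bare-rock screen), then the
   spatial mean; per vegetation plot, the mean over covering pixels first and
   the maximum over scenes second.
3. **Calibration**: ordinary least squares of areal nutrient density
   *d* = (dry mass / 0.25 m²) · conc / 1000 (ton km⁻² ≡ g m⁻²) on plot
   NDVI<sub>max</sub> at site level, after QC removal of snow-covered and
   incompletely harvested plots.
4. **Sequestration**: per-lake annual density
   *d(t)* = max(0, a + b · NDVI<sub>max</sub>(t)) and stock
   *d(t)* · A<sub>drainage</sub>; period contrasts (Welch *t*,
   Δ% = 100 (m₂ − m₁)/m₁); cross-lake mean ± SE; regional upscaling
   (mean difference × 46 528 km² ecoregion, × 33 935 km² tundra share,
   ÷ 22.5 y for annual rates).
5. **Trend statistics**: Mann–Kendall *S* with tie-corrected variance and
   continuity correction, Sen's slope (median of pairwise slopes),
   percent-per-year declines with the inclusive-year denominator, and a
   Gaussian additive mixed model approximated by a backfitted penalized
   cubic spline (GCV-selected smoothing) with lake-level random intercepts.
6. **Cover estimation**: Horvitz–Thompson (Hájek ratio) estimator
   Σ(cᵢ/πᵢ)/Σ(1/πᵢ) for rotating-panel unequal-probability surveys, with a
   5-y centered moving average.
7. **Synthetic worlds** (`synth_config()` / `generate_bundle()`): seeded
   landscapes with carved lake depressions, a logistic greening ramp
   (center 1995, width 3 y) that plateaus after ~2001, a linear plot
   calibration truth, log-linear chemistry declines with lake random
   intercepts, and a 15% → 22% cover trend — so the entire pipeline is
   testable offline.

## Worked example

Reproducing the regional phosphorus upscaling from the packaged per-lake
period table (`lake_sequestration_table()`):

```r
library(greenlakes)
tbl <- lake_sequestration_table()
upscale(tbl$p_mean_b - tbl$p_mean_a)
#> <upscale_result> P: mean diff 0.259 +/- 0.037 ton/km^2 over 9 lakes
#>   region (46528 km^2): 12046 +/- 1709 tons (printed scale 12.0 +/- 1.7)
#>   tundra (33935 km^2): 8785 tons; annual rate 390 tons/y over 22.5 y
```

The mean per-area increase of 0.26 ton P km⁻² between the early
(1983–1994) and late (2001–2020) periods scales to ≈12,000 t P across the
ecoregion, of which ≈8,800 t fall on tundra vegetation — about 390 t P
sequestered per year.

An end-to-end synthetic run (delineation → NDVI → calibration →
sequestration → chemistry trends):

```r
cfg <- synth_config(seed = 42, grid_nrows = 48, grid_ncols = 48, n_lakes = 3)
bundle <- generate_bundle(cfg)
fit <- fit_calibration(qc_filter(bundle$veg_plots), "P")
fit
#> <calibration_fit> P density = -0.09059 + 2.194 * NDVI_max (ton/km^2)
#>   n = 29 sites, r^2 = 0.955, p = 1.05e-19, residual sd = 0.0802

lk <- bundle$lakes[[1]]
ser <- subset(bundle$annual_ndvimax, unit == lk$id, c(year, value))
rec <- annual_sequestration(ser, fit, lk$drainage_km2, lk$id)
period_contrast(rec, 1983:1994, 2001:2020)
#> <period_stats> lake_01 P: 1983-1994 0.86 +/- 0.06 -> 2001-2020 1.02 +/- 0.07 (+19%, p = 8.65e-08)

am <- annual_mean(bundle$chem, "total_p")
d <- subset(am, lake_id == lk$id)
mann_kendall(d$value, d$year)
#> <trend_result> n = 38, S = -403, z = -5.054, p = 4.329e-07, tau = -0.573, Sen slope = -0.09397
```

The planted calibration slope (2.2) is recovered within noise, the lake's
P sequestration rises 19% between periods, and its Total-P declines
significantly — the planted greening → oligotrophication link.

## Command line

`Rscript -e 'greenlakes::greenlakes_cli()' <subcommand> [--options]` with
subcommands `synth`, `delineate`, `ndvi`, `calibrate`, `sequester`,
`trends`, `coverage`; see `?greenlakes_cli`.
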