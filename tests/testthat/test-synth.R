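small_cfg <- function(seed = 5, ...) {
  synth_config(seed = seed, grid_nrows = 32, grid_ncols = 32, n_lakes = 2,
               years = 1990:1999, scenes_per_year = 6, ...)
}

test_that("identical configurations give identical bundles", {
  b1 <- generate_bundle(small_cfg())
  b2 <- generate_bundle(small_cfg())
  expect_identical(serialize(b1$dem, NULL), serialize(b2$dem, NULL))
  expect_identical(b1$annual_ndvimax, b2$annual_ndvimax)
  expect_identical(b1$veg_plots, b2$veg_plots)
  expect_identical(b1$chem, b2$chem)
  expect_identical(b1$cover_survey, b2$cover_survey)
  # generation does not depend on the ambient RNG state
  set.seed(123)
  d1 <- generate_dem(small_cfg())
  set.seed(456)
  d2 <- generate_dem(small_cfg())
  expect_identical(d1$values, d2$values)
})

test_that("zero hill amplitude and no lakes give a strictly monotone plane", {
  cfg <- synth_config(seed = 2, grid_nrows = 16, grid_ncols = 16,
                      n_lakes = 0,
                      terrain = list(slope_drop = 30, hill_amplitude = 0,
                                     n_hills = 0, pit_depth = 15,
                                     pit_radius_cells = 3))
  dem <- generate_dem(cfg)
  expect_true(all(diff(t(dem$values)) < 0))  # strictly decreasing eastward
  expect_false(any(is_nodata(dem)))
})

test_that("generated DEMs drain after filling: every cell reaches the edge", {
  dem <- generate_dem(small_cfg(seed = 9))
  flow <- compute_d8(fill_depressions(dem))
  nr <- nrow(flow$codes)
  for (cell in sample(nr * ncol(flow$codes), 40)) {
    p <- oracle_path(flow$codes, ((cell - 1) %% nr) + 1,
                     ((cell - 1) %/% nr) + 1)
    expect_false(is.null(p))
  }
})

test_that("impossible lake placement fails loudly", {
  expect_error(
    generate_dem(synth_config(seed = 1, grid_nrows = 10, grid_ncols = 10,
                              n_lakes = 9)),
    "lakes")
})

test_that("scene stacks respect bounds, snow, water and morning fractions", {
  cfg <- small_cfg(seed = 6)
  dem <- generate_dem(cfg)
  lakes <- generate_lakes(cfg, dem)
  scenes <- generate_scenes(cfg, dem, lakes)
  expect_length(scenes, 10 * 6)
  vals <- unlist(lapply(scenes, function(s) s$grid$values))
  expect_true(all(vals >= -1 & vals <= 1))
  # lake pixels carry water-like negative NDVI
  lk <- lakes[[1]]$lake_mask$values > 0
  expect_true(all(scenes[[30]]$grid$values[lk] < 0))
  # winter scenes sit below the 0.2 screen on land
  doys <- vapply(scenes, function(s) s$doy, integer(1))
  winter <- scenes[doys < 100]
  expect_true(all(vapply(winter, function(s) {
    max(s$grid$values[!lk]) <= 0.2
  }, logical(1))))
  hours <- vapply(scenes, function(s) s$hour, numeric(1))
  expect_gt(mean(hours < 7), 0)
  expect_lt(mean(hours < 7), 0.35)
})

test_that("zero greening amplitude leaves annual NDVI_max trendless", {
  cfg <- synth_config(seed = 8, grid_nrows = 24, grid_ncols = 24,
                      n_lakes = 1, years = 1983:2012, scenes_per_year = 8,
                      greening = list(ramp_center_year = 1995,
                                      ramp_width_years = 3, amplitude = 0))
  dem <- generate_dem(cfg)
  lakes <- generate_lakes(cfg, dem)
  scenes <- generate_scenes(cfg, dem, lakes)
  drain <- lakes[[1]]$lake_mask
  drain$values <- 1 - drain$values  # whole grid minus lake
  ser <- annual_ndvimax_series(scenes, drain)
  tr <- mann_kendall(ser$value, ser$year)
  expect_gt(tr$p_two_sided, 0.05)
  expect_lt(abs(tr$sen_slope), 5e-4)
})

test_that("veg plots embed the planted linear truth and positive quantities", {
  cfg <- synth_config(seed = 10)
  veg <- generate_veg_plots(cfg)
  expect_equal(nrow(veg), 38 * 3)
  expect_true(all(veg$dry_mass > 0 & veg$conc_p > 0 & veg$conc_n > 0))
  # back-calculation: density recomputed from mass * conc matches
  # intercept + slope * ndvi up to the configured noise
  kept <- qc_filter(veg)
  dens <- plot_density(kept, "P")
  resid <- dens - (-0.1 + 2.2 * kept$ndvimax)
  expect_lt(abs(mean(resid)), 0.05)
  expect_lt(sd(resid), 0.25)
})

test_that("noiseless chemistry is fit perfectly by the mixed smooth", {
  cfg <- synth_config(seed = 11,
                      chem_link = list(gamma_p = 10, gamma_n = 8,
                                       ndvi_ref = 0.45, baseline_p = 5,
                                       baseline_din = 30, baseline_toc = 3,
                                       lake_intercept_sd = 0.3,
                                       noise_sd = 0))
  set.seed(50)
  ann <- data.frame(unit = rep(c("a", "b", "c"), each = 12),
                    year = rep(2001:2012, 3),
                    value = runif(36, 0.35, 0.65))
  chem <- generate_chem(cfg, ann)
  expect_true(all(chem$total_p > 0 & chem$din > 0 & chem$toc > 0))
  am <- annual_mean(chem, "total_p")
  m <- merge(am, ann, by.x = c("lake_id", "year"), by.y = c("unit", "year"))
  fit <- fit_mixed_smooth(m$value.y, log(m$value.x), m$lake_id)
  expect_gt(fit$deviance_explained, 1 - 1e-6)
})

test_that("null chemistry link keeps the Mann-Kendall level near nominal", {
  # gamma = 0 plus zero greening: annual Total-P means are i.i.d. noise
  rejections <- 0L
  n_rep <- 150
  ann <- data.frame(unit = "lake", year = 1991:2015, value = rep(0.45, 25))
  for (i in seq_len(n_rep)) {
    cfg <- synth_config(seed = 3000 + i,
                        chem_link = list(gamma_p = 0, gamma_n = 0,
                                         ndvi_ref = 0.45, baseline_p = 5,
                                         baseline_din = 30, baseline_toc = 3,
                                         lake_intercept_sd = 0.3,
                                         noise_sd = 0.15))
    chem <- generate_chem(cfg, ann)
    am <- annual_mean(chem, "total_p")
    if (mann_kendall(am$value, am$year)$p_two_sided < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_gt(rejections / n_rep, 0.005)
  expect_lt(rejections / n_rep, 0.11)
})

test_that("cover survey: panels rotate, probabilities valid, trend planted", {
  cfg <- synth_config(seed = 13)
  cs <- generate_cover_survey(cfg)
  expect_true(all(cs$inclusion_prob > 0 & cs$inclusion_prob <= 1))
  expect_true(all(cs$cover_fraction >= 0 & cs$cover_fraction <= 1))
  # one fifth of sites per year
  per_year <- tapply(cs$site_id, cs$year, function(x) length(unique(x)))
  expect_true(all(per_year %in% c(11L, 12L)))
  # each site revisited every 5 years
  yrs1 <- sort(unique(cs$year[cs$site_id == "nils_01"]))
  expect_true(all(diff(yrs1) == 5))
  # planted ~7 pp rise shows in the 5-y moving average of HT estimates
  hs <- ht_series(cs)
  rise <- 100 * (hs$ma5[nrow(hs)] - hs$ma5[1])
  expect_gt(rise, 4)
  expect_lt(rise, 10)
})
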