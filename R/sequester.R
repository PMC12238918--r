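# Per-lake nutrient sequestration series, period contrasts and regional
# upscaling. Units: areal densities in ton/km^2 (== g/m^2), totals in tons.

#' Annual sequestration series for one lake
#'
#' Converts an annual drainage NDVI_max series to areal nutrient density via
#' the calibration (negative predictions clamped to 0), multiplies by the
#' drainage area to get the total stock, and attaches a 3-year centered
#' moving average of the total (shrinking at the series edges; presentation
#' only -- period statistics use the raw annual values).
#'
#' @param ndvimax_series data.frame with columns `year` and `value`
#'   (drainage NDVI_max; `NA` values propagate as missing records).
#' @param fit A `calibration_fit` from [fit_calibration()].
#' @param drainage_km2 Drainage area (> 0).
#' @param lake_id Identifier recorded in the output.
#' @return data.frame: `lake_id`, `year`, `density` (ton/km^2), `total`
#'   (tons), `ma3` (tons).
#' @export
annual_sequestration <- function(ndvimax_series, fit, drainage_km2,
                                 lake_id = "lake") {
  stopifnot(inherits(fit, "calibration_fit"), drainage_km2 > 0)
  dens <- as.numeric(predict_density(fit, ndvimax_series$value))
  total <- dens * drainage_km2
  ma <- moving_average(total, ndvimax_series$year, window = 3)
  data.frame(lake_id = lake_id, year = ma$year,
             density = dens[order(ndvimax_series$year)],
             total = ma$value, ma3 = ma$ma)
}

#' Contrast sequestration between two periods
#'
#' Compares mean areal density (and total stock) between two inclusive year
#' ranges using the raw annual values: Welch's unequal-variance t-test on
#' densities, the absolute difference on totals, and the relative change
#' `100 * (mean_b - mean_a) / mean_a` on densities. Per-lake period
#' overrides (e.g., an earlier cutoff where greening started early) are
#' expressed by simply passing different ranges.
#'
#' @param records Output of [annual_sequestration()] for one lake.
#' @param period_a,period_b Inclusive year ranges (integer vectors; only
#'   their range is used).
#' @param nutrient Label recorded in the output.
#' @return A `period_stats` list: means/SDs per period, `delta_abs` (tons),
#'   `delta_pct`, `t_stat`, `p_value`, year counts.
#' @export
period_contrast <- function(records, period_a, period_b, nutrient = "P") {
  sel <- function(period) {
    r <- records[records$year >= min(period) & records$year <= max(period) &
                   !is.na(records$density), , drop = FALSE]
    if (nrow(r) < 2L) {
      stop("period ", min(period), "-", max(period),
           " has fewer than 2 non-missing years", call. = FALSE)
    }
    r
  }
  a <- sel(period_a); b <- sel(period_b)
  mean_a <- mean(a$density); mean_b <- mean(b$density)
  tt <- tryCatch(stats::t.test(b$density, a$density, var.equal = FALSE),
                 error = function(e) NULL)  # degenerate: zero variance
  structure(list(
    lake_id = records$lake_id[1L], nutrient = nutrient,
    period_a = range(period_a), period_b = range(period_b),
    n_a = nrow(a), n_b = nrow(b),
    mean_a = mean_a, sd_a = stats::sd(a$density),
    mean_b = mean_b, sd_b = stats::sd(b$density),
    delta_abs = mean(b$total) - mean(a$total),
    delta_pct = 100 * (mean_b - mean_a) / mean_a,
    t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value),
    class = "period_stats")
}

#' @export
print.period_stats <- function(x, ...) {
  cat(sprintf(
    "<period_stats> %s %s: %d-%d %.2f +/- %.2f -> %d-%d %.2f +/- %.2f (%+.0f%%, p = %.3g)\n",
    x$lake_id, x$nutrient, x$period_a[1], x$period_a[2], x$mean_a, x$sd_a,
    x$period_b[1], x$period_b[2], x$mean_b, x$sd_b, x$delta_pct, x$p_value))
  invisible(x)
}

#' Cross-lake period summary
#'
#' Unweighted mean of per-lake period mean densities, with uncertainty
#' expressed as the standard error across lakes (SD / sqrt(n)).
#'
#' @param per_lake Either a list of `period_stats` objects or a data.frame
#'   with columns `mean_a` and `mean_b`.
#' @return List with `n_lakes`, `mean_a`, `se_a`, `mean_b`, `se_b`.
#' @export
summarize_lakes <- function(per_lake) {
  if (is.data.frame(per_lake)) {
    ma <- per_lake$mean_a; mb <- per_lake$mean_b
  } else {
    ma <- vapply(per_lake, function(x) x$mean_a, numeric(1))
    mb <- vapply(per_lake, function(x) x$mean_b, numeric(1))
  }
  n <- length(ma)
  if (n < 2L) stop("need at least 2 lakes to summarize", call. = FALSE)
  list(n_lakes = n,
       mean_a = mean(ma), se_a = stats::sd(ma) / sqrt(n),
       mean_b = mean(mb), se_b = stats::sd(mb) / sqrt(n))
}

#' Upscale per-lake sequestration differences to the ecoregion
#'
#' The mean (+/- SE across lakes) per-area difference in sequestration
#' between two periods is multiplied by the ecoregion area and by the
#' tundra share of it. Ground truth is reported in tons; a companion
#' `printed_scale` field divides by 1000, which is the scale on which the
#' regional increase is conventionally quoted for these constants. The
#' annual rate spreads the tundra increase over the elapsed interval
#' between period midpoints.
#'
#' @param per_lake_diffs Per-lake differences in areal density
#'   (ton/km^2, >= 2 values).
#' @param region_km2 Ecoregion area (default 46528).
#' @param tundra_km2 Tundra share of the ecoregion (default 33935).
#' @param interval_years Elapsed time between period midpoints
#'   (default 22.5).
#' @param nutrient Label recorded in the output.
#' @return An `upscale_result` list: `mean_diff`, `se_diff` (ton/km^2),
#'   `total_increase`, `total_se`, `tundra_increase`, `tundra_se` (tons),
#'   `printed_scale` (those four / 1000), `annual_rate` (tons/y).
#' @export
upscale <- function(per_lake_diffs, region_km2 = 46528, tundra_km2 = 33935,
                    interval_years = 22.5, nutrient = "P") {
  stopifnot(length(per_lake_diffs) >= 2)
  if (region_km2 <= 0 || tundra_km2 <= 0 || interval_years <= 0) {
    stop("areas and interval must be positive", call. = FALSE)
  }
  n <- length(per_lake_diffs)
  m <- mean(per_lake_diffs)
  se <- stats::sd(per_lake_diffs) / sqrt(n)
  total <- m * region_km2
  tundra <- m * tundra_km2
  structure(list(
    nutrient = nutrient, n_lakes = n,
    per_lake_diffs = per_lake_diffs,
    mean_diff = m, se_diff = se,
    region_km2 = region_km2, tundra_km2 = tundra_km2,
    total_increase = total, total_se = se * region_km2,
    tundra_increase = tundra, tundra_se = se * tundra_km2,
    printed_scale = list(total_increase = total / 1000,
                         total_se = se * region_km2 / 1000,
                         tundra_increase = tundra / 1000,
                         tundra_se = se * tundra_km2 / 1000),
    interval_years = interval_years,
    annual_rate = tundra / interval_years), class = "upscale_result")
}

#' @export
print.upscale_result <- function(x, ...) {
  cat(sprintf(
    "<upscale_result> %s: mean diff %.3f +/- %.3f ton/km^2 over %d lakes\n",
    x$nutrient, x$mean_diff, x$se_diff, x$n_lakes))
  cat(sprintf("  region (%g km^2): %.0f +/- %.0f tons (printed scale %.1f +/- %.1f)\n",
              x$region_km2, x$total_increase, x$total_se,
              x$printed_scale$total_increase, x$printed_scale$total_se))
  cat(sprintf("  tundra (%g km^2): %.0f tons; annual rate %.0f tons/y over %.1f y\n",
              x$tundra_km2, x$tundra_increase, x$annual_rate,
              x$interval_years))
  invisible(x)
}
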