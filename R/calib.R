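# Plot-harvest processing and the NDVI_max -> nutrient-density calibration.
#
# Areal density works in ton/km^2, exploiting 1 g/m^2 == 1 ton/km^2:
#   density = (dry_mass [g] / plot_area [m^2]) * conc [mg/g] / 1000.

#' Construct vegetation plot samples
#'
#' @param site_id,plot_id Identifiers.
#' @param ndvimax Plot-scale annual maximum NDVI.
#' @param dry_mass Harvested above-ground dry mass (g, >= 0).
#' @param conc_p,conc_n Nutrient concentrations in dry mass (mg/g, >= 0).
#' @param plot_area Plot area in m^2 (default 0.25).
#' @param qc_snow,qc_incomplete_removal Logical QC flags.
#' @return data.frame of class `veg_plot_samples`.
#' @export
veg_plot_samples <- function(site_id, plot_id, ndvimax, dry_mass, conc_p,
                             conc_n, plot_area = 0.25, qc_snow = FALSE,
                             qc_incomplete_removal = FALSE) {
  df <- data.frame(site_id = site_id, plot_id = plot_id,
                   plot_area = plot_area, dry_mass = dry_mass,
                   conc_p = conc_p, conc_n = conc_n, ndvimax = ndvimax,
                   qc_snow = qc_snow,
                   qc_incomplete_removal = qc_incomplete_removal)
  stopifnot(all(df$dry_mass >= 0), all(df$conc_p >= 0), all(df$conc_n >= 0),
            all(df$plot_area > 0))
  class(df) <- c("veg_plot_samples", "data.frame")
  df
}

#' Areal nutrient density of a plot sample
#'
#' @param sample One row of a [veg_plot_samples()] frame (QC-clean).
#' @param nutrient `"P"` or `"N"`.
#' @return Density in ton/km^2 (== g/m^2).
#' @export
plot_density <- function(sample, nutrient = c("P", "N")) {
  nutrient <- match.arg(nutrient)
  if (any(sample$qc_snow) || any(sample$qc_incomplete_removal)) {
    stop("QC-flagged sample: apply qc_filter() before computing densities",
         call. = FALSE)
  }
  conc <- if (nutrient == "P") sample$conc_p else sample$conc_n
  (sample$dry_mass / sample$plot_area) * conc / 1000
}

#' Remove QC-flagged plots (and their sites)
#'
#' A site's density is the mean of its (by default three) plots, so losing
#' any plot to snow cover or incomplete vegetation removal invalidates the
#' whole site: all plots of an affected site are dropped. With the default
#' survey of 38 sites and 5 + 4 flagged plots on distinct sites this leaves
#' 29 usable sites.
#'
#' @param samples A [veg_plot_samples()] frame.
#' @return The filtered frame, with an attribute `qc_removed` giving counts
#'   of plots flagged by reason and sites dropped.
#' @export
qc_filter <- function(samples) {
  flagged <- samples$qc_snow | samples$qc_incomplete_removal
  bad_sites <- unique(samples$site_id[flagged])
  out <- samples[!(samples$site_id %in% bad_sites), , drop = FALSE]
  if (nrow(out) == 0L && nrow(samples) > 0L) {
    warning("all sites removed by QC filtering; empty sample set returned",
            call. = FALSE)
  }
  attr(out, "qc_removed") <- list(
    snow = sum(samples$qc_snow),
    incomplete_removal = sum(samples$qc_incomplete_removal),
    sites_dropped = length(bad_sites))
  out
}

#' Fit the NDVI_max to nutrient-density calibration
#'
#' Ordinary least squares of areal nutrient density (ton/km^2) on plot
#' NDVI_max. The default regresses site means (each site's plots averaged),
#' matching how the calibration is used downstream; `level = "plot"` uses
#' individual plots.
#'
#' @param samples QC-clean [veg_plot_samples()].
#' @param nutrient `"P"` or `"N"`.
#' @param level `"site"` (default) or `"plot"`.
#' @return A `calibration_fit` list: `nutrient`, `slope` (ton/km^2 per NDVI
#'   unit), `intercept` (ton/km^2), `n_sites`, `r2`, `p_value` (two-sided,
#'   slope), `residual_sd`.
#' @export
fit_calibration <- function(samples, nutrient = c("P", "N"),
                            level = c("site", "plot")) {
  nutrient <- match.arg(nutrient)
  level <- match.arg(level)
  if (any(samples$qc_snow) || any(samples$qc_incomplete_removal)) {
    stop("QC-flagged samples present: apply qc_filter() first", call. = FALSE)
  }
  dens <- plot_density(samples, nutrient)
  df <- data.frame(site_id = samples$site_id, ndvimax = samples$ndvimax,
                   density = dens)
  if (level == "site") {
    agg <- aggregate(df[c("ndvimax", "density")], by = df["site_id"], mean)
  } else {
    agg <- df
  }
  if (nrow(agg) < 3L) {
    stop("calibration needs at least 3 ", level, "s after aggregation",
         call. = FALSE)
  }
  if (stats::sd(agg$ndvimax) == 0) {
    stop("singular design: NDVI_max is constant across ", level, "s",
         call. = FALSE)
  }
  fit <- stats::lm(density ~ ndvimax, data = agg)
  sm <- summary(fit)
  structure(list(
    nutrient = nutrient,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    n_sites = nrow(agg),
    r2 = sm$r.squared,
    p_value = unname(sm$coefficients[2L, 4L]),
    residual_sd = sm$sigma,
    level = level), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> %s density = %.4g + %.4g * NDVI_max (ton/km^2)\n",
    x$nutrient, x$intercept, x$slope))
  cat(sprintf("  n = %d %ss, r^2 = %.3f, p = %.3g, residual sd = %.3g\n",
              x$n_sites, x$level, x$r2, x$p_value, x$residual_sd))
  invisible(x)
}

#' Predict nutrient density from NDVI_max
#'
#' Applies the linear calibration; negative predictions are clamped to 0
#' (the number clamped is reported via an attribute).
#'
#' @param fit A `calibration_fit`.
#' @param ndvimax Numeric vector of NDVI_max values.
#' @return Densities (ton/km^2) with attribute `n_clamped`.
#' @export
predict_density <- function(fit, ndvimax) {
  stopifnot(inherits(fit, "calibration_fit"))
  raw <- fit$intercept + fit$slope * ndvimax
  out <- pmax(raw, 0)
  attr(out, "n_clamped") <- sum(raw < 0, na.rm = TRUE)
  out
}

#' Write / read a calibration fit as JSON
#' @param fit A `calibration_fit`.
#' @param path File path.
#' @export
write_calibration <- function(fit, path) {
  stopifnot(inherits(fit, "calibration_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "calibration_fit")
}
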