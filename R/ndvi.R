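# Annual maximum NDVI extraction for drainage areas and vegetation plots.
#
# Two aggregation orders matter and are deliberately distinct:
#  * catchment scale: per-pixel annual maximum first, then the spatial mean
#    over drainage pixels whose maximum clears the snow screen (> 0.2);
#  * plot scale: spatial mean over the few pixels covering the plot first,
#    then the maximum over scenes.

#' Create an NDVI scene
#'
#' @param grid `grid_raster` of NDVI values in \[-1, 1\] (or nodata).
#' @param year Acquisition year.
#' @param doy Day of year (1-366).
#' @param hour Local acquisition hour (fractional).
#' @return An `ndvi_scene` object.
#' @export
ndvi_scene <- function(grid, year, doy, hour = 12) {
  stopifnot(is_grid_raster(grid))
  v <- valid_values(grid)
  if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9)) {
    stop("NDVI values must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(grid = grid, year = as.integer(year), doy = as.integer(doy),
                 hour = as.numeric(hour)),
            class = "ndvi_scene")
}

.scene_year <- function(scenes) vapply(scenes, function(s) s$year, integer(1))

#' Annual NDVI maximum over a drainage area
#'
#' Applies the acquisition-time screen (scenes before `min_hour` local time
#' are discarded), computes each drainage pixel's maximum NDVI over the
#' remaining scenes of the year, drops pixels whose maximum does not exceed
#' `threshold` (the snow/bare-ground screen), and returns the arithmetic
#' mean over the retained pixels.
#'
#' @param scenes List of `ndvi_scene` objects from a single year.
#' @param drainage_mask 0/1 `grid_raster`; pixels > 0 belong to the
#'   drainage area (catchment minus lake surface).
#' @param unit_id Identifier recorded in the output.
#' @param threshold Snow screen: pixel maxima must exceed this (default 0.2).
#' @param min_hour Scenes acquired before this local hour are filtered out
#'   (default 7).
#' @param low_pixels_as_zero If `TRUE`, pixels failing the snow screen enter
#'   the mean as 0 instead of being dropped (default `FALSE`).
#' @return A one-row data.frame: `unit`, `year`, `value`, `n_scenes_used`,
#'   `n_pixels_used`. `value` is `NA` when no pixel qualifies.
#' @export
catchment_ndvimax <- function(scenes, drainage_mask, unit_id = "catchment",
                              threshold = 0.2, min_hour = 7,
                              low_pixels_as_zero = FALSE) {
  stopifnot(length(scenes) >= 1)
  years <- unique(.scene_year(scenes))
  if (length(years) != 1L) {
    stop("scenes span multiple years; aggregate one year at a time",
         call. = FALSE)
  }
  keep <- vapply(scenes, function(s) s$hour >= min_hour, logical(1))
  scenes <- scenes[keep]
  msk <- drainage_mask$values > 0 & !is_nodata(drainage_mask)
  if (length(scenes) == 0L) {
    return(data.frame(unit = unit_id, year = years, value = NA_real_,
                      n_scenes_used = 0L, n_pixels_used = 0L))
  }
  pix_max <- rep(-Inf, sum(msk))
  for (s in scenes) {
    stopifnot_same_geometry(s$grid, drainage_mask)
    v <- s$grid$values
    v[is_nodata(s$grid)] <- NA_real_
    pix_max <- pmax(pix_max, v[msk], na.rm = TRUE)
  }
  pix_max[is.infinite(pix_max)] <- NA_real_
  ok <- !is.na(pix_max) & pix_max > threshold
  if (low_pixels_as_zero) {
    vals <- ifelse(ok, pix_max, 0)
    vals <- vals[!is.na(pix_max)]
    value <- if (length(vals)) mean(vals) else NA_real_
    npix <- length(vals)
  } else {
    value <- if (any(ok)) mean(pix_max[ok]) else NA_real_
    npix <- sum(ok)
  }
  data.frame(unit = unit_id, year = years, value = value,
             n_scenes_used = length(scenes), n_pixels_used = npix)
}

#' Annual NDVI maximum for a vegetation plot
#'
#' A plot covers a handful of pixels. For each scene the mean NDVI over the
#' covering pixels is computed first; the annual value is the maximum of
#' those scene means. Snow-covered scenes (footprint NDVI at or below the
#' screen) never win the maximum. No acquisition-hour filter is applied by
#' default: plot-scale scenes are assumed mid-morning.
#'
#' @param scenes List of `ndvi_scene` objects from a single year.
#' @param footprint Integer matrix with columns `row`, `col`: the pixels the
#'   plot covers (>= 1 pixel).
#' @param unit_id Identifier recorded in the output.
#' @param min_hour Optional acquisition-hour screen (default 0 = none).
#' @return A one-row data.frame as in [catchment_ndvimax()].
#' @export
plot_ndvimax <- function(scenes, footprint, unit_id = "plot", min_hour = 0) {
  footprint <- matrix(as.integer(footprint), ncol = 2)
  stopifnot(nrow(footprint) >= 1)
  if (length(scenes) == 0L) {
    return(data.frame(unit = unit_id, year = NA_integer_, value = NA_real_,
                      n_scenes_used = 0L, n_pixels_used = nrow(footprint)))
  }
  years <- unique(.scene_year(scenes))
  if (length(years) != 1L) {
    stop("scenes span multiple years; aggregate one year at a time",
         call. = FALSE)
  }
  scenes <- scenes[vapply(scenes, function(s) s$hour >= min_hour, logical(1))]
  means <- vapply(scenes, function(s) {
    v <- s$grid$values
    v[is_nodata(s$grid)] <- NA_real_
    mean(v[footprint], na.rm = TRUE)
  }, numeric(1))
  means <- means[is.finite(means)]
  value <- if (length(means)) max(means) else NA_real_
  data.frame(unit = unit_id, year = years, value = value,
             n_scenes_used = length(means), n_pixels_used = nrow(footprint))
}

#' Annual NDVI maxima for a multi-year scene stack
#'
#' Convenience wrapper splitting a stack by year and applying
#' [catchment_ndvimax()] to each.
#'
#' @inheritParams catchment_ndvimax
#' @param scenes List of `ndvi_scene` objects spanning any years.
#' @param ... Passed on to [catchment_ndvimax()].
#' @return data.frame with one row per year (years with no qualifying pixel
#'   get `NA` values).
#' @export
annual_ndvimax_series <- function(scenes, drainage_mask,
                                  unit_id = "catchment", ...) {
  yrs <- .scene_year(scenes)
  out <- lapply(sort(unique(yrs)), function(y) {
    catchment_ndvimax(scenes[yrs == y], drainage_mask, unit_id = unit_id, ...)
  })
  do.call(rbind, out)
}
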