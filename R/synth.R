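# Seeded synthetic landscapes with the statistical structure the analysis
# assumes: a terrain with closed lake depressions, a dated NDVI scene stack
# with a logistic greening ramp, plot harvests with a linear NDVI ->
# nutrient-density truth, lake chemistry declining log-linearly with
# drainage NDVI_max, and an unequal-probability rotating-panel cover survey.
# Every product draws from its own child RNG stream of the root seed, so
# adding a product never perturbs the others.

#' Synthetic-world configuration
#'
#' Bundles every tunable of the generator with validated defaults. The
#' defaults describe the stated world the rest of the package is tested
#' against: a 38-year record (1983-2020) over a ~6.4 x 6.4 km landscape
#' with nine lakes, a logistic greening ramp centered on 1995 (width 3 y)
#' that raises peak-season NDVI by 0.10 and plateaus after ~2001, a linear
#' plot calibration (P: 2.2 x NDVI - 0.1 ton/km^2; N an order of magnitude
#' higher), log-linear chemistry declines in drainage NDVI_max with
#' lake-level random intercepts, and a dwarf-shrub cover survey trending
#' from 15% to 22% over 2003-2020 in five rotating panels.
#'
#' @param seed Root RNG seed (integer).
#' @param grid_nrows,grid_ncols Grid dimensions (>= 8).
#' @param cell_size Cell edge (m).
#' @param n_lakes Number of lake depressions to carve (>= 0).
#' @param years Inclusive year range of the NDVI record.
#' @param scenes_per_year Scenes per year (>= 1).
#' @param greening List: `ramp_center_year`, `ramp_width_years`,
#'   `amplitude` (NDVI units, >= 0).
#' @param terrain List: `slope_drop` (total west-east elevation drop, m),
#'   `hill_amplitude`, `n_hills`, `pit_depth`, `pit_radius_cells`.
#' @param ndvi List: `base` (pre-greening peak NDVI at mean elevation),
#'   `elev_range` (NDVI decrease from lowest to highest terrain),
#'   `season_floor`, `season_width_days`, `peak_doy`, `noise_sd`.
#' @param snow List: `melt_doy`, `onset_doy`, `scale_days` controlling the
#'   day-of-year snow probability; snow scenes carry NDVI <= 0.2.
#' @param morning_scene_fraction Fraction of scenes acquired before 07:00.
#' @param calib_truth List: `slope_p`, `intercept_p`, `slope_n`,
#'   `intercept_n` (ton/km^2 per NDVI unit and ton/km^2; slopes > 0),
#'   `noise_sd_p`, `noise_sd_n` (plot density noise), `n_sites`,
#'   `plots_per_site`, `ndvi_range`, `qc_incomplete`, `qc_snow` (counts of
#'   flagged plots, each on a distinct site).
#' @param chem_link List: `gamma_p`, `gamma_n` (log-concentration decline
#'   per NDVI unit, >= 0), `ndvi_ref`, `baseline_p`, `baseline_din`,
#'   `baseline_toc`, `lake_intercept_sd`, `noise_sd`.
#' @param cover List: `years`, `start`, `end` (true mean cover),
#'   `n_sites`, `plots_per_site`, `site_sd`, `n_points` (point-intercept
#'   denominator), `pi_range` (inclusion probabilities).
#' @param delayed_ramp If `TRUE` (default) one lake's surroundings green
#'   `delay_years` later, mimicking a high-elevation laggard.
#' @param delayed_lake Index of that lake.
#' @param delay_years Ramp delay (y).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         grid_nrows = 64L, grid_ncols = 64L,
                         cell_size = 100,
                         n_lakes = 9L,
                         years = 1983:2020,
                         scenes_per_year = 12L,
                         greening = list(ramp_center_year = 1995,
                                         ramp_width_years = 3,
                                         amplitude = 0.10),
                         terrain = list(slope_drop = 30, hill_amplitude = 8,
                                        n_hills = 6, pit_depth = 15,
                                        pit_radius_cells = 3),
                         ndvi = list(base = 0.45, elev_range = 0.15,
                                     season_floor = 0.35,
                                     season_width_days = 55, peak_doy = 200,
                                     noise_sd = 0.02),
                         snow = list(melt_doy = 150, onset_doy = 280,
                                     scale_days = 10),
                         morning_scene_fraction = 0.1,
                         calib_truth = list(slope_p = 2.2, intercept_p = -0.1,
                                            slope_n = 28, intercept_n = -1,
                                            noise_sd_p = 0.15,
                                            noise_sd_n = 1.5,
                                            n_sites = 38L,
                                            plots_per_site = 3L,
                                            ndvi_range = c(0.25, 0.75),
                                            qc_incomplete = 5L, qc_snow = 4L),
                         chem_link = list(gamma_p = 10, gamma_n = 8,
                                          ndvi_ref = 0.45, baseline_p = 5,
                                          baseline_din = 30, baseline_toc = 3,
                                          lake_intercept_sd = 0.3,
                                          noise_sd = 0.15),
                         cover = list(years = 2003:2020, start = 0.15,
                                      end = 0.22, n_sites = 59L,
                                      plots_per_site = 9L, site_sd = 0.04,
                                      n_points = 100L,
                                      pi_range = c(0.4, 1)),
                         delayed_ramp = TRUE, delayed_lake = 3L,
                         delay_years = 15) {
  cfg <- list(seed = as.integer(seed), grid_nrows = as.integer(grid_nrows),
              grid_ncols = as.integer(grid_ncols), cell_size = cell_size,
              n_lakes = as.integer(n_lakes), years = years,
              scenes_per_year = as.integer(scenes_per_year),
              greening = greening, terrain = terrain, ndvi = ndvi,
              snow = snow, morning_scene_fraction = morning_scene_fraction,
              calib_truth = calib_truth, chem_link = chem_link,
              cover = cover, delayed_ramp = isTRUE(delayed_ramp),
              delayed_lake = as.integer(delayed_lake),
              delay_years = delay_years)
  stopifnot(cfg$grid_nrows >= 8L, cfg$grid_ncols >= 8L, cfg$cell_size > 0,
            cfg$n_lakes >= 0L, length(cfg$years) >= 1L,
            cfg$scenes_per_year >= 1L,
            cfg$greening$amplitude >= 0,
            cfg$chem_link$gamma_p >= 0, cfg$chem_link$gamma_n >= 0,
            cfg$calib_truth$slope_p > 0, cfg$calib_truth$slope_n > 0,
            cfg$morning_scene_fraction >= 0, cfg$morning_scene_fraction < 1,
            all(cfg$cover$pi_range > 0), all(cfg$cover$pi_range <= 1))
  class(cfg) <- "synth_config"
  cfg
}

with_stream <- function(cfg, name, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(child_seed(cfg$seed, name))
  force(code)
}

#' Generate a synthetic DEM with lake depressions
#'
#' Terrain is a west-to-east regional slope plus smooth Gaussian hills,
#' into which `n_lakes` closed circular depressions are carved at
#' well-separated interior locations. Placement is retried a bounded number
#' of times; an impossible placement is an explicit failure. The pit
#' centers are recorded in the `lake_centers` attribute (rows of
#' `row`, `col`).
#'
#' @param cfg A [synth_config()].
#' @return A `grid_raster` elevation model (no nodata cells).
#' @export
generate_dem <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  nr <- cfg$grid_nrows; nc <- cfg$grid_ncols
  tr <- cfg$terrain
  with_stream(cfg, "dem", {
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    rows <- matrix(rep(seq_len(nr), nc), nr, nc)
    z <- tr$slope_drop * (nc - cols) / (nc - 1)
    if (tr$hill_amplitude > 0 && tr$n_hills > 0) {
      for (i in seq_len(tr$n_hills)) {
        hr <- runif(1, 1, nr); hc <- runif(1, 1, nc)
        amp <- runif(1, 0.4, 1) * tr$hill_amplitude * sample(c(-1, 1), 1)
        width <- runif(1, 0.1, 0.25) * max(nr, nc)
        z <- z + amp * exp(-((rows - hr)^2 + (cols - hc)^2) / (2 * width^2))
      }
    }
    centers <- NULL
    if (cfg$n_lakes > 0L) {
      margin <- tr$pit_radius_cells + 3L
      min_sep <- 2 * tr$pit_radius_cells + 4
      if (nr - 2 * margin < 1 || nc - 2 * margin < 1) {
        stop("grid too small to place lakes with the configured pit radius",
             call. = FALSE)
      }
      for (attempt in 1:50) {
        cand <- cbind(row = round(runif(cfg$n_lakes, margin, nr - margin)),
                      col = round(runif(cfg$n_lakes, margin, nc - margin)))
        d <- as.matrix(stats::dist(cand))
        diag(d) <- Inf
        if (all(d >= min_sep)) { centers <- cand; break }
      }
      if (is.null(centers)) {
        stop(sprintf(
          "could not place %d lakes on a %d x %d grid after 50 attempts",
          cfg$n_lakes, nr, nc), call. = FALSE)
      }
      # carve each pit as a bowl clamped below the minimum elevation of its
      # rim, so a closed depression exists regardless of slope and hills
      R <- tr$pit_radius_cells
      for (i in seq_len(cfg$n_lakes)) {
        d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
        rim <- d2 > R^2 & d2 <= (R + 2)^2
        rim_min <- min(z[rim])
        inside <- d2 <= R^2
        bowl <- rim_min - tr$pit_depth * (1 - d2[inside] / R^2)
        z[inside] <- pmin(z[inside], bowl)
      }
    }
    out <- grid_raster(z, 0, 0, cfg$cell_size)
    attr(out, "lake_centers") <- centers
    out
  })
}

#' Derive lake sites (outlet + lake mask) from a synthetic DEM
#'
#' Runs depression filling once: each carved pit floods up to its spill
#' level, and the lake mask is the flooded component around the pit center.
#' The outlet seed coordinate is the lake cell with maximal flow
#' accumulation, i.e., right at the spill.
#'
#' @param cfg A [synth_config()].
#' @param dem The DEM from [generate_dem()] (with `lake_centers`).
#' @return List of lake sites: `id`, `name`, `outlet` (x, y), `lake_mask`.
#' @export
generate_lakes <- function(cfg, dem) {
  centers <- attr(dem, "lake_centers")
  if (is.null(centers) || nrow(centers) == 0L) return(list())
  filled <- fill_depressions(dem)
  flow <- compute_d8(filled)
  accum <- flow_accumulation(flow)
  wet <- filled$values > dem$values + 1e-6
  nr <- nrow(wet); nc <- ncol(wet)
  lakes <- vector("list", nrow(centers))
  depth <- filled$values - dem$values
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (i in seq_len(nrow(centers))) {
    # on sloping terrain the flooded bottom can sit off the carved center:
    # seed the flood fill at the deepest water cell near the pit
    near <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2 <=
      (2 * cfg$terrain$pit_radius_cells)^2
    d <- depth
    d[!near] <- -Inf
    if (max(d) <= 1e-6) {
      stop(sprintf("lake %d failed to flood: pit at (%d, %d) is not a depression",
                   i, centers[i, 1], centers[i, 2]), call. = FALSE)
    }
    seed_cell <- which.max(d)
    comp <- .flood_component(wet, ((seed_cell - 1) %% nr) + 1,
                             ((seed_cell - 1) %/% nr) + 1)
    a <- accum$values
    a[!comp] <- -Inf
    best <- which.max(a)
    xy <- cell_xy(dem, ((best - 1) %% nr) + 1, ((best - 1) %/% nr) + 1)
    lakes[[i]] <- list(
      id = sprintf("lake_%02d", i), name = sprintf("Lake %d", i),
      outlet = unname(xy),
      lake_mask = grid_raster(matrix(as.numeric(comp), nr, nc),
                              dem$x_origin, dem$y_origin, dem$cell_size),
      center = centers[i, ])
  }
  lakes
}

# connected component (8-neighborhood) of TRUE cells containing (r0, c0)
.flood_component <- function(wet, r0, c0) {
  nr <- nrow(wet); nc <- ncol(wet)
  comp <- matrix(FALSE, nr, nc)
  if (!wet[r0, c0]) return(comp)
  queue <- integer(nr * nc)
  queue[1L] <- r0 + (c0 - 1L) * nr
  comp[r0, c0] <- TRUE
  head <- 1L; tail <- 1L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    rr <- ((i - 1L) %% nr) + 1L; cc <- ((i - 1L) %/% nr) + 1L
    for (k in 1:8) {
      r2 <- rr + D8_DR[k]; c2 <- cc + D8_DC[k]
      if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
      if (wet[r2, c2] && !comp[r2, c2]) {
        comp[r2, c2] <- TRUE
        tail <- tail + 1L
        queue[tail] <- r2 + (c2 - 1L) * nr
      }
    }
  }
  comp
}

.ramp_value <- function(year_frac, center, width) {
  stats::plogis((year_frac - center) / width)
}

.snow_prob <- function(doy, snow) {
  stats::plogis((snow$melt_doy - doy) / snow$scale_days) +
    stats::plogis((doy - snow$onset_doy) / snow$scale_days)
}

#' Generate a dated NDVI scene stack
#'
#' Per pixel and scene, NDVI is
#' `clamp(base + amplitude * logistic((t - center) / width) * season(doy)
#'  + noise, -1, 1)`, where `base` decreases smoothly with elevation,
#' `season(doy)` is a Gaussian bump peaking mid-summer, and snow-flagged
#' scenes (day-of-year-dependent probability) carry NDVI below 0.2
#' everywhere so the `> 0.2` screen is the operative snow filter. A stated
#' fraction of scenes is acquired before 07:00 local time; lake pixels
#' carry water-like negative NDVI. When `delayed_ramp` is set, pixels near
#' the configured lake green `delay_years` later.
#'
#' @param cfg A [synth_config()].
#' @param dem DEM from [generate_dem()].
#' @param lakes Lake sites from [generate_lakes()] (may be empty).
#' @return List of [ndvi_scene()] objects
#'   (`length(years) * scenes_per_year`).
#' @export
generate_scenes <- function(cfg, dem, lakes = list()) {
  stopifnot(inherits(cfg, "synth_config"))
  nr <- cfg$grid_nrows; nc <- cfg$grid_ncols
  nd <- cfg$ndvi
  z <- dem$values
  zn <- if (diff(range(z)) > 0) (z - min(z)) / diff(range(z)) else z * 0
  base <- nd$base + nd$elev_range * (0.5 - zn)
  lake_any <- matrix(FALSE, nr, nc)
  for (lk in lakes) lake_any <- lake_any | lk$lake_mask$values > 0
  delayed_region <- matrix(FALSE, nr, nc)
  if (cfg$delayed_ramp && length(lakes) >= cfg$delayed_lake) {
    ctr <- lakes[[cfg$delayed_lake]]$center
    rows <- matrix(rep(seq_len(nr), nc), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    rad <- 3 * cfg$terrain$pit_radius_cells
    delayed_region <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= rad^2
  }
  doys <- round(365 * (seq_len(cfg$scenes_per_year) - 0.5) /
                  cfg$scenes_per_year)
  g <- cfg$greening
  with_stream(cfg, "scenes", {
    scenes <- vector("list", length(cfg$years) * cfg$scenes_per_year)
    s <- 0L
    for (year in cfg$years) {
      for (doy in doys) {
        s <- s + 1L
        yf <- year + doy / 365
        ramp <- g$amplitude * .ramp_value(yf, g$ramp_center_year,
                                          g$ramp_width_years)
        ramp_late <- g$amplitude *
          .ramp_value(yf, g$ramp_center_year + cfg$delay_years,
                      g$ramp_width_years)
        season <- nd$season_floor + (1 - nd$season_floor) *
          exp(-((doy - nd$peak_doy) / nd$season_width_days)^2)
        amp <- matrix(ramp, nr, nc)
        amp[delayed_region] <- ramp_late
        v <- (base + amp) * season +
          matrix(stats::rnorm(nr * nc, 0, nd$noise_sd), nr, nc)
        if (stats::runif(1) < .snow_prob(doy, cfg$snow)) {
          v <- matrix(stats::runif(nr * nc, 0, 0.15), nr, nc)
        }
        v[lake_any] <- stats::runif(sum(lake_any), -0.15, -0.05)
        v <- pmin(pmax(v, -1), 1)
        hour <- if (stats::runif(1) < cfg$morning_scene_fraction) {
          stats::runif(1, 5, 6.9)
        } else stats::runif(1, 9, 14)
        scenes[[s]] <- ndvi_scene(
          grid_raster(v, dem$x_origin, dem$y_origin, dem$cell_size),
          year = year, doy = doy, hour = hour)
      }
    }
    scenes
  })
}

#' Generate plot harvest samples with a linear calibration truth
#'
#' Each site gets an NDVI_max (drawn uniformly from `ndvi_range`, or
#' extracted from `scenes` via [plot_ndvimax()] at random non-lake
#' footprints when a scene stack is supplied) and each plot a true areal
#' density `intercept + slope * NDVI` plus Gaussian noise; dry mass and
#' concentrations are back-calculated so that
#' `(dry_mass / 0.25 m^2) * conc / 1000` reproduces the noisy density.
#' Negative densities are resampled (bounded retries). The configured
#' numbers of snow and incomplete-removal QC flags are planted on distinct
#' sites.
#'
#' @param cfg A [synth_config()].
#' @param scenes Optional scene stack (the final year is used).
#' @param lakes Optional lake list (footprints avoid lake pixels).
#' @return A [veg_plot_samples()] frame with attribute `truth` (the planted
#'   slopes/intercepts).
#' @export
generate_veg_plots <- function(cfg, scenes = NULL, lakes = list()) {
  ct <- cfg$calib_truth
  ns <- ct$n_sites; np <- ct$plots_per_site
  with_stream(cfg, "veg_plots", {
    if (is.null(scenes)) {
      site_ndvi <- stats::runif(ns, ct$ndvi_range[1], ct$ndvi_range[2])
    } else {
      yrs <- vapply(scenes, function(s) s$year, integer(1))
      last <- scenes[yrs == max(yrs)]
      grid <- last[[1]]$grid
      lake_any <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
      for (lk in lakes) lake_any <- lake_any | lk$lake_mask$values > 0
      land <- which(!lake_any)
      cells <- sample(land, ns)
      nr <- nrow(grid$values)
      site_ndvi <- vapply(cells, function(i) {
        fp <- cbind(((i - 1) %% nr) + 1, ((i - 1) %/% nr) + 1)
        plot_ndvimax(last, fp)$value
      }, numeric(1))
    }
    rows <- list()
    for (i in seq_len(ns)) {
      for (j in seq_len(np)) {
        nv <- min(max(site_ndvi[i] + stats::rnorm(1, 0, 0.01), -1), 1)
        dens_p <- dens_n <- -1
        for (try in 1:100) {
          dens_p <- ct$intercept_p + ct$slope_p * nv +
            stats::rnorm(1, 0, ct$noise_sd_p)
          dens_n <- ct$intercept_n + ct$slope_n * nv +
            stats::rnorm(1, 0, ct$noise_sd_n)
          if (dens_p > 0 && dens_n > 0) break
        }
        if (dens_p <= 0 || dens_n <= 0) {
          stop("could not back-calculate a positive density after 100 retries",
               call. = FALSE)
        }
        dm_gm2 <- 150 + 900 * nv + stats::rnorm(1, 0, 30)
        dm <- max(dm_gm2, 10) * 0.25
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = sprintf("site_%02d", i), plot_id = j, ndvimax = nv,
          dry_mass = dm,
          conc_p = dens_p * 1000 * 0.25 / dm,
          conc_n = dens_n * 1000 * 0.25 / dm)
      }
    }
    df <- do.call(rbind, rows)
    out <- veg_plot_samples(df$site_id, df$plot_id, df$ndvimax, df$dry_mass,
                            df$conc_p, df$conc_n)
    nflag <- ct$qc_incomplete + ct$qc_snow
    if (nflag > 0) {
      if (nflag > ns) stop("more QC flags than sites", call. = FALSE)
      flag_sites <- sample(unique(out$site_id), nflag)
      for (k in seq_len(nflag)) {
        rowsel <- which(out$site_id == flag_sites[k] &
                          out$plot_id == 1L)
        if (k <= ct$qc_incomplete) {
          out$qc_incomplete_removal[rowsel] <- TRUE
        } else {
          out$qc_snow[rowsel] <- TRUE
        }
      }
    }
    attr(out, "truth") <- ct
    out
  })
}

#' Generate lake chemistry linked to drainage NDVI_max
#'
#' For each lake and year, 3-4 within-year samples are drawn with
#' `log(conc) = log(baseline) + alpha_lake - gamma * (NDVI_max - ndvi_ref)
#' + eps`, where `alpha_lake ~ N(0, lake_intercept_sd)` is drawn once per
#' lake (independently for P and N) and `eps ~ N(0, noise_sd)`. Years with
#' missing NDVI are skipped.
#'
#' @param cfg A [synth_config()].
#' @param annual_ndvimax data.frame with columns `unit` (lake id), `year`,
#'   `value` (drainage NDVI_max).
#' @return A [chem_samples()] frame with attribute `truth`.
#' @export
generate_chem <- function(cfg, annual_ndvimax) {
  cl <- cfg$chem_link
  lakes <- sort(unique(annual_ndvimax$unit))
  with_stream(cfg, "chem", {
    alpha_p <- stats::rnorm(length(lakes), 0, cl$lake_intercept_sd)
    alpha_n <- stats::rnorm(length(lakes), 0, cl$lake_intercept_sd)
    names(alpha_p) <- names(alpha_n) <- lakes
    rows <- list()
    for (i in seq_len(nrow(annual_ndvimax))) {
      lk <- annual_ndvimax$unit[i]
      yr <- annual_ndvimax$year[i]
      nv <- annual_ndvimax$value[i]
      if (is.na(nv)) next
      nsamp <- sample(3:4, 1)
      doys <- sort(sample(60:330, nsamp))
      for (d in doys) {
        lp <- log(cl$baseline_p) + alpha_p[lk] -
          cl$gamma_p * (nv - cl$ndvi_ref) + stats::rnorm(1, 0, cl$noise_sd)
        ln <- log(cl$baseline_din) + alpha_n[lk] -
          cl$gamma_n * (nv - cl$ndvi_ref) + stats::rnorm(1, 0, cl$noise_sd)
        lt <- log(cl$baseline_toc) + 0.5 * alpha_p[lk] +
          stats::rnorm(1, 0, cl$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          lake_id = lk, date = as.Date(d - 1, origin = paste0(yr, "-01-01")),
          total_p = exp(lp), din = exp(ln), toc = exp(lt))
      }
    }
    df <- do.call(rbind, rows)
    out <- chem_samples(df$lake_id, df$date, df$total_p, df$din, df$toc)
    attr(out, "truth") <- c(cl, list(alpha_p = alpha_p, alpha_n = alpha_n))
    out
  })
}

#' Generate a rotating-panel cover survey
#'
#' Sites are split into five panels; each site is observed every fifth
#' year. True mean cover rises linearly from `start` to `end` over the
#' survey years, with Gaussian site effects; plot observations add
#' binomial point-intercept noise (`n_points` points). Each site carries a
#' fixed inclusion probability drawn from `pi_range`.
#'
#' @param cfg A [synth_config()].
#' @return A [cover_plot_obs()] frame with attribute `truth`.
#' @export
generate_cover_survey <- function(cfg) {
  cv <- cfg$cover
  yrs <- cv$years
  with_stream(cfg, "cover", {
    site_pi <- stats::runif(cv$n_sites, cv$pi_range[1], cv$pi_range[2])
    site_eff <- stats::rnorm(cv$n_sites, 0, cv$site_sd)
    panel <- ((seq_len(cv$n_sites) - 1L) %% 5L) + 1L
    rows <- list()
    span <- max(yrs) - min(yrs)
    for (y in yrs) {
      on_duty <- which(panel == ((y - min(yrs)) %% 5L) + 1L)
      trend <- cv$start + (cv$end - cv$start) * (y - min(yrs)) / span
      for (s in on_duty) {
        truth <- min(max(trend + site_eff[s], 0.01), 0.95)
        obs <- stats::rbinom(cv$plots_per_site, cv$n_points, truth) /
          cv$n_points
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = sprintf("nils_%02d", s),
          plot_id = seq_len(cv$plots_per_site), year = y,
          cover_fraction = obs, inclusion_prob = site_pi[s],
          panel = panel[s])
      }
    }
    df <- do.call(rbind, rows)
    out <- cover_plot_obs(df$site_id, df$plot_id, df$year,
                          df$cover_fraction, df$inclusion_prob, df$panel)
    attr(out, "truth") <- cv
    out
  })
}

#' Generate the full synthetic bundle
#'
#' Chains the generators and the watershed/NDVI modules: DEM, lake sites,
#' delineated catchments (fill, D8, accumulation, snap, upstream
#' traversal), scene stack, per-lake annual drainage NDVI_max, plot
#' harvests, chemistry and the cover survey. Identical configurations give
#' identical bundles.
#'
#' @param cfg A [synth_config()].
#' @param snap_radius Outlet snap radius in meters (default 250).
#' @return A `synth_bundle` list: `cfg`, `dem`, `lakes` (each with
#'   `catchment_mask`, `drainage_mask` and areas), `scenes`,
#'   `annual_ndvimax`, `veg_plots`, `chem`, `cover_survey`.
#' @export
generate_bundle <- function(cfg, snap_radius = 250) {
  dem <- generate_dem(cfg)
  lakes <- generate_lakes(cfg, dem)
  filled <- fill_depressions(dem)
  flow <- compute_d8(filled)
  accum <- flow_accumulation(flow)
  for (i in seq_along(lakes)) {
    cell <- snap_outlet(lakes[[i]]$outlet, accum, radius = snap_radius)
    catch <- delineate(flow, cell)
    lakes[[i]]$outlet_cell <- cell
    lakes[[i]]$catchment_mask <- catch
    drain <- catch
    drain$values <- pmax(catch$values - lakes[[i]]$lake_mask$values, 0)
    lakes[[i]]$drainage_mask <- drain
    ar <- areas(catch, lakes[[i]]$lake_mask)
    lakes[[i]]$catchment_km2 <- ar$catchment_km2
    lakes[[i]]$lake_km2 <- ar$lake_km2
    lakes[[i]]$drainage_km2 <- ar$drainage_km2
  }
  scenes <- generate_scenes(cfg, dem, lakes)
  annual <- do.call(rbind, lapply(lakes, function(lk) {
    annual_ndvimax_series(scenes, lk$drainage_mask, unit_id = lk$id)
  }))
  veg <- generate_veg_plots(cfg)
  chem <- if (length(lakes)) generate_chem(cfg, annual) else NULL
  cover <- generate_cover_survey(cfg)
  structure(list(cfg = cfg, dem = dem, lakes = lakes, scenes = scenes,
                 annual_ndvimax = annual, veg_plots = veg, chem = chem,
                 cover_survey = cover), class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf(
    "<synth_bundle> seed %d: %d x %d grid, %d lakes, %d scenes (%d-%d)\n",
    x$cfg$seed, x$cfg$grid_nrows, x$cfg$grid_ncols, length(x$lakes),
    length(x$scenes), min(x$cfg$years), max(x$cfg$years)))
  invisible(x)
}
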