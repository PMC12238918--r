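# Dwarf-shrub cover estimation from unequal-probability survey plots:
# Horvitz-Thompson estimation and its 5-year moving average.

#' Construct cover-survey observations
#'
#' @param site_id,plot_id Identifiers.
#' @param year Survey year.
#' @param cover_fraction Observed cover in \[0, 1\].
#' @param inclusion_prob First-order inclusion probability in (0, 1\].
#' @param panel Rotation panel (1-5; one fifth of sites per year).
#' @return data.frame of class `cover_plot_obs`.
#' @export
cover_plot_obs <- function(site_id, plot_id, year, cover_fraction,
                           inclusion_prob, panel = NA_integer_) {
  df <- data.frame(site_id = site_id, plot_id = plot_id, year = year,
                   cover_fraction = cover_fraction,
                   inclusion_prob = inclusion_prob, panel = panel)
  stopifnot(all(df$cover_fraction >= 0 & df$cover_fraction <= 1),
            all(df$inclusion_prob > 0 & df$inclusion_prob <= 1))
  class(df) <- c("cover_plot_obs", "data.frame")
  df
}

#' Horvitz-Thompson cover estimate for one year
#'
#' Ratio (Hajek) form by default: `sum(cover_i / pi_i) / sum(1 / pi_i)`,
#' which targets the mean cover fraction and reduces to the arithmetic mean
#' under equal inclusion probabilities. `type = "total"` returns the pure
#' HT total `sum(cover_i / pi_i)` instead.
#'
#' @param obs A [cover_plot_obs()] frame for a single year.
#' @param type `"ratio"` (default) or `"total"`.
#' @return One-row data.frame: `year`, `ht_estimate`, `n_plots`.
#' @export
ht_estimate <- function(obs, type = c("ratio", "total")) {
  type <- match.arg(type)
  stopifnot(nrow(obs) >= 1)
  if (any(obs$inclusion_prob <= 0)) {
    stop("inclusion probabilities must be positive", call. = FALSE)
  }
  yr <- unique(obs$year)
  if (length(yr) != 1L) {
    stop("observations span multiple years; estimate one year at a time",
         call. = FALSE)
  }
  w <- 1 / obs$inclusion_prob
  est <- if (type == "ratio") {
    sum(obs$cover_fraction * w) / sum(w)
  } else {
    sum(obs$cover_fraction * w)
  }
  data.frame(year = yr, ht_estimate = est, n_plots = nrow(obs))
}

#' Annual Horvitz-Thompson series with 5-year moving average
#'
#' Applies [ht_estimate()] per year and attaches the centered moving
#' average (shrinking at the edges, missing years skipped) computed by
#' [moving_average()].
#'
#' @param obs A [cover_plot_obs()] frame spanning any years.
#' @param window Moving-average window (odd, default 5).
#' @param type Passed to [ht_estimate()].
#' @return data.frame: `year`, `ht_estimate`, `n_plots`, `ma5`,
#'   `n_in_window`.
#' @export
ht_series <- function(obs, window = 5, type = "ratio") {
  yrs <- sort(unique(obs$year))
  est <- do.call(rbind, lapply(yrs, function(y) {
    ht_estimate(obs[obs$year == y, , drop = FALSE], type = type)
  }))
  ma <- moving_average(est$ht_estimate, est$year, window = window)
  est$ma5 <- ma$ma
  est$n_in_window <- ma$n_in_window
  est
}
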