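# Small shared helpers.

#' Centered moving average over a (possibly gappy) annual series
#'
#' For each year the mean is taken over observations whose year lies within
#' `(window - 1) / 2` of it, so the window shrinks at the series edges and
#' missing years are simply skipped (the number of contributing years is
#' recorded).
#'
#' @param values Numeric values.
#' @param years Corresponding years (default consecutive).
#' @param window Odd window length >= 1.
#' @return data.frame with `year`, `value` (input), `ma` and `n_in_window`.
#' @export
moving_average <- function(values, years = seq_along(values), window = 5) {
  stopifnot(window >= 1, window %% 2 == 1, length(values) == length(years))
  half <- (window - 1) / 2
  o <- order(years)
  years <- years[o]; values <- values[o]
  ok <- !is.na(values)
  ma <- vapply(years, function(y) {
    w <- ok & abs(years - y) <= half
    if (any(w)) mean(values[w]) else NA_real_
  }, numeric(1))
  nw <- vapply(years, function(y) sum(ok & abs(years - y) <= half),
               integer(1))
  data.frame(year = years, value = values, ma = ma, n_in_window = nw)
}

# deterministic 31-bit child seed derived from a root seed and a stream
# name, so adding a generator product never perturbs the others
child_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
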