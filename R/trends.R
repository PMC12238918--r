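# Trend statistics for lake chemistry: annual aggregation, Mann-Kendall
# tests with tie-corrected variance, Sen's slope, percent-per-year declines
# and a penalized-spline smooth with lake-level random intercepts.

#' Construct lake chemistry samples
#'
#' @param lake_id Identifiers.
#' @param date `Date` (or year-fraction numeric) of sampling.
#' @param total_p Total phosphorus (ug/L, >= 0).
#' @param din Dissolved inorganic nitrogen, the sum of nitrite-N, nitrate-N
#'   and ammonium-N (ug/L, >= 0).
#' @param toc Total organic carbon (mg/L, >= 0).
#' @return data.frame of class `chem_samples` with a `year` column.
#' @export
chem_samples <- function(lake_id, date, total_p, din, toc = NA_real_) {
  year <- if (inherits(date, "Date")) {
    as.integer(format(date, "%Y"))
  } else as.integer(floor(date))
  df <- data.frame(lake_id = lake_id, date = date, year = year,
                   total_p = total_p, din = din, toc = toc)
  stopifnot(all(df$total_p >= 0, na.rm = TRUE),
            all(df$din >= 0, na.rm = TRUE))
  class(df) <- c("chem_samples", "data.frame")
  df
}

#' Annual means of chemistry samples
#'
#' Arithmetic mean of the within-year samples (typically 3-4 sampling
#' occasions) per lake and year.
#'
#' @param samples A [chem_samples()] frame.
#' @param response Column to aggregate (`"total_p"`, `"din"` or `"toc"`).
#' @return data.frame with `lake_id`, `year`, `value`, `n_samples`.
#' @export
annual_mean <- function(samples, response = c("total_p", "din", "toc")) {
  response <- match.arg(response)
  v <- samples[[response]]
  keep <- !is.na(v)
  agg <- aggregate(list(value = v[keep]),
                   by = list(lake_id = samples$lake_id[keep],
                             year = samples$year[keep]), mean)
  nn <- aggregate(list(n_samples = v[keep]),
                  by = list(lake_id = samples$lake_id[keep],
                            year = samples$year[keep]), length)
  out <- merge(agg, nn, by = c("lake_id", "year"))
  out[order(out$lake_id, out$year), , drop = FALSE]
}

#' Mann-Kendall trend test
#'
#' Computes the S statistic, its tie-corrected variance
#' `var_s = (n (n-1) (2n+5) - sum_t t (t-1) (2t+5)) / 18` over tie groups in
#' the data values, the continuity-corrected normal deviate
#' `z = (S -+ 1) / sqrt(var_s)` (0 when S = 0), the two-sided normal
#' p-value, tau-b, and Sen's slope/intercept of the same series.
#'
#' @param values Numeric series (missing values dropped).
#' @param times Observation times (default consecutive); used for Sen's
#'   slope and to order the series.
#' @return A `trend_result` list: `n`, `s`, `var_s`, `z`, `p_two_sided`,
#'   `kendall_tau`, `sen_slope`, `sen_intercept`.
#' @export
mann_kendall <- function(values, times = seq_along(values)) {
  ok <- !is.na(values) & !is.na(times)
  x <- values[ok][order(times[ok])]
  t_ <- sort(times[ok])
  n <- length(x)
  if (n < 4L) stop("Mann-Kendall needs >= 4 non-missing points",
                   call. = FALSE)
  d <- sign(outer(x, x, "-"))
  s <- sum(d[lower.tri(d)])  # sum over i < j of sign(x_j - x_i)
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  # tau-b: tie-adjusted denominator (times assumed untied unless duplicated)
  n0 <- n * (n - 1) / 2
  nt <- sum(ties * (ties - 1) / 2)
  tt <- table(t_); tt <- tt[tt > 1]
  nu <- sum(tt * (tt - 1) / 2)
  tau <- s / sqrt((n0 - nt) * (n0 - nu))
  sen <- sen_slope(x, t_)
  structure(list(n = n, s = s, var_s = var_s, z = z, p_two_sided = p,
                 kendall_tau = tau, sen_slope = sen$slope,
                 sen_intercept = sen$intercept), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend_result> n = %d, S = %d, z = %.3f, p = %.4g, tau = %.3f, Sen slope = %.4g\n",
    x$n, x$s, x$z, x$p_two_sided, x$kendall_tau, x$sen_slope))
  invisible(x)
}

#' Exact Mann-Kendall p-value by permutation (small n)
#'
#' Enumerates all permutations of the series ranks (n <= 10) and returns the
#' exact two-sided probability of |S| at least as large as observed. Serves
#' as an oracle for the normal approximation.
#'
#' @param values Numeric series, n <= 10.
#' @return Exact two-sided p-value.
#' @export
mann_kendall_exact_p <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  stopifnot(n >= 3L, n <= 10L)
  d <- sign(outer(x, x, "-"))
  s_obs <- abs(sum(d[lower.tri(d)]))
  perms <- .permutations(n)
  s_all <- apply(perms, 1L, function(p) {
    d <- sign(outer(x[p], x[p], "-"))
    sum(d[lower.tri(d)])
  })
  mean(abs(s_all) >= s_obs)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Sen's slope
#'
#' Median of all pairwise slopes `(x_j - x_i) / (t_j - t_i)` over i < j;
#' pairs with duplicate timestamps are excluded. The intercept is the
#' median of `x - slope * t`.
#'
#' @param values Numeric series (n >= 2 after removing missings).
#' @param times Observation times (default consecutive).
#' @return List with `slope` (units per time unit) and `intercept`.
#' @export
sen_slope <- function(values, times = seq_along(values)) {
  ok <- !is.na(values) & !is.na(times)
  x <- values[ok]; t_ <- times[ok]
  n <- length(x)
  if (n < 2L) stop("Sen's slope needs >= 2 points", call. = FALSE)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)  # row > col: j > i
  dt <- t_[ij[, 1L]] - t_[ij[, 2L]]
  dx <- x[ij[, 1L]] - x[ij[, 2L]]
  keep <- dt != 0
  if (!any(keep)) stop("all timestamps are duplicated", call. = FALSE)
  slope <- stats::median(dx[keep] / dt[keep])
  list(slope = slope, intercept = stats::median(x - slope * t_))
}

#' Percent-per-year decline between two endpoint concentrations
#'
#' Uses the inclusive-year denominator
#' `100 * (c_start - c_end) / c_start / (year_end - year_start + 1)`,
#' the convention under which e.g. a decline from 5.3 to 1.2 ug/L over
#' 1996-2020 is 3.1 %/y.
#'
#' @param c_start,c_end Concentrations (start > 0).
#' @param year_start,year_end Years (`year_end > year_start`).
#' @return Decline in percent per year (positive = decline).
#' @export
percent_decline <- function(c_start, c_end, year_start, year_end) {
  stopifnot(c_start > 0, year_end > year_start)
  100 * (c_start - c_end) / c_start / (year_end - year_start + 1)
}

# cubic B-spline design with k basis functions on the range of x;
# for k < 4 a polynomial basis (1, x, ...) is used instead
.smooth_basis <- function(x, k, xr = range(x)) {
  if (k < 4L) {
    B <- outer(x, 0:(k - 1L), `^`)
    attr(B, "penalty") <- matrix(0, k, k)
    return(B)
  }
  nknots <- k - 2L  # interior + boundary layout giving k columns
  knots <- seq(xr[1L], xr[2L], length.out = nknots)
  B <- splines::splineDesign(
    knots = c(rep(xr[1L], 3L), knots, rep(xr[2L], 3L)),
    x = pmin(pmax(x, xr[1L]), xr[2L]), ord = 4L)
  D <- diff(diag(ncol(B)), differences = 2L)  # 2nd-difference penalty
  attr(B, "penalty") <- crossprod(D)
  B
}

#' Penalized-spline smooth with lake-level random intercepts
#'
#' Approximates a Gaussian additive mixed model: a cubic penalized
#' regression spline in `x` (second-difference penalty on the B-spline
#' coefficients, smoothing parameter chosen by generalized cross-validation
#' on a log-spaced grid) plus a random intercept per lake, fitted by
#' backfitting. Given the intercepts, the smooth is refitted by penalized
#' least squares; given the smooth, each lake's intercept is the
#' shrinkage-weighted mean of its residuals,
#' `b_l = n_l * rbar_l / (n_l + sigma^2 / tau^2)` with moment estimates of
#' the residual and between-lake variances, centered to sum to zero.
#' Iteration stops when the relative change in fitted values drops below
#' `tol`.
#'
#' @param x Predictor (e.g., drainage NDVI_max or shrub cover).
#' @param y Response (e.g., log nutrient concentration).
#' @param lake Factor/character lake labels (>= 2 lakes unless `k = 2`).
#' @param k Basis dimension (default 10; `k = 2` gives a straight line).
#' @param lambda_grid Smoothing-parameter grid for GCV.
#' @param max_iter,tol Backfitting controls.
#' @return A `mixed_smooth_fit` list: `fitted`, `smooth` (the spline part),
#'   `intercepts` (named, sum ~ 0), `lambda`, `edf`,
#'   `deviance_explained` (= 1 - RSS/TSS), plus a `predict_smooth` function
#'   of new x.
#' @export
fit_mixed_smooth <- function(x, y, lake, k = 10,
                             lambda_grid = 10^seq(-6, 8, length.out = 30),
                             max_iter = 200, tol = 1e-8) {
  ok <- !is.na(x) & !is.na(y) & !is.na(lake)
  x <- x[ok]; y <- y[ok]; lake <- factor(lake[ok])
  n <- length(y)
  if (n < 10L) stop("mixed smooth needs >= 10 points", call. = FALSE)
  if (nlevels(lake) < 2L && k > 2L) {
    # single lake: intercept is absorbed by the smooth
  }
  xr <- range(x)
  B <- .smooth_basis(x, k, xr)
  P <- attr(B, "penalty")
  BtB <- crossprod(B)
  nl <- table(lake)
  b <- setNames(rep(0, nlevels(lake)), levels(lake))
  fitted_old <- rep(Inf, n)
  lambda <- NA_real_
  beta <- NULL
  for (iter in seq_len(max_iter)) {
    yt <- y - b[lake]
    # GCV over the grid for the partial residual fit
    best <- NULL
    for (lam in lambda_grid) {
      A <- BtB + lam * P
      ch <- tryCatch(chol(A), error = function(e) NULL)
      if (is.null(ch)) next
      bet <- backsolve(ch, forwardsolve(t(ch), crossprod(B, yt)))
      fit <- drop(B %*% bet)
      edf <- sum(diag(chol2inv(ch) %*% BtB))
      rss <- sum((yt - fit)^2)
      gcv <- n * rss / (n - edf)^2
      if (is.null(best) || gcv < best$gcv) {
        best <- list(gcv = gcv, beta = bet, fit = fit, lam = lam, edf = edf)
      }
    }
    if (is.null(best)) stop("smooth fit failed on all lambda values",
                            call. = FALSE)
    smooth <- best$fit
    lambda <- best$lam
    beta <- best$beta
    # intercept update: shrinkage-weighted lake means of residuals
    r <- y - smooth
    if (nlevels(lake) >= 2L) {
      rbar <- tapply(r, lake, mean)
      sigma2 <- max(mean((r - rbar[lake])^2), 1e-12)
      tau2 <- max(stats::var(as.numeric(rbar)), 1e-12)
      kappa <- sigma2 / tau2
      b <- as.numeric(nl) * rbar / (as.numeric(nl) + kappa)
      b <- b - mean(b)
    }  # single lake: the smooth absorbs the intercept, b stays 0
    fitted <- unname(smooth + b[lake])
    delta <- sqrt(sum((fitted - fitted_old)^2) /
                    max(sum(fitted_old^2), 1e-12))
    if (is.finite(delta) && delta < tol) {
      fitted_old <- fitted
      break
    }
    fitted_old <- fitted
    if (iter == max_iter) {
      stop(sprintf(
        "mixed smooth did not converge in %d iterations (last rel. change %.3g)",
        max_iter, delta), call. = FALSE)
    }
  }
  rss <- sum((y - fitted_old)^2)
  tss <- sum((y - mean(y))^2)
  beta_final <- beta
  predict_smooth <- function(newx) {
    drop(.smooth_basis(newx, k, xr) %*% beta_final)
  }
  structure(list(
    fitted = fitted_old, smooth = drop(B %*% beta_final),
    x = x, y = y, lake = lake,
    intercepts = setNames(as.numeric(b), levels(lake)),
    lambda = lambda, k = k,
    deviance_explained = 1 - rss / tss,
    predict_smooth = predict_smooth), class = "mixed_smooth_fit")
}

#' @export
print.mixed_smooth_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_smooth_fit> k = %d, lambda = %.3g, %d lakes, deviance explained = %.1f%%\n",
    x$k, x$lambda, length(x$intercepts), 100 * x$deviance_explained))
  invisible(x)
}
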