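test_that("annual means aggregate within-year samples per lake", {
  s <- chem_samples(rep("L", 3), as.Date(c("2000-03-01", "2000-08-01",
                                           "2001-06-01")),
                    total_p = c(4, 6, 5), din = c(10, 20, 30))
  am <- annual_mean(s, "total_p")
  expect_equal(am$value, c(5, 5))
  expect_equal(am$n_samples, c(2L, 1L))
})

test_that("Mann-Kendall matches the closed-form normal approximation", {
  # strictly increasing n = 4: S = 6, var_s = 26/3, z = 5/sqrt(26/3)
  tr <- mann_kendall(c(1, 2, 3, 4))
  expect_equal(tr$s, 6)
  expect_equal(tr$var_s, 26 / 3)
  expect_equal(tr$z, 5 / sqrt(26 / 3))
  expect_equal(tr$p_two_sided, 2 * pnorm(-5 / sqrt(26 / 3)))
  expect_equal(tr$p_two_sided, 0.0894, tolerance = 1e-3)

  # antisymmetry: reversing negates S, keeps p
  rev_tr <- mann_kendall(c(4, 3, 2, 1))
  expect_equal(rev_tr$s, -6)
  expect_equal(rev_tr$p_two_sided, tr$p_two_sided)

  # constant series: S = 0, p = 1 (not an error)
  const_tr <- mann_kendall(rep(2, 6))
  expect_equal(const_tr$s, 0)
  expect_equal(const_tr$p_two_sided, 1)

  expect_error(mann_kendall(c(1, 2, 3)), ">= 4")
})

test_that("tie correction subtracts the tie-group terms from var_s", {
  x <- c(1, 2, 2, 3, 4)  # one tie group of size 2
  tr <- mann_kendall(x)
  n <- 5
  expect_equal(tr$var_s,
               (n * (n - 1) * (2 * n + 5) - 2 * 1 * 9) / 18)
})

test_that("normal approximation tracks the exact permutation p at small n", {
  for (x in list(c(1, 3, 2, 5, 4, 6), c(2, 1, 4, 3, 6, 5, 8))) {
    p_norm <- mann_kendall(x)$p_two_sided
    p_exact <- mann_kendall_exact_p(x)
    expect_lt(abs(p_norm - p_exact), 0.06)
  }
  # a clear trend should be significant under both
  expect_lt(mann_kendall_exact_p(1:7), 0.01)
})

test_that("Mann-Kendall is invariant to input record order", {
  set.seed(20)
  x <- rnorm(15); t_ <- 2000:2014
  perm <- sample(15)
  a <- mann_kendall(x, t_)
  b <- mann_kendall(x[perm], t_[perm])
  expect_equal(b$s, a$s)
  expect_equal(b$sen_slope, a$sen_slope)
})

test_that("Sen's slope is exact on lines, robust to one outlier", {
  t_ <- 0:8
  expect_equal(sen_slope(2 * t_ + 1, t_), list(slope = 2, intercept = 1))
  y <- 2 * t_ + 1
  y[5] <- y[5] + 100  # gross outlier in 9 points
  expect_equal(sen_slope(y, t_)$slope, 2)
  expect_equal(sen_slope(c(3, 1), c(0, 1))$slope, -2)
  # shift invariance / time equivariance
  s1 <- sen_slope(y, t_)
  expect_equal(sen_slope(y + 10, t_)$slope, s1$slope)
  expect_equal(sen_slope(y, t_ + 1995)$slope, s1$slope)
  # duplicate timestamps excluded from pairs; all-duplicate fails
  expect_equal(sen_slope(c(1, 5, 3), c(0, 0, 1))$slope,
               median(c((3 - 1) / 1, (3 - 5) / 1)))
  expect_error(sen_slope(c(1, 2), c(5, 5)), "duplicated")
})

test_that("percent decline uses the inclusive-year denominator", {
  expect_equal(percent_decline(10, 10, 2000, 2010), 0)
  expect_equal(percent_decline(10, 5, 2001, 2010), 100 * 0.5 / 10)
  expect_error(percent_decline(0, 1, 2000, 2010))
})

test_that("mixed smooth: noiseless signal plus lake offsets is fit exactly", {
  set.seed(30)
  lakes <- rep(letters[1:4], each = 15)
  x <- runif(60, 0.3, 0.7)
  offs <- c(a = 0.5, b = -0.2, c = 0, d = -0.3)
  y <- 2 - 3 * x + offs[lakes]  # linear signal lies in the penalty null space
  fit <- fit_mixed_smooth(x, y, lakes)
  expect_gt(fit$deviance_explained, 1 - 1e-6)
  # recovered intercepts match the centered true offsets
  expect_equal(unname(fit$intercepts), unname(offs - mean(offs)),
               tolerance = 1e-4)
})

test_that("mixed smooth with k = 2 and one lake reduces to OLS", {
  set.seed(31)
  x <- runif(30); y <- 1 + 2 * x + rnorm(30, 0, 0.1)
  fit <- fit_mixed_smooth(x, y, rep("only", 30), k = 2)
  ols <- lm(y ~ x)
  expect_equal(fit$fitted, unname(fitted(ols)), tolerance = 1e-6)
})

test_that("mixed smooth on pure noise explains little and stays near flat", {
  set.seed(32)
  devs <- replicate(20, {
    x <- runif(40, 0, 1)
    y <- rnorm(40)
    lk <- rep(c("a", "b"), 20)
    fit <- fit_mixed_smooth(x, y, lk)
    fit$deviance_explained
  })
  expect_lt(mean(devs), 0.35)
  expect_lt(median(devs), 0.3)
})

test_that("mixed smooth recovers a planted monotone decreasing link", {
  set.seed(33)
  lakes <- rep(sprintf("l%d", 1:5), each = 20)
  x <- runif(100, 0.3, 0.7)
  y <- -4 * x + rep(rnorm(5, 0, 0.3), each = 20) + rnorm(100, 0, 0.1)
  fit <- fit_mixed_smooth(x, y, lakes)
  grid <- seq(quantile(x, 0.05), quantile(x, 0.95), length.out = 50)
  sm <- fit$predict_smooth(grid)
  expect_true(all(diff(sm) < 0))
})
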