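test_that("trend_regression matches the normal equations exactly", {
  set.seed(61)
  yrs <- seq(-5, 5)
  vals <- 2.2 - 0.024 * yrs + rnorm(11, sd = 0.02)
  tf <- trend_regression(yrs, vals, 8)
  X <- cbind(1, yrs)
  beta <- solve(t(X) %*% X, t(X) %*% vals)
  expect_equal(tf$intercept, beta[1], tolerance = 1e-10)
  expect_equal(tf$slope, beta[2], tolerance = 1e-10)
  expect_equal(tf$prediction, beta[1] + beta[2] * 8, tolerance = 1e-10)
  ss_res <- sum((vals - X %*% beta)^2)
  expect_equal(tf$r_squared, 1 - ss_res / sum((vals - mean(vals))^2),
               tolerance = 1e-10)
})

test_that("trend_regression handles exact and degenerate fits", {
  tf <- trend_regression(1:5, 2 + 3 * (1:5), 10)
  expect_equal(tf$r_squared, 1)
  expect_equal(tf$prediction, 32, tolerance = 1e-10)
  # constant values: zero slope, the flat line explains everything
  tc <- trend_regression(1:4, rep(2, 4), 9)
  expect_equal(tc$slope, 0)
  expect_equal(tc$prediction, 2)
  expect_equal(tc$r_squared, 1)
  expect_error(trend_regression(1:2, 1:2, 3), "at least 3")
  expect_error(trend_regression(c(1, 1, 2), 1:3, 3), "distinct")
})

test_that("bootstrap interval covers the distance of same-law frequency pairs", {
  dist <- gamma_spec(1, 3)
  ci <- bootstrap_distance_ci(dist, q98, n = 5000, n_vectors = 200, seed = 62)
  expect_lt(ci$lo, ci$hi)
  expect_gt(ci$lo, 0)
  # fresh same-distribution pairs should fall inside ~95% of the time
  set.seed(63)
  p <- cell_probabilities(dist, q98)
  hits <- replicate(200, {
    a <- drop(rmultinom(1, 5000, p)) / 5000
    b <- drop(rmultinom(1, 5000, p)) / 5000
    d <- linf(a, b)
    d >= ci$lo && d <= ci$hi
  })
  expect_gt(mean(hits), 0.85)
})

test_that("bootstrap interval endpoints shrink with the sample size", {
  dist <- gamma_spec(1, 3)
  ci_small <- bootstrap_distance_ci(dist, q98, n = 2000, n_vectors = 150,
                                    seed = 64)
  ci_big <- bootstrap_distance_ci(dist, q98, n = 50000, n_vectors = 150,
                                  seed = 64)
  expect_lt(ci_big$hi, ci_small$hi)
  expect_lt(ci_big$lo, ci_small$lo)
})

test_that("KL bootstrap counts undefined pairs instead of averaging them", {
  # a tiny sample over a scale with a rare cell forces zero cells
  dist <- gamma_spec(1, 3)
  sc <- interval_scale(c(0, 9), c(9, Inf))
  ci <- bootstrap_distance_ci(dist, sc, n = 30, n_vectors = 50,
                              metric = "kl", seed = 65)
  expect_gt(ci$n_undefined, 0)
  expect_true(is.finite(ci$hi))
  ci2 <- bootstrap_distance_ci(dist, q98, n = 20000, n_vectors = 50,
                               metric = "kl", seed = 65)
  expect_identical(ci2$n_undefined, 0L)
  expect_gte(ci2$lo, 0)
})

test_that("a distribution drift moves the interval away from zero", {
  d1 <- gamma_spec(1, 3)
  d2 <- gamma_spec(1, 4)
  same <- bootstrap_distance_ci(d1, q98, n = 20000, n_vectors = 100, seed = 66)
  drift <- bootstrap_distance_ci(d1, q98, n = 20000, n_vectors = 100,
                                 seed = 66, dist2 = d2)
  expect_gt(drift$lo, same$hi)
})

test_that("estimation_error_report flags errors against the intervals", {
  truth <- c(0.5, 0.3, 0.2)
  ci <- list(hi = 0.05, lo = 0.001)
  class(ci) <- "distance_ci"
  near <- estimation_error_report(c(0.51, 0.29, 0.2), truth, ci_linf = ci)
  expect_equal(near$linf, 0.01)
  expect_true(near$linf_within_ci)
  far <- estimation_error_report(c(0.7, 0.2, 0.1), truth, ci_linf = ci)
  expect_false(far$linf_within_ci)
  # undefined KL propagates as NA, not an error
  rep0 <- estimation_error_report(c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                                  ci_kl = ci)
  expect_identical(rep0$kl, NA_real_)
  expect_identical(rep0$kl_within_ci, NA)
})
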