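test_that("cell probabilities are CDF differences and conserve mass", {
  # Gamma(1, 3) is exponential: closed-form cells 1 - exp(-x/3)
  d <- gamma_spec(1, 3)
  expF <- function(x) 1 - exp(-x / 3)
  expect_equal(cell_probabilities(d, q97),
               diff(c(expF(c(0, 1, 2, 3)), 1)), tolerance = 1e-12)
  expect_equal(cell_probabilities(d, q98),
               diff(c(expF(c(0, 1, 2.5, 4.5, 6.5)), 1)), tolerance = 1e-12)
  expect_equal(cell_probabilities(d, interval_scale(0, Inf)), 1)

  set.seed(5)
  for (i in 1:10) {
    dist <- gamma_spec(runif(1, 0.5, 3), runif(1, 0.5, 4))
    sc <- random_contiguous_scale(sample(2:6, 1))
    expect_lt(abs(sum(cell_probabilities(dist, sc)) - 1), 1e-12)
  }
})

test_that("interval_probability matches the CDF and handles edge intervals", {
  expect_equal(interval_probability(gamma_spec(2, 1), 0, Inf), 1)
  expect_equal(interval_probability(gamma_spec(1, 3), 0, 1),
               1 - exp(-1 / 3))
  expect_equal(interval_probability(gamma_spec(1, 3), 2, 2), 0)
})

test_that("midpoint mean is the dot product with midpoints and is linear", {
  expect_equal(midpoint_mean(c(1, 0, 0, 0), q97), 0.5)
  # counts are normalised first, so the mean is the weighted average
  z <- c(0.505, 0.226, 0.122, 0.0663, 0.0797)
  expect_equal(midpoint_mean(z, q98),
               sum(z * c(0.5, 1.75, 3.5, 5.5, 6.5)) / sum(z))
  set.seed(6)
  for (i in 1:10) {
    p <- random_prob_vector(5); q <- random_prob_vector(5)
    lam <- runif(1)
    expect_equal(midpoint_mean(lam * p + (1 - lam) * q, q98),
                 lam * midpoint_mean(p, q98) +
                   (1 - lam) * midpoint_mean(q, q98))
  }
  expect_error(midpoint_mean(c(0.5, 0.5), q98), "match")
})

test_that("pinned-shape two-bin fit has the closed-form scale m/log(2)", {
  for (m in c(1, 2.5, 4)) {
    sc <- interval_scale(c(0, m), c(m, Inf))
    fit <- fit_grouped_mle(c(0.5, 0.5), sc, fixed = list(shape = 1))
    expect_equal(fit$dist$params$scale, m / log(2), tolerance = 1e-6)
  }
})

test_that("grouped MLE recovers parameters from exact expected counts", {
  truth <- gamma_spec(2, 1.5)
  counts <- 1e6 * cell_probabilities(truth, q98)
  fit <- fit_grouped_mle(counts, q98)
  expect_equal(fit$dist$params$shape, 2, tolerance = 0.01)
  expect_equal(fit$dist$params$scale, 1.5, tolerance = 0.01)
  # the fitted point beats a likelihood grid around the truth
  grid <- expand.grid(shape = seq(1.9, 2.1, length.out = 11),
                      scale = seq(1.4, 1.6, length.out = 11))
  gl <- apply(grid, 1, function(g) {
    sum(counts * log(cell_probabilities(gamma_spec(g[1], g[2]), q98)))
  })
  expect_gte(fit$loglik, max(gl) - 1e-6)
})

test_that("fitting probabilities equals fitting the counts they came from", {
  counts <- c(5200, 2600, 1400, 800)
  f1 <- fit_grouped_mle(counts, q97)
  f2 <- fit_grouped_mle(counts / sum(counts), q97)
  expect_equal(f1$dist$params$shape, f2$dist$params$shape, tolerance = 1e-4)
  expect_equal(f1$mean, f2$mean, tolerance = 1e-4)
})

test_that("grouped MLE attains at least the truth's likelihood on model data", {
  set.seed(9)
  for (i in 1:5) {
    truth <- gamma_spec(runif(1, 0.7, 2.5), runif(1, 1, 3))
    counts <- drop(rmultinom(1, 5e4, cell_probabilities(truth, q98)))
    fit <- fit_grouped_mle(counts, q98)
    ll_truth <- sum(counts * log(cell_probabilities(truth, q98)))
    expect_gte(fit$loglik, ll_truth - 1e-8)
  }
})

test_that("recovered means stay within 3 SE over a gamma parameter grid", {
  set.seed(10)
  for (shape in c(0.8, 1, 2)) {
    for (scale in c(1, 2, 3)) {
      truth <- gamma_spec(shape, scale)
      counts <- drop(rmultinom(1, 1e5, cell_probabilities(truth, q97)))
      fit <- fit_grouped_mle(counts, q97)
      expect_false(is.na(fit$se_mean))
      expect_lt(abs(fit$mean - shape * scale), 3 * fit$se_mean)
    }
  }
})

test_that("degenerate grouped data is rejected with clear errors", {
  expect_error(fit_grouped_mle(c(100, 0, 0, 0), q97), "single cell")
  expect_error(fit_grouped_mle(c(1, 2, 3), q97), "option count")
  expect_error(fit_grouped_mle(c(1, 2, 3, 4), q97, family = "weibull"),
               "unsupported")
  raw <- ltpa_scale_1998(smoothed = FALSE)
  expect_error(fit_grouped_mle(c(1, 1, 1, 1, 1), raw), "contiguous")
})
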