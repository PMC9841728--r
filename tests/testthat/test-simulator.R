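test_that("a scenario is fully reproducible from its seed", {
  cfg <- sim_config(n_population = 3000L, n_cohort = 1000L,
                    n_replicates = 2L, seed = 42L)
  s1 <- build_scenario(cfg)
  s2 <- build_scenario(cfg)
  expect_identical(s1$truth$x, s2$truth$x)
  expect_identical(s1$observables, s2$observables)
  s3 <- build_scenario(sim_config(n_population = 3000L, n_cohort = 1000L,
                                  n_replicates = 2L, seed = 43L))
  expect_false(identical(s1$truth$x, s3$truth$x))
})

test_that("assign_responses bins on half-open intervals with upper boundaries", {
  expect_identical(assign_responses(c(0, 0.99, 1, 2.49, 2.5, 4.49, 4.5, 9), q98),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L))
  expect_identical(assign_responses(c(0.5, 1, 2, 3, 50), q97),
                   c(1L, 2L, 3L, 4L, 4L))
  expect_error(assign_responses(-0.1, q97), "below")
  expect_error(assign_responses(1, ltpa_scale_1998(smoothed = FALSE)),
               "contiguous")
})

test_that("binned frequencies converge to the latent cell probabilities", {
  set.seed(51)
  dist <- gamma_spec(1, 3)
  x <- draw_population(dist, 2e5)
  freq <- tabulate(assign_responses(x, q98), 5) / length(x)
  expect_lt(linf(freq, cell_probabilities(dist, q98)), 0.005)
})

test_that("perturb_transition_matrix stays stochastic and near its centre", {
  set.seed(52)
  M <- random_stochastic_matrix(5)
  P <- perturb_transition_matrix(M, 1000)
  expect_equal(colSums(P), rep(1, 5), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_lt(linf_matrix(P, M), 0.1)
  # larger concentration -> tighter around the centre
  d_small <- mean(replicate(50, linf_matrix(perturb_transition_matrix(M, 1e5), M)))
  d_big <- mean(replicate(50, linf_matrix(perturb_transition_matrix(M, 100), M)))
  expect_lt(d_small, d_big)
})

test_that("generate_time_matrix respects column sums and diagonal bounds", {
  set.seed(53)
  refs <- replicate(6, random_stochastic_matrix(5), simplify = FALSE)
  arr <- array(unlist(refs), dim = c(5, 5, 6))
  dmin <- diag(apply(arr, 1:2, min)); dmax <- diag(apply(arr, 1:2, max))
  for (i in 1:10) {
    M <- generate_time_matrix(refs)
    expect_equal(colSums(M), rep(1, 5), tolerance = 1e-12)
    expect_true(all(M >= 0))
    expect_true(all(diag(M) >= dmin - 1e-12 & diag(M) <= dmax + 1e-12))
  }
  # a single reference is returned as-is
  expect_equal(generate_time_matrix(refs[1]), refs[[1]], tolerance = 1e-12)
  expect_error(generate_time_matrix(list()), "at least one")
  expect_error(generate_time_matrix(list(diag(2), diag(3))), "dimension")
})

test_that("evolve_responses follows the time-related matrix", {
  set.seed(54)
  resp <- sample.int(5, 5000, replace = TRUE)
  v <- tabulate(resp, 5) / length(resp)
  # identity matrix leaves responses untouched
  expect_identical(evolve_responses(resp, diag(5)), resp)
  B <- random_stochastic_matrix(5)
  out <- evolve_responses(resp, B)
  emp <- tabulate(out, 5) / length(out)
  expect_lt(linf(emp, as.vector(B %*% v)), 0.03)
  # expected-counts mode is the exact matrix-vector product
  expect_equal(evolve_responses(resp, B, mode = "expected-counts"),
               as.vector(B %*% v), tolerance = 1e-12)
  expect_error(evolve_responses(c(0L, 1L), diag(5)), "dimension")
})

test_that("select_cohort samples without replacement within range", {
  idx <- select_cohort(1000, 400, seed = 55)
  expect_length(idx, 400)
  expect_false(anyDuplicated(idx) > 0)
  expect_true(all(idx >= 1 & idx <= 1000))
  expect_error(select_cohort(100, 101), "exceed")
})

test_that("scenario internals are mutually consistent", {
  sc <- build_scenario(sim_config(n_population = 6000L, n_cohort = 2500L,
                                  n_replicates = 2L, seed = 56L))
  tr <- sc$truth; ob <- sc$observables
  expect_equal(sum(ob$y1), 1)
  # cohort vectors re-derivable from the latent draws and cohort indices
  xs <- tr$x[tr$cohort_idx]
  expect_equal(tr$u1, tabulate(assign_responses(xs, q97), 4) / 2500)
  expect_equal(tr$v1, tabulate(assign_responses(xs, q98), 5) / 2500)
  expect_equal(tr$cohort_mean, mean(xs))
  # each replicate's observed second-time vector is near B1 %*% v1
  for (r in seq_along(ob$replicates)) {
    rep_r <- ob$replicates[[r]]
    expect_lt(linf(rep_r$v_prime, as.vector(tr$B1[[r]] %*% tr$v1)), 0.03)
    expect_s3_class(rep_r$pairs, "paired_responses")
    # T1 spans the revision: target options by source options
    expect_identical(dim(rep_r$T1), c(5L, 4L))
    expect_equal(colSums(rep_r$T1), rep(1, 4), tolerance = 1e-12)
  }
  # the default reference set reproduces the published variability scale
  expect_gt(ob$beta_reference, 0.005)
  expect_lt(ob$beta_reference, 0.1)
})

test_that("expected-counts evolution is deterministic given the matrices", {
  sc <- build_scenario(sim_config(n_population = 4000L, n_cohort = 1500L,
                                  evolution = "expected-counts",
                                  n_replicates = 1L, seed = 57L))
  rep1 <- sc$observables$replicates[[1]]
  expect_null(rep1$pairs)
  expect_equal(rep1$v_prime,
               as.vector(sc$truth$B1[[1]] %*% sc$truth$v1), tolerance = 1e-12)
})
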