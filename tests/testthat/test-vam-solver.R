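test_that("vam_control enforces the proportion-weight ordering", {
  expect_error(vam_control(theta = c(1, 2, 3, 4)), "theta1")
  expect_error(vam_control(theta = c(10, 10, 10, 1)), "theta1")
  expect_error(vam_control(theta = c(10, 10, 1, -1)), "positive")
  expect_silent(vam_control(theta = c(100, 100, 10, 1)))
})

test_that("decomposition recovers an exactly factorable instance", {
  set.seed(31)
  dist <- gamma_spec(1, 3)
  G <- ideal_revision_matrix(dist, q97, q98)
  B_ref <- random_stochastic_matrix(5)
  T1 <- B_ref %*% G
  u <- cell_probabilities(dist, q97)
  vp <- as.vector(T1 %*% u)
  dec <- vam_decompose(T1, u, vp, B_ref, G)
  expect_true(dec$target_met)
  expect_lt(max(dec$slacks), 1e-6)
  expect_lt(linf_matrix(dec$A_hat, G), 1e-6)
  expect_lt(linf_matrix(dec$B_hat, B_ref), 1e-6)
  expect_lt(max(abs(colSums(dec$A_hat) - 1)), 1e-6)
  expect_lt(max(abs(colSums(dec$B_hat) - 1)), 1e-6)
  expect_true(all(dec$A_hat >= -1e-9) && all(dec$B_hat >= -1e-9))
})

test_that("a revision-free instance yields an identity revision factor", {
  set.seed(32)
  T1 <- random_stochastic_matrix(4)
  u <- random_prob_vector(4)
  dec <- vam_decompose(T1, u, as.vector(T1 %*% u), B_ref = T1, G = diag(4))
  expect_lt(linf_matrix(dec$A_hat, diag(4)), 1e-6)
  expect_lt(dec$slacks[["alpha"]], 1e-6)
})

test_that("the alternating objective is non-increasing and slacks are tight", {
  set.seed(33)
  for (i in 1:5) {
    # noisy instance: T perturbed away from an exact factorisation
    G <- ideal_revision_matrix(gamma_spec(runif(1, 0.8, 1.5),
                                          runif(1, 2, 4)), q97, q98)
    B_ref <- random_stochastic_matrix(5)
    T1 <- perturb_transition_matrix(B_ref %*% G, 2000)
    u <- random_prob_vector(4)
    vp <- as.vector(perturb_transition_matrix(cbind(T1 %*% u), 5000))
    # noisy residuals sit above the slack target, which is warned about
    dec <- suppressWarnings(vam_decompose(T1, u, vp, B_ref, G))
    tr <- dec$objective_trace
    expect_true(all(diff(tr) <= 1e-7 * pmax(1, abs(tr[-length(tr)]))))
    # reported slacks equal independently recomputed residuals
    expect_equal(dec$slacks[["gamma"]],
                 linf_matrix(dec$B_hat %*% dec$A_hat, T1))
    expect_equal(dec$slacks[["epsilon"]],
                 max(abs(dec$B_hat %*% dec$A_hat %*% u - vp)))
    expect_equal(dec$slacks[["beta"]], linf_matrix(dec$B_hat, B_ref))
    expect_equal(dec$slacks[["alpha"]], linf_matrix(dec$A_hat, G))
  }
})

test_that("exact factorisations are recovered across many random instances", {
  set.seed(34)
  for (i in 1:25) {
    d1 <- sample(3:4, 1); d2 <- d1 + sample(0:2, 1)
    G <- random_stochastic_matrix(d2, d1)
    B_ref <- random_stochastic_matrix(d2)
    T1 <- B_ref %*% G
    u <- random_prob_vector(d1)
    dec <- vam_decompose(T1, u, as.vector(T1 %*% u), B_ref, G)
    expect_lte(dec$slacks[["gamma"]], 1e-4)
  }
})

test_that("align applies a revision matrix and respects total probability", {
  dist <- gamma_spec(1.3, 2.2)
  G <- ideal_revision_matrix(dist, q97, q98)
  p <- cell_probabilities(dist, q97)
  expect_equal(align(p, G), cell_probabilities(dist, q98), tolerance = 1e-10)
  expect_equal(align(c(0.2, 0.3, 0.5), diag(3)), c(0.2, 0.3, 0.5))
})

test_that("dimension and stochasticity violations are rejected", {
  G <- matrix(0.25, 4, 4)
  expect_error(vam_decompose(diag(4), random_prob_vector(3),
                             random_prob_vector(4), diag(4), G),
               "dimension|length")
  bad <- diag(4); bad[1, 1] <- 0.5
  expect_error(vam_decompose(bad, random_prob_vector(4),
                             random_prob_vector(4), diag(4), G),
               "sum to 1")
})
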