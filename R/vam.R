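#' Control parameters for the VAM decomposition
#'
#' The decomposition minimises `theta1*gamma + theta2*epsilon + theta3*beta +
#' theta4*alpha`, where the slack variables bound, in L-infinity,
#' the factorisation residual `|B A - T|` (gamma), the vector residual
#' `|B A u - v'|` (epsilon), the distance of the time factor from its
#' reference `|B - B_ref|` (beta), and the distance of the revision factor
#' from the ideal revision matrix `|A - G|` (alpha).  The proportion weights
#' must satisfy `theta1 == theta2 > theta3 > theta4 > 0`: the factorisation
#' and vector residuals carry the highest priority because they only absorb
#' estimation noise and the fourth-decimal working precision of probability
#' vectors, while the two similarity assumptions are softer.
#'
#' If the converged solution misses the `slack_target` on gamma or epsilon,
#' `theta1` and `theta2` are escalated by `theta_escalation` (up to
#' `max_escalations` times) and the solve repeats, mirroring the rule that
#' those two slacks take absolute priority.
#'
#' @param theta Length-4 positive weights, `theta1 == theta2 > theta3 >
#'   theta4 > 0`.
#' @param slack_target Target ceiling for the realised gamma and epsilon
#'   slacks (default `1e-4`, the working precision of probability vectors).
#' @param max_alternations Maximum number of alternating solves.
#' @param tol Relative objective-change threshold declaring convergence.
#' @param theta_escalation Multiplier applied to `theta1`, `theta2` when the
#'   slack target is missed.
#' @param max_escalations Cap on escalation rounds.
#' @return A list of class `"vam_control"`.
#' @export
vam_control <- function(theta = c(1e4, 1e4, 1e2, 1),
                        slack_target = 1e-4,
                        max_alternations = 200L,
                        tol = 1e-9,
                        theta_escalation = 10,
                        max_escalations = 5L) {
  theta <- as.numeric(theta)
  if (length(theta) != 4L || any(theta <= 0))
    stop("'theta' must be four positive weights")
  if (!(theta[1L] == theta[2L] && theta[2L] > theta[3L] && theta[3L] > theta[4L]))
    stop("'theta' must satisfy theta1 == theta2 > theta3 > theta4 > 0")
  structure(list(theta = theta, slack_target = slack_target,
                 max_alternations = as.integer(max_alternations), tol = tol,
                 theta_escalation = theta_escalation,
                 max_escalations = as.integer(max_escalations)),
            class = "vam_control")
}

# ---- internal linear programs -------------------------------------------
# Both subproblems of the bilinear product constraint are LPs once one
# factor is fixed.  Variables are the free factor's entries (column-major)
# followed by the active slack variables; everything is >= 0, which
# boot::simplex assumes.  Absolute-value constraints |r| <= s become the
# pair r - s <= 0, -r - s <= 0.

# fix A: solve for B (n x n), slacks gamma, epsilon, beta
.lp_solve_B <- function(A, T1, u, vp, Bref, theta) {
  n <- nrow(T1); m <- ncol(T1)
  nv <- n * n + 3L
  idx <- function(i, k) (k - 1L) * n + i
  obj <- c(rep(0, n * n), theta[1L], theta[2L], theta[3L])
  nr <- 2L * (n * m + n + n * n)
  A1 <- matrix(0, nr, nv); b1 <- numeric(nr); r <- 0L
  put <- function(row, rhs) { r <<- r + 1L; A1[r, ] <<- row; b1[r] <<- rhs }
  for (j in seq_len(m)) for (i in seq_len(n)) {       # |BA - T| <= gamma
    row <- numeric(nv); row[idx(i, seq_len(n))] <- A[, j]; row[n * n + 1L] <- -1
    put(row, T1[i, j])
    row[idx(i, seq_len(n))] <- -A[, j]
    put(row, -T1[i, j])
  }
  w <- as.vector(A %*% u)
  for (i in seq_len(n)) {                             # |B(Au) - v'| <= epsilon
    row <- numeric(nv); row[idx(i, seq_len(n))] <- w; row[n * n + 2L] <- -1
    put(row, vp[i])
    row[idx(i, seq_len(n))] <- -w
    put(row, -vp[i])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {       # |B - Bref| <= beta
    row <- numeric(nv); row[idx(i, k)] <- 1; row[n * n + 3L] <- -1
    put(row, Bref[i, k])
    row[idx(i, k)] <- -1
    put(row, -Bref[i, k])
  }
  A3 <- matrix(0, n, nv)                              # column sums of B
  for (k in seq_len(n)) A3[k, idx(seq_len(n), k)] <- 1
  s <- boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = rep(1, n),
                     n.iter = 100L * (nv + nr))
  if (s$solved < 0)
    stop("time-factor linear program infeasible; inputs are inconsistent")
  matrix(s$soln[seq_len(n * n)], n, n)
}

# fix B: solve for A (n x m), slacks gamma, epsilon, alpha
.lp_solve_A <- function(B, T1, u, vp, G, theta) {
  n <- nrow(T1); m <- ncol(T1)
  nv <- n * m + 3L
  idx <- function(k, j) (j - 1L) * n + k
  obj <- c(rep(0, n * m), theta[1L], theta[2L], theta[4L])
  nr <- 2L * (n * m + n + n * m)
  A1 <- matrix(0, nr, nv); b1 <- numeric(nr); r <- 0L
  put <- function(row, rhs) { r <<- r + 1L; A1[r, ] <<- row; b1[r] <<- rhs }
  for (j in seq_len(m)) for (i in seq_len(n)) {       # |BA - T| <= gamma
    row <- numeric(nv); row[idx(seq_len(n), j)] <- B[i, ]; row[n * m + 1L] <- -1
    put(row, T1[i, j])
    row[idx(seq_len(n), j)] <- -B[i, ]
    put(row, -T1[i, j])
  }
  for (i in seq_len(n)) {                             # |BAu - v'| <= epsilon
    row <- numeric(nv)
    for (j in seq_len(m)) row[idx(seq_len(n), j)] <- B[i, ] * u[j]
    row[n * m + 2L] <- -1
    put(row, vp[i])
    for (j in seq_len(m)) row[idx(seq_len(n), j)] <- -B[i, ] * u[j]
    put(row, -vp[i])
  }
  for (j in seq_len(m)) for (k in seq_len(n)) {       # |A - G| <= alpha
    row <- numeric(nv); row[idx(k, j)] <- 1; row[n * m + 3L] <- -1
    put(row, G[k, j])
    row[idx(k, j)] <- -1
    put(row, -G[k, j])
  }
  A3 <- matrix(0, m, nv)                              # column sums of A
  for (j in seq_len(m)) A3[j, idx(seq_len(n), j)] <- 1
  s <- boot::simplex(a = obj, A1 = A1, b1 = b1, A3 = A3, b3 = rep(1, m),
                     n.iter = 100L * (nv + nr))
  if (s$solved < 0)
    stop("revision-factor linear program infeasible; inputs are inconsistent")
  matrix(s$soln[seq_len(n * m)], n, m)
}

.realized_slacks <- function(A, B, T1, u, vp, Bref, G) {
  c(gamma = linf_matrix(B %*% A, T1),
    epsilon = max(abs(B %*% A %*% u - vp)),
    beta = linf_matrix(B, Bref),
    alpha = linf_matrix(A, G))
}

#' Decompose a revision-spanning transition matrix
#'
#' Splits the cohort transition matrix `T` observed across a questionnaire
#' revision into a revision-related factor `A` (applied first) and a
#' time-related factor `B`, i.e. `T ~ B %*% A`, by minimising the weighted
#' slack objective described in [vam_control()].  The product constraint is
#' bilinear, so the problem is solved by alternating linear programs: with
#' `A` fixed the minimisation over `(B, gamma, epsilon, beta)` is an LP, and
#' with `B` fixed the minimisation over `(A, gamma, epsilon, alpha)` is an
#' LP.  Each subproblem contains the previous iterate as a feasible point,
#' so the realised objective is non-increasing across alternations.
#' Iteration starts from `A = G` and stops at relative objective change
#' below `control$tol` or `control$max_alternations`.  All entries of both
#' factors are constrained non-negative and every column sums to 1.
#'
#' @param T1 Cohort transition matrix spanning the revision
#'   (`d_to` x `d_from`), column-stochastic.
#' @param u Cohort probability vector on the source scale at the first time.
#' @param v_prime Cohort probability vector on the target scale at the
#'   second time.
#' @param B_ref Reference time-related matrix (`d_to` x `d_to`), e.g. the
#'   cohort transition matrix of the first post-revision year pair.
#' @param G Ideal revision matrix from [ideal_revision_matrix()].
#' @param control A [vam_control()] list.
#' @param input_tol Column-sum tolerance applied when validating the inputs;
#'   printed 3-significant-digit matrices need a looser value.
#' @return An object of class `"vam_decomposition"`: list with `A_hat`,
#'   `B_hat`, `slacks` (realised `gamma`, `epsilon`, `beta`, `alpha`),
#'   `objective`, `objective_trace`, `iterations`, `converged`,
#'   `target_met`, `theta` (weights after any escalation) and
#'   `escalations`.
#' @examples
#' G <- ideal_revision_matrix(gamma_spec(1, 3), ltpa_scale_1997(),
#'                            ltpa_scale_1998())
#' B <- diag(5)
#' u <- cell_probabilities(gamma_spec(1, 3), ltpa_scale_1997())
#' dec <- vam_decompose(B %*% G, u, as.vector(B %*% G %*% u), B, G)
#' dec$slacks
#' @export
vam_decompose <- function(T1, u, v_prime, B_ref, G,
                          control = vam_control(), input_tol = 1e-4) {
  T1 <- check_transition_matrix(T1, tol = input_tol)
  B_ref <- check_transition_matrix(B_ref, tol = input_tol)
  G <- check_transition_matrix(G, tol = input_tol)
  u <- check_prob_vector(u, tol = input_tol)
  v_prime <- check_prob_vector(v_prime, tol = input_tol)
  n <- nrow(T1); m <- ncol(T1)
  if (length(u) != m || length(v_prime) != n ||
      !all(dim(B_ref) == c(n, n)) || !all(dim(G) == c(n, m)))
    stop("dimension mismatch among T1, u, v_prime, B_ref, G")

  theta <- control$theta
  escal <- 0L
  A <- G
  repeat {
    trace <- numeric(0)
    obj_prev <- Inf
    converged <- FALSE
    for (it in seq_len(control$max_alternations)) {
      B <- .lp_solve_B(A, T1, u, v_prime, B_ref, theta)
      A <- .lp_solve_A(B, T1, u, v_prime, G, theta)
      sl <- .realized_slacks(A, B, T1, u, v_prime, B_ref, G)
      obj <- sum(theta * sl)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          (obj_prev - obj) < control$tol * max(1, abs(obj_prev))) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
    target_met <- sl[["gamma"]] <= control$slack_target &&
      sl[["epsilon"]] <= control$slack_target
    if (target_met || escal >= control$max_escalations) break
    escal <- escal + 1L
    theta[1:2] <- theta[1:2] * control$theta_escalation
  }
  if (!target_met)
    warning(sprintf(
      "slack target %g not met after %d theta escalations (gamma = %.3g, epsilon = %.3g)",
      control$slack_target, escal, sl[["gamma"]], sl[["epsilon"]]))
  structure(list(A_hat = A, B_hat = B, slacks = sl, objective = obj,
                 objective_trace = trace, iterations = it,
                 converged = converged, target_met = target_met,
                 theta = theta, escalations = escal),
            class = "vam_decomposition")
}

#' @export
print.vam_decomposition <- function(x, ...) {
  cat("VAM transition-matrix decomposition (T ~ B %*% A)\n")
  cat("  dimensions: A ", nrow(x$A_hat), "x", ncol(x$A_hat),
      ", B ", nrow(x$B_hat), "x", ncol(x$B_hat), "\n", sep = "")
  cat("  realised slacks: gamma =", signif(x$slacks[["gamma"]], 3),
      ", epsilon =", signif(x$slacks[["epsilon"]], 3),
      ", beta =", signif(x$slacks[["beta"]], 3),
      ", alpha =", signif(x$slacks[["alpha"]], 3), "\n")
  cat("  alternations:", x$iterations,
      if (x$converged) "(converged)" else "(iteration cap)",
      " theta escalations:", x$escalations,
      " slack target met:", x$target_met, "\n")
  invisible(x)
}

#' Align a probability vector to another questionnaire version
#'
#' Applies a revision matrix to a probability vector observed under the
#' source version, returning the estimated distribution the same
#' respondents would have produced under the target version.  Numerically
#' this is [apply_transition()]; semantically it rests on the assumption
#' that population and cohort react to the revision identically, so a
#' cohort-estimated revision factor may be applied to the population vector.
#'
#' @param p Probability vector on the source scale.
#' @param A Revision matrix (`d_to` x `d_from`), e.g. `A_hat` from
#'   [vam_decompose()].
#' @return Probability vector on the target scale.
#' @export
align <- function(p, A) {
  A <- check_transition_matrix(A, tol = 1e-2)
  apply_transition(A, p)
}

#' Version Alignment Method: fit the full pipeline
#'
#' The one-stop fit for a survey whose questionnaire changed between two
#' consecutive observation times.  Given the population's pre-revision
#' probability vector, the paired cohort responses spanning the revision,
#' and a post-revision reference for the time-related transition matrix, it
#'
#' 1. fits the latent distribution to the cohort's pre-revision counts by
#'    grouped MLE,
#' 2. builds the ideal revision matrix `G` between the two scales,
#' 3. estimates the cohort transition matrix `T` from the paired responses,
#' 4. decomposes `T ~ B %*% A` with [vam_decompose()], and
#' 5. aligns the population and cohort vectors to the target version and
#'    estimates their means by both the midpoint method and grouped MLE.
#'
#' @param y Population probability vector (or counts) on the source scale at
#'   the pre-revision time.
#' @param pairs A [paired_responses()] cohort spanning the revision.
#' @param B_ref Reference time-related matrix on the target scale.
#' @param family Latent distribution family (default `"gamma"`).
#' @param control A [vam_control()] list.
#' @param beta_reference Optional scalar: an external reference for how far
#'   apart consecutive time-related matrices tend to be (e.g. the average
#'   L-infinity among post-revision cohort matrices).  Reported alongside
#'   the realised beta slack for diagnosis; not used by the solver.
#' @param input_tol Passed to [vam_decompose()].
#' @return An object of class `"vam"` with components `z` and `v` (aligned
#'   population and cohort vectors on the target scale), `A_hat`, `B_hat`,
#'   `decomposition`, `latent_fit` (the cohort [fit_grouped_mle()]), `G`,
#'   `estimates` (means of `z` and `v` by midpoint and MLE), `u`, `y`,
#'   `scales` and `beta_reference`.
#' @seealso [vam_decompose()], [align()], [build_scenario()] for simulated
#'   inputs with ground truth.
#' @export
vam <- function(y, pairs, B_ref, family = "gamma",
                control = vam_control(), beta_reference = NULL,
                input_tol = 1e-4) {
  stopifnot(inherits(pairs, "paired_responses"))
  scale_from <- pairs$scale_from
  scale_to <- pairs$scale_to
  if (length(y) != n_options(scale_from))
    stop("'y' does not match the cohort's source scale")
  y <- counts_to_prob(y)

  u_counts <- tabulate(pairs$from, nbins = n_options(scale_from))
  u <- counts_to_prob(u_counts)
  v_prime <- counts_to_prob(tabulate(pairs$to, nbins = n_options(scale_to)))

  latent_fit <- fit_grouped_mle(u_counts, scale_from, family = family)
  G <- ideal_revision_matrix(latent_fit$dist, scale_from, scale_to)
  T1 <- estimate_transition_matrix(pairs)
  dec <- vam_decompose(T1, u, v_prime, B_ref, G, control = control,
                       input_tol = input_tol)

  z <- align(y, dec$A_hat)
  v <- align(u, dec$A_hat)
  z_fit <- fit_grouped_mle(z, scale_to, family = family)
  v_fit <- fit_grouped_mle(v, scale_to, family = family)
  est <- data.frame(
    vector = c("population", "population", "cohort", "cohort"),
    method = c("midpoint", "mle", "midpoint", "mle"),
    mean = c(midpoint_mean(z, scale_to), z_fit$mean,
             midpoint_mean(v, scale_to), v_fit$mean))

  structure(list(z = z, v = v, A_hat = dec$A_hat, B_hat = dec$B_hat,
                 decomposition = dec, latent_fit = latent_fit, G = G,
                 T1 = T1, u = u, v_prime = v_prime, y = y,
                 estimates = est, population_fit = z_fit, cohort_fit = v_fit,
                 scales = list(from = scale_from, to = scale_to),
                 beta_reference = beta_reference),
            class = "vam")
}

#' @export
print.vam <- function(x, ...) {
  cat("Version Alignment Method fit: ",
      x$scales$from$version_id, " -> ", x$scales$to$version_id, "\n", sep = "")
  cat("  latent fit (cohort, pre-revision): ", x$latent_fit$dist$family, "(",
      paste(signif(unlist(x$latent_fit$dist$params), 4), collapse = ", "),
      "), mean ", signif(x$latent_fit$mean, 5), "\n", sep = "")
  cat("  aligned population vector z:", paste(round(x$z, 4), collapse = " "),
      "\n")
  cat("  mean estimates on the target version:\n")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' @export
coef.vam <- function(object, ...) {
  stats::setNames(object$estimates$mean,
                  paste(object$estimates$vector, object$estimates$method,
                        sep = "_"))
}

#' @export
summary.vam <- function(object, ...) {
  dec <- object$decomposition
  out <- list(fit = object, slacks = dec$slacks,
              beta_reference = object$beta_reference,
              target_met = dec$target_met, iterations = dec$iterations,
              escalations = dec$escalations)
  class(out) <- "summary.vam"
  out
}

#' @export
print.summary.vam <- function(x, ...) {
  print(x$fit)
  cat("  decomposition slacks: gamma =", signif(x$slacks[["gamma"]], 3),
      ", epsilon =", signif(x$slacks[["epsilon"]], 3),
      ", beta =", signif(x$slacks[["beta"]], 3),
      ", alpha =", signif(x$slacks[["alpha"]], 3), "\n")
  if (!is.null(x$beta_reference))
    cat("  external beta reference:", signif(x$beta_reference, 3),
        "(realised beta", if (x$slacks[["beta"]] <= x$beta_reference)
          "within" else "beyond", "it)\n")
  cat("  alternations:", x$iterations, " escalations:", x$escalations,
      " slack target met:", x$target_met, "\n")
  invisible(x)
}
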