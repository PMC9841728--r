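#' Ideal revision matrix between two interval scales
#'
#' Under the ideal survey response model a respondent's option on either
#' questionnaire version is a deterministic function of the same latent
#' answer `x`.  Given a latent distribution, the transition from source
#' option `j` to target option `i` induced purely by the version change is
#' the conditional probability
#' `G[i, j] = P(x in I2_i | x in I1_j) = Phi(I2_i intersect I1_j) / Phi(I1_j)`,
#' where `Phi` is the latent probability mass of an interval.  Columns sum to
#' 1 by construction; empty intersections contribute exactly 0, so a source
#' interval nested inside one target interval yields a unit column.  This
#' matrix is the reference the VAM solver pulls the estimated revision
#' factor towards.
#'
#' @param dist A [dist_spec()] for the latent answer (typically fitted to the
#'   cohort's pre-revision responses with [fit_grouped_mle()]).
#' @param scale_from,scale_to Contiguous [interval_scale()]s (smooth raw
#'   scales with [smooth_gaps()] first, which encodes the nearest-interval
#'   response assumption).
#' @return A column-stochastic matrix with `n_options(scale_to)` rows and
#'   `n_options(scale_from)` columns.
#' @examples
#' G <- ideal_revision_matrix(gamma_spec(0.801, 2.028),
#'                            ltpa_scale_1997(), ltpa_scale_1998())
#' colSums(G)  # all 1
#' @export
ideal_revision_matrix <- function(dist, scale_from, scale_to) {
  stopifnot(inherits(dist, "dist_spec"),
            inherits(scale_from, "interval_scale"),
            inherits(scale_to, "interval_scale"))
  if (!is_contiguous(scale_from) || !is_contiguous(scale_to))
    stop("both scales must be contiguous on [0, Inf); apply smooth_gaps() first")
  d1 <- n_options(scale_from)
  d2 <- n_options(scale_to)
  src_mass <- vapply(seq_len(d1), function(j)
    interval_probability(dist, scale_from$lb[j], scale_from$ub[j]), 0)
  if (any(src_mass <= 0))
    stop("zero-mass source column: the latent distribution places no mass on ",
         "source interval(s) ", paste(which(src_mass <= 0), collapse = ", "))
  G <- matrix(0, d2, d1)
  for (j in seq_len(d1)) {
    for (i in seq_len(d2)) {
      lo <- max(scale_from$lb[j], scale_to$lb[i])
      hi <- min(scale_from$ub[j], scale_to$ub[i])
      G[i, j] <- interval_probability(dist, lo, hi) / src_mass[j]
    }
    # guard against CDF round-off: renormalise the tiny residual
    G[, j] <- G[, j] / sum(G[, j])
  }
  G
}
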