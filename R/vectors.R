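#' Probability vectors and transition matrices over interval scales
#'
#' Grouped responses at one time point are summarised by a count vector
#' (observations per option) or a probability vector (relative frequencies,
#' i.e. a discrete distribution over the options).  Transitions between two
#' time points are summarised by a column-stochastic matrix whose `(i, j)`
#' entry is the probability of moving from option `j` to option `i`.
#' These helpers validate and convert between the three representations;
#' vectors and matrices themselves stay plain base-R numerics so that the
#' usual linear algebra applies.
#'
#' @name grouped-containers
NULL

#' Convert counts to a probability vector
#'
#' @param counts Non-negative integer vector of observations per option.
#' @return Numeric vector of relative frequencies summing to 1.
#' @examples
#' counts_to_prob(c(10, 30, 60))
#' @export
counts_to_prob <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  n <- sum(counts)
  if (n <= 0)
    stop("empty sample: total count is zero")
  counts / n
}

#' Validate a probability vector
#'
#' @param p Numeric vector.
#' @param tol Tolerance on `sum(p) == 1`.  Published tables round
#'   probabilities to a few decimals, so the default matches that working
#'   precision rather than machine precision.
#' @return `p`, invisibly normalised metadata-free; an error if invalid.
#' @export
check_prob_vector <- function(p, tol = 1e-4) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("probability vector entries must lie in [0, 1]")
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("probability vector sums to %.6f, not 1 (tol %g)", sum(p), tol))
  p
}

#' Validate a column-stochastic transition matrix
#'
#' @param M Numeric matrix, target options in rows, source options in columns.
#' @param tol Tolerance on each column sum; printed matrices rounded to three
#'   significant digits need a looser tolerance than freshly estimated ones.
#' @return `M`, or an error if entries fall outside `[0, 1]` or a column sum
#'   misses 1 by more than `tol`.
#' @export
check_transition_matrix <- function(M, tol = 1e-4) {
  M <- as.matrix(M)
  if (anyNA(M) || any(M < -1e-12) || any(M > 1 + 1e-12))
    stop("transition matrix entries must lie in [0, 1]")
  cs <- colSums(M)
  if (any(abs(cs - 1) > tol))
    stop(sprintf("transition matrix columns must sum to 1 (max deviation %.2e, tol %g)",
                 max(abs(cs - 1)), tol))
  M
}

#' L-infinity distance between probability vectors
#'
#' The maximum absolute difference between corresponding relative
#' frequencies.  A metric on probability vectors of equal dimension, bounded
#' by 1.
#'
#' @param p,q Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @examples
#' linf(c(0.5, 0.3, 0.2), c(0.4, 0.4, 0.2))  # 0.1
#' @export
linf <- function(p, q) {
  if (length(p) != length(q))
    stop("incompatible scales: vectors have different dimensions")
  max(abs(as.numeric(p) - as.numeric(q)))
}

#' L-infinity distance between transition matrices
#'
#' Defined column-wise as the maximum [linf()] over every pair of
#' corresponding columns, which equals the element-wise maximum absolute
#' difference.
#'
#' @param M,N Matrices of identical dimension.
#' @return Non-negative scalar.
#' @export
linf_matrix <- function(M, N) {
  M <- as.matrix(M); N <- as.matrix(N)
  if (!all(dim(M) == dim(N)))
    stop("incompatible matrices: dimensions differ")
  max(abs(M - N))
}

#' Kullback-Leibler divergence between probability vectors
#'
#' `sum(p * log(p / q))` in natural log with the convention `0 * log(0) = 0`.
#' When `q` has a zero cell where `p` is positive the divergence is
#' undefined; `NA_real_` is returned as an explicit sentinel (no `NaN`
#' arithmetic is performed).
#'
#' @param p,q Numeric probability vectors of equal length.
#' @return Non-negative scalar, or `NA_real_` when undefined.
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))  # 0.5*log(2) + 0.5*log(2/3)
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q))
    stop("incompatible scales: vectors have different dimensions")
  p <- as.numeric(p); q <- as.numeric(q)
  if (any(q == 0 & p > 0))
    return(NA_real_)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Paired cohort responses at two consecutive times
#'
#' A cohort is the set of individuals observed at both of two consecutive
#' time points; their paired responses identify the transition matrix
#' directly.  The two time points may use different questionnaire versions
#' (that is the revision-spanning case VAM needs).
#'
#' @param id Vector of unique individual identifiers.
#' @param from Integer option index at the first time, on `scale_from`.
#' @param to Integer option index at the second time, on `scale_to`.
#' @param scale_from,scale_to [interval_scale()] objects.
#' @return An object of class `"paired_responses"`.
#' @export
paired_responses <- function(id, from, to, scale_from, scale_to) {
  stopifnot(inherits(scale_from, "interval_scale"),
            inherits(scale_to, "interval_scale"))
  if (anyDuplicated(id))
    stop("individual ids must be unique")
  n <- length(id)
  if (length(from) != n || length(to) != n || n == 0L)
    stop("'id', 'from', 'to' must be non-empty and of equal length")
  from <- as.integer(from); to <- as.integer(to)
  if (anyNA(from) || any(from < 1L) || any(from > n_options(scale_from)))
    stop("'from' indices outside the source scale's option range")
  if (anyNA(to) || any(to < 1L) || any(to > n_options(scale_to)))
    stop("'to' indices outside the target scale's option range")
  structure(list(id = id, from = from, to = to,
                 scale_from = scale_from, scale_to = scale_to),
            class = "paired_responses")
}

#' @export
print.paired_responses <- function(x, ...) {
  cat("Paired cohort responses: ", length(x$id), " individuals, ",
      x$scale_from$version_id, " -> ", x$scale_to$version_id, "\n", sep = "")
  invisible(x)
}

#' Estimate a transition matrix from paired cohort responses
#'
#' Entry `(i, j)` is the fraction of individuals who chose option `j` at the
#' first time and option `i` at the second, among those who chose `j` first;
#' columns therefore sum to 1 exactly.  A source option never observed at the
#' first time leaves its column undefined: the default is an error, or choose
#' a fill policy.
#'
#' @param pairs A [paired_responses()] object.
#' @param empty_column One of `"error"` (default), `"uniform"` (fill with
#'   `1/d`), or `"identity"` (unit column at the same index; requires equal
#'   dimensions).  A non-default fill is reported with a message.
#' @return A column-stochastic matrix, `d_to` rows by `d_from` columns.
#' @export
estimate_transition_matrix <- function(pairs,
                                       empty_column = c("error", "uniform",
                                                        "identity")) {
  stopifnot(inherits(pairs, "paired_responses"))
  empty_column <- match.arg(empty_column)
  d1 <- n_options(pairs$scale_from)
  d2 <- n_options(pairs$scale_to)
  tab <- table(factor(pairs$to, levels = seq_len(d2)),
               factor(pairs$from, levels = seq_len(d1)))
  counts <- matrix(as.numeric(tab), d2, d1)
  src <- colSums(counts)
  if (any(src == 0)) {
    j <- which(src == 0)
    if (empty_column == "error")
      stop("no cohort observations for source option(s) ",
           paste(j, collapse = ", "),
           "; choose an explicit empty_column policy to fill them")
    message("filling empty source column(s) ", paste(j, collapse = ", "),
            " with policy '", empty_column, "'")
    if (empty_column == "identity" && d1 != d2)
      stop("'identity' fill needs equal source and target dimensions")
    for (k in j) {
      counts[, k] <- if (empty_column == "uniform") 1 / d2 else 0
      if (empty_column == "identity") counts[k, k] <- 1
    }
    src <- colSums(counts)
  }
  sweep(counts, 2, src, "/")
}

#' Push a probability vector through a transition matrix
#'
#' The matrix-vector product `T %*% p`: the distribution over target options
#' implied by source distribution `p` and the transition law `T`.  Total
#' probability is preserved for column-stochastic `T`.
#'
#' @param T_mat Column-stochastic matrix (`d_to` x `d_from`).
#' @param p Probability vector of length `d_from`.
#' @return Probability vector of length `d_to`.
#' @export
apply_transition <- function(T_mat, p) {
  T_mat <- as.matrix(T_mat)
  if (ncol(T_mat) != length(p))
    stop("incompatible scales: matrix has ", ncol(T_mat),
         " source options but vector has length ", length(p))
  as.vector(T_mat %*% as.numeric(p))
}
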