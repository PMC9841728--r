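#' Bootstrap confidence interval for distances between probability vectors
#'
#' How far apart can two probability vectors be when both are relative
#' frequencies of finite samples from the *same* distribution?  Two
#' independent groups of `n_vectors` probability vectors are generated, each
#' the relative frequencies of `n` multinomial draws from the latent
#' distribution binned by the scale; all `n_vectors^2` cross-group pairwise
#' distances are computed and the central 95% interval (2.5th and 97.5th
#' percentiles, linear interpolation between order statistics) is returned.
#' An estimation error falling inside this interval is indistinguishable
#' from pure sampling noise.  For the KL metric, pairs whose divergence is
#' undefined (a zero cell in the reference where the other is positive) are
#' excluded and counted.
#'
#' @param dist A [dist_spec()].
#' @param scale A contiguous [interval_scale()].
#' @param n Multinomial sample size behind each probability vector.
#' @param n_vectors Vectors per group (default 1000, giving `1e6` distances).
#' @param metric `"linf"` or `"kl"`.
#' @param seed Optional integer seed.
#' @param dist2 Optional second [dist_spec()] for the second group, to
#'   measure the effect of a parameter drift; defaults to `dist`.
#' @return A list of class `"distance_ci"`: `lo`, `hi`, `metric`, `n`,
#'   `n_vectors`, `n_undefined`.
#' @examples
#' \donttest{
#' bootstrap_distance_ci(gamma_spec(1, 3), ltpa_scale_1998(),
#'                       n = 20000, n_vectors = 200, seed = 1)
#' }
#' @export
bootstrap_distance_ci <- function(dist, scale, n, n_vectors = 1000L,
                                  metric = c("linf", "kl"), seed = NULL,
                                  dist2 = NULL) {
  metric <- match.arg(metric)
  stopifnot(n >= 1, n_vectors >= 2)
  if (!is.null(seed)) set.seed(seed)
  p1 <- cell_probabilities(dist, scale)
  p2 <- if (is.null(dist2)) p1 else cell_probabilities(dist2, scale)
  d <- length(p1)
  g1 <- stats::rmultinom(n_vectors, n, p1) / n
  g2 <- stats::rmultinom(n_vectors, n, p2) / n
  n_undef <- 0L
  if (metric == "linf") {
    D <- matrix(0, n_vectors, n_vectors)
    for (k in seq_len(d))
      D <- pmax(D, abs(outer(g1[k, ], g2[k, ], "-")))
    vals <- as.vector(D)
  } else {
    # KL(p || q) across groups, term-wise over cells; undefined pairs out
    D <- matrix(0, n_vectors, n_vectors)
    undef <- matrix(FALSE, n_vectors, n_vectors)
    for (k in seq_len(d)) {
      pk <- g1[k, ]; qk <- g2[k, ]
      undef <- undef | outer(pk > 0, qk == 0, "&")
      term <- outer(pk, qk, function(p, q) ifelse(p > 0 & q > 0,
                                                  p * log(p / q), 0))
      D <- D + term
    }
    n_undef <- sum(undef)
    vals <- D[!undef]
  }
  qs <- stats::quantile(vals, c(0.025, 0.975), names = FALSE, type = 7)
  structure(list(lo = qs[1L], hi = qs[2L], metric = metric, n = n,
                 n_vectors = n_vectors, n_undefined = n_undef),
            class = "distance_ci")
}

#' @export
print.distance_ci <- function(x, ...) {
  cat("95% bootstrap interval of ", x$metric, " distances (n = ", x$n,
      ", ", x$n_vectors, " vectors/group): [",
      signif(x$lo, 3), ", ", signif(x$hi, 3), "]\n", sep = "")
  if (x$n_undefined > 0)
    cat("  (", x$n_undefined, " undefined pairs excluded)\n", sep = "")
  invisible(x)
}

#' Linear trend of annual estimates
#'
#' Ordinary least squares of annual values on calendar year, with a
#' prediction at a target year.  Used to sanity-check an aligned
#' pre-revision estimate against the trend of the revision-free years.
#'
#' @param years Numeric years (at least 3, distinct).
#' @param values Annual estimates, same length.
#' @param target_year Year at which to predict.
#' @return A list of class `"trend_fit"`: `slope`, `intercept`,
#'   `r_squared`, `prediction`, `target_year`, and the underlying `lm`
#'   object as `model`.
#' @examples
#' fx <- mj_summaries()
#' post <- fx$annual_means[fx$annual_means$year >= 1998, ]
#' trend_regression(post$year, post$mle, 1997)
#' @export
trend_regression <- function(years, values, target_year) {
  years <- as.numeric(years); values <- as.numeric(values)
  if (length(years) < 3L || length(values) != length(years))
    stop("need at least 3 (year, value) pairs of equal length")
  if (length(unique(years)) != length(years) || stats::var(years) == 0)
    stop("years must be distinct and non-constant")
  fit <- stats::lm(values ~ years)
  pred <- unname(stats::predict(fit, data.frame(years = target_year)))
  # perfect fits make summary.lm warn; the R^2 itself is still well-defined
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 1  # constant values: the flat line is exact
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 prediction = pred, target_year = target_year,
                 model = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Linear trend: slope ", signif(x$slope, 5), "/year, R^2 ",
      signif(x$r_squared, 3), "; prediction at ", x$target_year, ": ",
      signif(x$prediction, 6), "\n", sep = "")
  invisible(x)
}

#' Estimation-error report for an aligned probability vector
#'
#' Reports the L-infinity and KL distances between an estimated and a true
#' probability vector, optionally flagging whether each lies inside a
#' same-distribution bootstrap interval from [bootstrap_distance_ci()]
#' (inside, or below its lower endpoint, means the error is consistent with
#' sampling noise alone).
#'
#' @param estimate,truth Probability vectors of equal length.
#' @param ci_linf,ci_kl Optional `"distance_ci"` objects for the two
#'   metrics.
#' @return Named list with `linf`, `kl` (possibly `NA` if undefined) and,
#'   when intervals are supplied, `linf_within_ci` / `kl_within_ci`.
#' @export
estimation_error_report <- function(estimate, truth,
                                    ci_linf = NULL, ci_kl = NULL) {
  out <- list(linf = linf(estimate, truth),
              kl = kl_divergence(estimate, truth))
  if (!is.null(ci_linf))
    out$linf_within_ci <- out$linf <= ci_linf$hi
  if (!is.null(ci_kl))
    out$kl_within_ci <- if (is.na(out$kl)) NA else out$kl <= ci_kl$hi
  out
}
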