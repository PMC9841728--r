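#' Interval scales for grouped survey responses
#'
#' An interval scale is the numeric side of a closed-ended "grouped data"
#' question: an ordered set of half-open intervals `[lb, ub)`, one per response
#' option, with the top interval usually unbounded (`ub = Inf`).  A respondent
#' whose latent answer is `x` picks the option whose interval contains `x`
#' (membership rule `lb <= x < ub`).
#'
#' @param lb,ub Numeric vectors of lower and upper bounds, one entry per
#'   option.  Bounds must satisfy `lb < ub` and intervals must be pairwise
#'   disjoint and strictly increasing.  `ub` may end in `Inf`.
#' @param version_id Character identifier for the questionnaire version.
#' @param labels Optional character vector of option wordings.
#' @return An object of class `"interval_scale"`: a list with elements
#'   `version_id`, `lb`, `ub`, `labels`.
#' @examples
#' interval_scale(c(0, 1, 2, 3), c(1, 2, 3, Inf), "Q1997")
#' @export
interval_scale <- function(lb, ub, version_id = "scale", labels = NULL) {
  lb <- as.numeric(lb)
  ub <- as.numeric(ub)
  if (length(lb) != length(ub) || length(lb) == 0L)
    stop("'lb' and 'ub' must be non-empty vectors of equal length")
  if (anyNA(lb) || anyNA(ub))
    stop("interval bounds must not be NA")
  if (any(lb < 0))
    stop("interval lower bounds must be >= 0")
  if (any(!is.finite(lb)))
    stop("interval lower bounds must be finite")
  if (any(lb >= ub))
    stop("each interval must satisfy lb < ub")
  if (length(lb) > 1L && any(ub[-length(ub)] > lb[-1L] + 1e-12))
    stop("intervals overlap or are out of order")
  if (!is.null(labels) && length(labels) != length(lb))
    stop("'labels' must have one entry per interval")
  structure(
    list(version_id = as.character(version_id), lb = lb, ub = ub,
         labels = labels),
    class = "interval_scale")
}

#' @export
print.interval_scale <- function(x, ...) {
  d <- n_options(x)
  cat("Interval scale '", x$version_id, "' (", d, " options)\n", sep = "")
  iv <- paste0("[", format(x$lb, trim = TRUE), ", ",
               ifelse(is.finite(x$ub), format(x$ub, trim = TRUE), "Inf"), ")")
  lab <- if (is.null(x$labels)) rep("", d) else paste0("  ", x$labels)
  cat(paste0("  ", seq_len(d), ": ", iv, lab, collapse = "\n"), "\n")
  invisible(x)
}

#' Number of response options of a scale
#' @param scale An [interval_scale()].
#' @return Integer option count.
#' @export
n_options <- function(scale) {
  stopifnot(inherits(scale, "interval_scale"))
  length(scale$lb)
}

#' Is a scale contiguous on `[0, Inf)`?
#'
#' Contiguous means the first lower bound is 0, consecutive intervals share
#' their endpoint (`ub[i] == lb[i + 1]`), and the last upper bound is `Inf`.
#' Operations that treat the scale as a partition of the latent support
#' (binning, cell probabilities, ideal revision matrices) require this.
#'
#' @param scale An [interval_scale()].
#' @return Logical scalar.
#' @export
is_contiguous <- function(scale) {
  stopifnot(inherits(scale, "interval_scale"))
  d <- n_options(scale)
  scale$lb[1L] == 0 && !is.finite(scale$ub[d]) &&
    (d == 1L || isTRUE(all.equal(scale$ub[-d], scale$lb[-1L], tolerance = 1e-12)))
}

#' Smooth the gaps of a discontinuous scale
#'
#' Questionnaire options sometimes leave numeric gaps (e.g. "1 to 2 hours"
#' followed by "3 to 4 hours" leaves `(2, 3)` uncovered).  Under the
#' nearest-interval response assumption a respondent whose answer falls in a
#' gap picks the closest option, so each gap is split at its midpoint: the
#' lower interval's upper bound is extended to the midpoint and the upper
#' interval's lower bound pulled down to it.  Option count and ordering are
#' preserved and every original interval is a subset of its smoothed version.
#' The operation is idempotent.
#'
#' @param scale An [interval_scale()] with disjoint, ordered intervals.
#' @return A contiguous-between-options [interval_scale()] (the first lower
#'   bound and last upper bound are left as given).
#' @examples
#' raw <- interval_scale(c(0, 1, 3, 5, 7), c(1, 2, 4, 6, Inf), "Q1998-raw")
#' smooth_gaps(raw)  # gaps split at 2.5, 4.5, 6.5
#' @export
smooth_gaps <- function(scale) {
  stopifnot(inherits(scale, "interval_scale"))
  lb <- scale$lb
  ub <- scale$ub
  d <- length(lb)
  if (d > 1L) {
    mid <- (ub[-d] + lb[-1L]) / 2
    ub[-d] <- mid
    lb[-1L] <- mid
  }
  interval_scale(lb, ub, version_id = scale$version_id, labels = scale$labels)
}

#' Interval midpoints with the top-coded convention
#'
#' For mean estimation by the midpoint method each finite interval `[a, b)`
#' contributes its midpoint `(a + b) / 2`; the top-coded interval `[a, Inf)`
#' has no midpoint and its lower bound `a` is used instead (which is why the
#' midpoint method systematically underestimates heavy-tailed quantities).
#'
#' @param scale A contiguous [interval_scale()] (pass raw scales through
#'   [smooth_gaps()] first).
#' @return Numeric vector of representative values, one per option.
#' @examples
#' interval_midpoints(ltpa_scale_1997())  # 0.5 1.5 2.5 3.0
#' @export
interval_midpoints <- function(scale) {
  stopifnot(inherits(scale, "interval_scale"))
  d <- n_options(scale)
  if (d > 1L && any(!is.finite(scale$ub[-d])))
    stop("only the top interval may have an infinite upper bound")
  ifelse(is.finite(scale$ub), (scale$lb + scale$ub) / 2, scale$lb)
}

#' The 1997 and 1998 LTPA weekly-duration scales
#'
#' The MJ health-screening questionnaire asked for weekly leisure-time
#' physical activity (LTPA) duration in hours/week as a grouped-data item.
#' The 1997 version had four options with intervals
#' `{[0,1), [1,2), [2,3), [3,Inf)}`.  The 1998 revision had five options
#' whose printed intervals are discontinuous; after gap smoothing they are
#' `{[0,1), [1,2.5), [2.5,4.5), [4.5,6.5), [6.5,Inf)}`.
#'
#' @param smoothed For the 1998 scale, return the gap-smoothed version
#'   (default) or the raw discontinuous option intervals.
#' @return An [interval_scale()].
#' @export
ltpa_scale_1997 <- function() {
  interval_scale(c(0, 1, 2, 3), c(1, 2, 3, Inf), "Q1997",
                 labels = c("<1 h/week", "1-2 h/week", "2-3 h/week",
                            ">3 h/week"))
}

#' @rdname ltpa_scale_1997
#' @export
ltpa_scale_1998 <- function(smoothed = TRUE) {
  raw <- interval_scale(c(0, 1, 3, 5, 7), c(1, 2, 4, 6, Inf), "Q1998",
                        labels = c("<1 h/week", "1-2 h/week", "3-4 h/week",
                                   "5-6 h/week", ">7 h/week"))
  if (smoothed) smooth_gaps(raw) else raw
}

# internal: check two scales refer to the same option structure
same_scale_dim <- function(a, b) n_options(a) == n_options(b)
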