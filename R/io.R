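#' Read and write interval scales, vectors and matrices
#'
#' Plain-text interchange for the package's objects: scales as JSON or YAML
#' (by file extension), matrices and vectors as headerless CSV, aggregated
#' counts as `option,count` CSV, and paired cohort responses as
#' `id,t1_option,t2_option` CSV.  An unbounded upper limit is written as
#' the token `"inf"`.  Writers round probabilities to 5 decimals by
#' default, matching the reporting convention of published tables; pass
#' `digits = NA` for full precision.
#'
#' @name vamalign-io
NULL

#' @rdname vamalign-io
#' @param path File path; `.json`, `.yaml`/`.yml` for scales, `.csv`
#'   otherwise.
#' @return `read_scale()`: an [interval_scale()].
#' @export
read_scale <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- switch(ext,
                json = jsonlite::fromJSON(path, simplifyVector = TRUE),
                yaml = , yml = yaml::read_yaml(path),
                stop("unsupported scale file extension '.", ext, "'"))
  iv <- obj$intervals
  if (is.data.frame(iv)) {
    lb <- iv$lb; ub_raw <- as.list(iv$ub); labels <- iv$labels
  } else {
    # YAML stores one mapping per interval
    lb <- vapply(iv, function(r) as.numeric(r$lb), 0)
    ub_raw <- lapply(iv, `[[`, "ub")
    labels <- if (is.null(iv[[1L]]$labels)) NULL else
      vapply(iv, function(r) as.character(r$labels), "")
  }
  ub <- vapply(ub_raw, function(u)
    if (identical(tolower(as.character(u)), "inf")) Inf else as.numeric(u), 0)
  interval_scale(as.numeric(lb), ub, version_id = obj$version_id,
                 labels = labels)
}

#' @rdname vamalign-io
#' @param scale An [interval_scale()].
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "interval_scale"))
  ub <- ifelse(is.finite(scale$ub), scale$ub, "inf")
  obj <- list(version_id = scale$version_id,
              intervals = data.frame(lb = scale$lb, ub = ub,
                                     stringsAsFactors = FALSE))
  if (!is.null(scale$labels)) obj$intervals$labels <- scale$labels
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         json = jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                     digits = NA, pretty = TRUE),
         yaml = , yml = yaml::write_yaml(
           list(version_id = obj$version_id,
                intervals = lapply(seq_len(nrow(obj$intervals)), function(i)
                  as.list(obj$intervals[i, , drop = FALSE]))), path),
         stop("unsupported scale file extension '.", ext, "'"))
  invisible(path)
}

#' @rdname vamalign-io
#' @param check Validate the matrix as column-stochastic after reading.
#' @param tol Column-sum tolerance for validation.
#' @return `read_matrix()`: a numeric matrix.
#' @export
read_matrix <- function(path, check = TRUE, tol = 1e-2) {
  M <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(M) <- NULL
  # coercion NAs are reported as a single clear error below
  suppressWarnings(storage.mode(M) <- "double")
  if (anyNA(M))
    stop("malformed matrix file '", path, "': non-numeric entries")
  if (check) check_transition_matrix(M, tol = tol)
  M
}

#' @rdname vamalign-io
#' @param M Numeric matrix.
#' @param digits Decimal places for probabilities (default 5; `NA` keeps
#'   full precision).
#' @export
write_matrix <- function(M, path, digits = 5) {
  if (!is.na(digits)) M <- round(M, digits)
  utils::write.table(M, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname vamalign-io
#' @return `read_vector()`: a numeric vector (one value per line or a
#'   single CSV row).
#' @export
read_vector <- function(path) {
  v <- scan(path, sep = ",", quiet = TRUE)
  v[!is.na(v)]
}

#' @rdname vamalign-io
#' @param v Numeric vector.
#' @export
write_vector <- function(v, path, digits = 5) {
  if (!is.na(digits)) v <- round(v, digits)
  cat(paste(v, collapse = ","), "\n", file = path)
  invisible(path)
}

#' @rdname vamalign-io
#' @return `read_counts()`: a named numeric vector of counts indexed by
#'   option.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path)
  need <- c("option", "count")
  if (!all(need %in% names(df)))
    stop("counts file must have 'option' and 'count' columns")
  bad <- which(is.na(df$count) | df$count < 0)
  if (length(bad))
    stop("counts file '", path, "': negative or missing count at data line ",
         bad[1L])
  counts <- numeric(max(df$option))
  counts[df$option] <- df$count
  counts
}

#' @rdname vamalign-io
#' @param scale_from,scale_to [interval_scale()]s for the two time points.
#' @return `read_pairs()`: a [paired_responses()] object from a CSV with
#'   columns `id`, `t1_option`, `t2_option`.
#' @export
read_pairs <- function(path, scale_from, scale_to) {
  df <- utils::read.csv(path)
  need <- c("id", "t1_option", "t2_option")
  if (!all(need %in% names(df)))
    stop("pairs file must have 'id', 't1_option', 't2_option' columns")
  paired_responses(df$id, df$t1_option, df$t2_option, scale_from, scale_to)
}

#' @rdname vamalign-io
#' @param pairs A [paired_responses()] object.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "paired_responses"))
  utils::write.csv(data.frame(id = pairs$id, t1_option = pairs$from,
                              t2_option = pairs$to),
                   path, row.names = FALSE)
  invisible(path)
}
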