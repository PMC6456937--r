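#' Impute missing values in one time series
#'
#' @param x numeric vector with `NA` marking missing observations.
#' @param method `"linear"` (default): straight-line interpolation between the
#'   nearest observed neighbours in time, with leading/trailing gaps filled by
#'   the nearest observed value; `"zero"`: missing values become 0; `"fail"`:
#'   any missing value is an error.
#' @param factor_id optional id used in error messages.
#' @return A complete numeric vector of the same length.
#' @export
impute_missing <- function(x, method = c("linear", "zero", "fail"), factor_id = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x)
  who <- if (is.null(factor_id)) "series" else sprintf("factor '%s'", factor_id)
  if (!anyNA(x)) return(x)
  if (method == "fail") stop(sprintf("%s contains missing values (method = 'fail')", who))
  if (method == "zero") { x[is.na(x)] <- 0; return(x) }
  obs <- which(!is.na(x))
  if (!length(obs)) stop(sprintf("%s is entirely missing; cannot interpolate", who))
  if (length(obs) == 1L) { x[] <- x[obs]; return(x) }
  stats::approx(obs, x[obs], xout = seq_along(x), method = "linear", rule = 2)$y
}

#' Rank-based inverse-normal transformation of one series
#'
#' Replaces each value by the normal score `qnorm(R_k / (n + 1))`, where `R_k`
#' is the (mid)rank of the k-th observation among all n. The transform is
#' order-preserving and invariant to strictly increasing transformations of
#' the input, which makes the downstream local similarity and liquid
#' association scores behave like correlation-scale statistics. No post-hoc
#' rescaling to unit variance is applied; the sample variance of normal scores
#' is slightly below 1 by construction and the significance approximations
#' account for it.
#'
#' @param x complete numeric vector (impute first; see [impute_missing()]).
#' @param factor_id optional id carried through to the result.
#' @return An object of class `normalized_series`: list with `factor_id`,
#'   `z` (normal scores) and `ranks` (midranks).
#' @export
rank_normal_transform <- function(x, factor_id = NULL) {
  x <- as.numeric(x)
  if (!length(x)) stop("empty series")
  if (anyNA(x)) stop("series contains missing values; impute first")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm(r / (n + 1))
  if (length(unique(x)) == 1L && n > 1L) {
    warning(sprintf("constant series%s: all normal scores are 0 and it can never associate",
                    if (is.null(factor_id)) "" else sprintf(" ('%s')", factor_id)))
  }
  structure(list(factor_id = factor_id, z = z, ranks = r),
            class = "normalized_series")
}

#' Normalize every factor of an abundance table
#'
#' Imputes each row, then applies [rank_normal_transform()]. The same
#' normalized scores are reused by both the local similarity and the liquid
#' association stages.
#'
#' @param table an [abundance_table()].
#' @param impute_method passed to [impute_missing()].
#' @return An object of class `normalized_set`: a named list of
#'   `normalized_series`, one per factor, in the input row order, with
#'   attribute `n` (series length).
#' @export
normalize_table <- function(table, impute_method = c("linear", "zero", "fail")) {
  stopifnot(inherits(table, "abundance_table"))
  impute_method <- match.arg(impute_method)
  out <- vector("list", length(table$factor_ids))
  names(out) <- table$factor_ids
  for (i in seq_along(out)) {
    id <- table$factor_ids[i]
    xi <- tryCatch(impute_missing(table$values[i, ], impute_method, factor_id = id),
                   error = function(e) stop(sprintf("factor '%s': %s", id, conditionMessage(e)),
                                            call. = FALSE))
    out[[i]] <- rank_normal_transform(xi, factor_id = id)
  }
  structure(out, n = ncol(table$values), class = "normalized_set")
}

# coerce a normalized_series / numeric vector to plain numeric scores
.z_of <- function(x) {
  if (inherits(x, "normalized_series")) x$z else as.numeric(x)
}

# stack a normalized_set (or named list / matrix) into a factors-in-columns matrix
.z_matrix <- function(normalized) {
  if (is.matrix(normalized)) return(normalized)
  stopifnot(is.list(normalized), length(normalized) >= 1L)
  zs <- lapply(normalized, .z_of)
  n <- unique(lengths(zs))
  if (length(n) != 1L) stop("normalized series have unequal lengths")
  m <- matrix(unlist(zs, use.names = FALSE), nrow = n)
  colnames(m) <- names(normalized)
  m
}
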