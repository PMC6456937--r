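#' Construct an abundance table
#'
#' An `abundance_table` holds a factor-by-timepoint numeric matrix (rows are
#' OTUs or environmental factors, columns are time points), the class of each
#' factor, and an explicit missing-value mask (`NA` entries of `values`).
#' Row order is preserved end-to-end by every operation in the package.
#'
#' @param values numeric matrix, factors in rows, timepoints in columns.
#'   Missing observations are `NA`, never silently zero.
#' @param factor_ids character vector of unique row identifiers.
#' @param factor_class named character vector mapping every factor id to
#'   `"OTU"` or `"environment"`.
#' @param timepoint_labels character vector of column labels.
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `factor_ids`, `factor_class`, `timepoint_labels`.
#' @export
abundance_table <- function(values, factor_ids,
                            factor_class = NULL,
                            timepoint_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  factor_ids <- as.character(factor_ids)
  if (nrow(values) < 1L) stop("abundance table needs at least one factor row")
  if (ncol(values) < 2L) stop("abundance table needs at least two timepoints")
  if (length(factor_ids) != nrow(values))
    stop("factor_ids length does not match the number of rows")
  dup <- factor_ids[duplicated(factor_ids)]
  if (length(dup))
    stop("duplicate factor ID(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(timepoint_labels)) timepoint_labels <- paste0("T", seq_len(ncol(values)))
  if (is.null(factor_class)) {
    factor_class <- stats::setNames(rep("OTU", length(factor_ids)), factor_ids)
  }
  factor_class <- factor_class[factor_ids]
  if (anyNA(names(factor_class)) || anyNA(factor_class))
    stop("every factor needs a class")
  if (!all(factor_class %in% c("OTU", "environment")))
    stop("factor classes are restricted to 'OTU' and 'environment'")
  dimnames(values) <- list(factor_ids, timepoint_labels)
  structure(
    list(values = values, factor_ids = factor_ids,
         factor_class = factor_class,
         timepoint_labels = as.character(timepoint_labels)),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d factors x %d timepoints (%d OTU, %d environment), %d missing cells\n",
              nrow(x$values), ncol(x$values),
              sum(x$factor_class == "OTU"), sum(x$factor_class == "environment"),
              sum(is.na(x$values))))
  invisible(x)
}

#' Read a factor-by-timepoint abundance matrix
#'
#' Parses a tab-delimited file whose first row is a header of timepoint labels
#' and whose first column holds factor IDs. Cells equal to `na_token`
#' (case-insensitive) or empty are recorded as missing. Parsing is
#' locale-independent (decimal point only).
#'
#' @param path path to a TSV file.
#' @param na_token string marking a missing cell (default `"na"`).
#' @param factor_class optional named character vector of factor classes, as
#'   returned by [read_factor_classes()]; factors without an entry default to
#'   `"OTU"` with a warning.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, na_token = "na", factor_class = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("file must have a header row and at least one factor row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  n_col <- length(header)
  tp <- header[-1L]
  ids <- character(length(cells) - 1L)
  vals <- matrix(NA_real_, nrow = length(cells) - 1L, ncol = n_col - 1L)
  for (i in seq_along(ids)) {
    row <- cells[[i + 1L]]
    if (length(row) != n_col)
      stop(sprintf("ragged row %d: expected %d fields, found %d", i + 1L, n_col, length(row)))
    ids[i] <- row[1L]
    body <- row[-1L]
    miss <- tolower(trimws(body)) %in% c(tolower(na_token), "")
    num <- suppressWarnings(as.numeric(body))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d (factor '%s'), column %d: '%s'",
                   i + 1L, ids[i], bad[1L] + 1L, body[bad[1L]]))
    num[miss] <- NA_real_
    vals[i, ] <- num
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate factor ID(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(factor_class)) {
    absent <- setdiff(ids, names(factor_class))
    if (length(absent)) {
      for (a in absent)
        warning(sprintf("factor '%s' has no class entry; defaulting to OTU", a))
      factor_class <- c(factor_class, stats::setNames(rep("OTU", length(absent)), absent))
    }
  }
  abundance_table(vals, ids, factor_class = factor_class, timepoint_labels = tp)
}

#' Read a factor class table
#'
#' Two tab-separated columns: factor ID and class (`OTU` or `environment`).
#' No header is expected; a header line reading `factor_id<TAB>class` is
#' tolerated and skipped.
#'
#' @param path path to the TSV file.
#' @return A named character vector mapping factor id to class.
#' @export
read_factor_classes <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(trimws(cells[[1L]])), c("factor_id", "class")))
    cells <- cells[-1L]
  ids <- vapply(cells, `[`, "", 1L)
  cls <- trimws(vapply(cells, function(r) if (length(r) >= 2L) r[2L] else "", ""))
  bad <- !cls %in% c("OTU", "environment")
  if (any(bad))
    stop(sprintf("unknown factor class '%s' for factor '%s' (allowed: OTU, environment)",
                 cls[which(bad)[1L]], ids[which(bad)[1L]]))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate factor ID(s) in class table: ", paste(unique(dup), collapse = ", "))
  stats::setNames(cls, ids)
}

# shared formatting: 6 significant digits, plain decimal notation
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(signif(v, 6L), scientific = FALSE, trim = TRUE)
  }, "")
  out
}

# deterministic result ordering: P ascending, |score| descending, lexical IDs
.order_results <- function(p, score, ids) {
  ord <- order(p, -abs(score), ids, method = "radix")
  ord
}

#' Write a pair association table
#'
#' Tab-delimited with header `X Y LS sign interval_start interval_end delay P Q`,
#' floats at 6 significant digits, rows sorted by P, then |LS| descending,
#' then lexically by the combined factor IDs so re-runs are byte-identical.
#'
#' @param pairs a `pair_table` data frame as returned by [screen_pairs()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- c("X", "Y", "LS", "sign", "interval_start", "interval_end", "delay", "P", "Q")
  if (is.null(pairs) || nrow(pairs) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  ord <- .order_results(pairs$p, pairs$ls, paste(pairs$x_id, pairs$y_id))
  pairs <- pairs[ord, , drop = FALSE]
  out <- data.frame(X = pairs$x_id, Y = pairs$y_id,
                    LS = .fmt_num(pairs$ls), sign = pairs$sign,
                    interval_start = pairs$interval_start,
                    interval_end = pairs$interval_end, delay = pairs$delay,
                    P = .fmt_num(pairs$p), Q = .fmt_num(pairs$q),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a triplet association table
#'
#' Tab-delimited with header `X Y Z LA P Q type`, floats at 6 significant
#' digits, deterministic row order (P ascending, |LA| descending, lexical IDs).
#'
#' @param triplets a `triplet_table` data frame as returned by [scan_mediators()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_triplet_table <- function(triplets, path) {
  cols <- c("X", "Y", "Z", "LA", "P", "Q", "type")
  if (is.null(triplets) || nrow(triplets) == 0L) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  ord <- .order_results(triplets$p, triplets$la,
                        paste(triplets$x_id, triplets$y_id, triplets$z_id))
  triplets <- triplets[ord, , drop = FALSE]
  out <- data.frame(X = triplets$x_id, Y = triplets$y_id, Z = triplets$z_id,
                    LA = .fmt_num(triplets$la), P = .fmt_num(triplets$p),
                    Q = .fmt_num(triplets$q), type = triplets$la_type,
                    stringsAsFactors = FALSE)
  names(out) <- cols
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a pair table written by [write_pair_table()]
#' @param path file path.
#' @return data frame with the package's internal pair columns.
#' @export
read_pair_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric", "character",
                                        "integer", "integer", "integer", "numeric", "numeric"))
  data.frame(x_id = d$X, y_id = d$Y, ls = d$LS, sign = d$sign,
             interval_start = d$interval_start, interval_end = d$interval_end,
             delay = d$delay, p = d$P, q = d$Q, stringsAsFactors = FALSE)
}

#' Read back a triplet table written by [write_triplet_table()]
#' @param path file path.
#' @return data frame with the package's internal triplet columns.
#' @export
read_triplet_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character",
                                        "numeric", "numeric", "numeric", "character"))
  data.frame(x_id = d$X, y_id = d$Y, z_id = d$Z, la = d$LA,
             p = d$P, q = d$Q, la_type = d$type, stringsAsFactors = FALSE)
}
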