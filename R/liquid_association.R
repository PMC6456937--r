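#' Liquid association score
#'
#' The liquid association of a pair (X, Y) with respect to a scouting
#' (mediator) variable Z is `LA(X;Y|Z) = E(XYZ)`, estimated as the mean of
#' elementwise triple products of the normalized series. Because the product
#' is commutative the score is fully symmetric in its three arguments: it
#' measures three-way dependence, and the screened pair determines which
#' variable plays the mediator role. A positive score means the X–Y product
#' co-varies positively with the (zero-centred) level of Z, i.e. the pair's
#' correlation is strongest where Z is high.
#'
#' @param zx,zy,zz normalized series of equal length `m >= 1`
#'   ([rank_normal_transform()] output or plain numeric vectors).
#' @return The LA score (a scalar).
#' @export
la_score <- function(zx, zy, zz) {
  zx <- .z_of(zx); zy <- .z_of(zy); zz <- .z_of(zz)
  m <- length(zx)
  if (length(zy) != m || length(zz) != m) stop("series lengths differ")
  if (m < 1L) stop("empty series")
  mean(zx * zy * zz)
}

#' Permutation test for a liquid association score
#'
#' Permutes only the mediator series Z, recomputes the LA score each time,
#' and returns the pseudocounted two-sided p-value
#' `(1 + #\{|LA_perm| >= |LA_obs|\}) / (n_perm + 1)`. The two-sided form is
#' the default because both LA signs are meaningful (high-Z- and
#' low-Z-enhanced mediation); `one_sided = TRUE` counts only permuted scores
#' higher than the observed one.
#'
#' @param zx,zy,zz normalized series of equal length.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param one_sided if TRUE, p is the upper-tail fraction of the signed score.
#' @return p-value on the lattice `k / (n_perm + 1)`.
#' @export
la_permutation_test <- function(zx, zy, zz, n_perm = 1000L, seed = NULL,
                                one_sided = FALSE) {
  zx <- .z_of(zx); zy <- .z_of(zy); zz <- .z_of(zz)
  m <- length(zx)
  if (length(zy) != m || length(zz) != m) stop("series lengths differ")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  xy <- zx * zy
  obs <- mean(xy * zz)
  .with_seed(seed, {
    idx <- replicate(n_perm, sample.int(m))
    perm <- as.vector(crossprod(matrix(zz[idx], nrow = m), xy)) / m
    hits <- if (one_sided) sum(perm >= obs) else sum(abs(perm) >= abs(obs))
    (1 + hits) / (n_perm + 1)
  })
}

#' Classify a mediated-correlation triplet
#'
#' The four triplet types combine the sign of the screened pair's LS score
#' with the sign of the LA score. Since `LA = E(XYZ)` weights the X–Y product
#' by the level of Z, a positive LA means the pair co-varies (in its LS
#' direction) where Z is high, and a negative LA where Z is low:
#' \describe{
#'   \item{A}{LS +, LA +: high Z enhances the positive correlation.}
#'   \item{B}{LS -, LA +: low Z enhances the negative correlation.}
#'   \item{C}{LS +, LA -: low Z enhances the positive correlation.}
#'   \item{D}{LS -, LA -: high Z enhances the negative correlation.}
#' }
#'
#' @param pair_ls_sign `"+"` or `"-"` (sign of the pair's LS score); vectorized.
#' @param la_sign `"+"` or `"-"` (sign of the LA score); vectorized.
#' @return Character vector of types in `{"A","B","C","D"}`.
#' @export
classify_la_type <- function(pair_ls_sign, la_sign) {
  ok <- function(s) all(s %in% c("+", "-"))
  if (!ok(pair_ls_sign) || !ok(la_sign))
    stop("signs must be '+' or '-' (a zero score is never classified)")
  key <- paste0(pair_ls_sign, la_sign)
  unname(c("++" = "A", "-+" = "B", "+-" = "C", "--" = "D")[key])
}

#' Scan candidate mediators for screened pairs
#'
#' For each screened pair (X, Y), every other factor is evaluated as a
#' candidate mediator Z: the LA score is computed on the same normalized
#' scores used by the pairwise screen, tested by permutation of Z, and the
#' q-values are computed over the whole triplet family pooled across all
#' screened pairs in the run. Triplets with `p <= p_cut`, `q <= q_cut` and
#' (optionally) `|LA| >= la_effect_cut` are kept and classified into the four
#' mediated-correlation types.
#'
#' @param pairs a `pair_table` of screened pairs ([screen_pairs()] output).
#' @param normalized the `normalized_set` the pairs were screened on.
#' @param n_perm permutations per triplet (default 1000).
#' @param p_cut p-value cutoff (default 0.001).
#' @param q_cut q-value cutoff (default 0.05).
#' @param la_effect_cut optional minimal |LA| (e.g. 0.8 to restrict to strong
#'   mediation); `NULL` (default) disables the effect filter.
#' @param seed base seed; each (pair, mediator) test draws its permutations
#'   from a substream keyed by the three factor IDs.
#' @param one_sided passed to [la_permutation_test()].
#' @param keep_all if TRUE, return all tested triplets with a `kept` column.
#' @return A data frame of class `triplet_table` with columns `x_id`, `y_id`,
#'   `z_id`, `la`, `m`, `p`, `q`, `la_type`, `pair_ls_sign`, plus attribute
#'   `counts` (triplets tested / surviving each filter).
#' @export
scan_mediators <- function(pairs, normalized, n_perm = 1000L, p_cut = 0.001,
                           q_cut = 0.05, la_effect_cut = NULL, seed = NULL,
                           one_sided = FALSE, keep_all = FALSE) {
  Z <- .z_matrix(normalized)
  ids <- colnames(Z)
  m <- nrow(Z)
  if (nrow(pairs) == 0L) {
    tab <- data.frame(x_id = character(0), y_id = character(0), z_id = character(0),
                      la = numeric(0), m = integer(0), p = numeric(0), q = numeric(0),
                      la_type = character(0), pair_ls_sign = character(0),
                      stringsAsFactors = FALSE)
    attr(tab, "counts") <- list(triplets_tested = 0L, pass_p = 0L,
                                pass_pq = 0L, pass_all = 0L)
    class(tab) <- c("triplet_table", "data.frame")
    return(tab)
  }
  missing_ids <- setdiff(unique(c(pairs$x_id, pairs$y_id)), ids)
  if (length(missing_ids))
    stop("screened pair references unknown factor(s): ",
         paste(missing_ids, collapse = ", "))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- pairs$x_id[i]; y <- pairs$y_id[i]
    cand <- setdiff(ids, c(x, y))
    if (!length(cand)) next
    xy <- Z[, x] * Z[, y]
    la <- as.vector(crossprod(Z[, cand, drop = FALSE], xy)) / m
    p <- numeric(length(cand))
    for (j in seq_along(cand)) {
      p[j] <- la_permutation_test(
        Z[, x], Z[, y], Z[, cand[j]], n_perm = n_perm,
        seed = .substream_seed(seed, paste(x, y, cand[j], sep = "\r")),
        one_sided = one_sided)
    }
    rows[[i]] <- data.frame(x_id = x, y_id = y, z_id = cand, la = la, m = m,
                            p = p, pair_ls_sign = pairs$sign[i],
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$q <- storey_qvalues(tab$p)$q
  pass_p <- tab$p <= p_cut
  pass_pq <- pass_p & tab$q <= q_cut
  kept <- pass_pq
  if (!is.null(la_effect_cut)) kept <- kept & abs(tab$la) >= la_effect_cut
  counts <- list(triplets_tested = nrow(tab), pass_p = sum(pass_p),
                 pass_pq = sum(pass_pq), pass_all = sum(kept))
  la_sign <- ifelse(tab$la >= 0, "+", "-")
  tab$la_type <- classify_la_type(tab$pair_ls_sign, la_sign)
  tab <- tab[, c("x_id", "y_id", "z_id", "la", "m", "p", "q",
                 "la_type", "pair_ls_sign")]
  if (keep_all) tab$kept <- kept else tab <- tab[kept, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "counts") <- counts
  class(tab) <- c("triplet_table", "data.frame")
  tab
}
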