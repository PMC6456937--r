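# Independent oracles used across the suite. These deliberately use naive
# exhaustive computation, not the package's algorithms.

# offsets in the package's documented tie-break order: |d| ascending,
# negative before positive
oracle_offsets <- function(D) {
  out <- 0L
  if (D > 0L) for (a in 1:D) out <- c(out, -a, a)
  out
}

# exhaustive local similarity: enumerate every offset and every interval,
# pick the best under the documented tie-break chain
oracle_local_similarity <- function(zx, zy, D = 0L) {
  n <- length(zx)
  best <- NULL
  rank_d <- 0L
  for (d in oracle_offsets(D)) {
    rank_d <- rank_d + 1L
    k0 <- max(1L, 1L - d); k1 <- min(n, n - d)
    s <- zx[k0:k1] * zy[(k0 + d):(k1 + d)]
    L <- length(s)
    S <- c(0, cumsum(s))
    for (i in 0:(L - 1L)) {
      for (j in (i + 1L):L) {
        seg <- S[j + 1L] - S[i + 1L]
        for (sgn in 0:1) {
          val <- if (sgn == 0L) seg else -seg
          cand <- list(value = val, sgn = sgn, rank_d = rank_d,
                       start = k0 + i, end = k0 + j - 1L, delay = d)
          if (is.null(best) ||
              cand$value > best$value ||
              (cand$value == best$value && cand$sgn < best$sgn) ||
              (cand$value == best$value && cand$sgn == best$sgn &&
               cand$rank_d < best$rank_d) ||
              (cand$value == best$value && cand$sgn == best$sgn &&
               cand$rank_d == best$rank_d && cand$start < best$start) ||
              (cand$value == best$value && cand$sgn == best$sgn &&
               cand$rank_d == best$rank_d && cand$start == best$start &&
               cand$end < best$end)) {
            best <- cand
          }
        }
      }
    }
  }
  list(ls = best$value / n, sign = if (best$sgn == 0L) "+" else "-",
       interval = c(best$start, best$end), delay = best$delay)
}

# plain Benjamini-Hochberg step-up, written out longhand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# all permutations of 1..n (n small), one per row
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (pos in 1:n) {
    for (k in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- integer(n)
      row[pos] <- n
      row[-pos] <- sub[k, ]
      out[r, ] <- row
    }
  }
  out
}

# rank-normalize a plain vector (duplicates the definition on purpose)
oracle_normal_scores <- function(x) {
  qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

# draw one null LS statistic for rank-normalized independent series
null_ls_stat <- function(z) {
  S <- cumsum(sample(z) * sample(z))
  (max(S, 0) - min(S, 0)) / length(z)
}
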