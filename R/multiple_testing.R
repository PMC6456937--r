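#' Storey-style q-values
#'
#' Estimates the null proportion with the single-lambda plug-in
#' `pi0 = #\{p > lambda\} / ((1 - lambda) * m)` (capped at 1 and clamped
#' below at `1/m` so q-values cannot vanish), then applies the
#' Benjamini–Hochberg step-up scaled by `pi0`:
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j` on the sorted p-values.
#' With `pi0_method = "one"` (pi0 fixed at 1) this reduces exactly to BH
#' adjusted p-values. The single-lambda estimator is used instead of a
#' spline smoother because it stays well-defined on the discrete lattice of
#' permutation p-values.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param lambda tuning parameter for the pi0 plug-in (default 0.5).
#' @param pi0_method `"storey"` (default) or `"one"` to force pi0 = 1.
#' @return A list of class `pvalue_family`: `p` (input), `pi0`, and `q`
#'   (same order as `p`).
#' @export
storey_qvalues <- function(p, lambda = 0.5, pi0_method = c("storey", "one")) {
  pi0_method <- match.arg(pi0_method)
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- if (pi0_method == "one") 1 else
    min(1, sum(p > lambda) / ((1 - lambda) * m))
  pi0 <- max(pi0, 1 / m)
  q <- pmin(pi0 * stats::p.adjust(p, method = "BH"), 1)
  structure(list(p = p, pi0 = pi0, q = q), class = "pvalue_family")
}

#' @export
print.pvalue_family <- function(x, ...) {
  cat(sprintf("pvalue_family: %d tests, pi0 = %.3f, %d with q <= 0.05\n",
              length(x$p), x$pi0, sum(x$q <= 0.05)))
  invisible(x)
}
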