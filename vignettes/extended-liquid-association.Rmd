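---
title: "Extended liquid association: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended liquid association: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ela)
```

## The problem

Monthly time series of microbial communities — OTU relative abundances
fingerprinted from the same water samples as temperature, nutrients,
chlorophyll and other environmental measurements — carry two kinds of signal
beyond simple pairwise correlation. First, two factors may track each other
over only *part* of the record (a bloom season, a warm interval), which a
global correlation coefficient dilutes. Second, the strength of a pairwise
relationship may itself depend on a third factor: two taxa that co-occur
tightly when silicate is high may decouple when it is low. This package
screens for the first signal with **local similarity analysis** (LSA) and for
the second with **liquid association** (LA), and renders the resulting
pair-plus-mediator triplets as a Cytoscape-loadable network. Output is
associational: neither stage supports causal claims.

## Normalization

Each factor series $X_1,\dots,X_n$ is imputed (linear interpolation in time
by default, selectable to zero-fill or hard failure) and replaced by normal
scores
$$Z_k = \Phi^{-1}\!\left[\frac{R_k}{n+1}\right],$$
where $R_k$ is the (mid)rank of $X_k$ and $\Phi$ the standard normal CDF.
Midranks keep tied values symmetric around zero. The transform is invariant
to monotone distortions of the raw scale — OTU fingerprint intensities and
environmental measurements become comparable — and makes both downstream
statistics behave on a correlation-like scale. The scores are used *as is*:
their sample variance
$v_n = \tfrac1n\sum_k \Phi^{-1}(k/(n+1))^2$
is slightly below 1 (0.93 at $n = 120$), and the significance machinery
accounts for that explicitly rather than rescaling the data.

A constant series gets all-zero scores and a warning; it can never associate
with anything and is best removed upstream.

## Local similarity

For normalized series $x, y$ and alignment offset $d$ (|d| ≤ D, default
D = 0: synchronous associations only), form products $s_k = x_k y_{k+d}$ and
find the segment whose sum has maximal absolute value, via the standard
positive/negative accumulator recurrences
$P_k = \max(0, P_{k-1} + s_k)$, $N_k = \max(0, N_{k-1} - s_k)$.
The LS score is that maximal |segment sum| divided by the *full* length $n$,
so a pair correlated at $\rho$ over the whole series scores roughly
$v_n\,\rho$. The sign records which accumulator won; the optimal segment is
reported in x-series coordinates. Ties are resolved deterministically:
positive over negative, smaller |d| (negative before positive at equal |d|),
earliest start, shortest segment. The dynamic program is checked against an
exhaustive enumeration over all intervals and offsets — exact equality,
including tie-breaks — in the test suite.

### Significance

Under independence, the partial-sum walk of the products behaves like a
random walk with step standard deviation $v_n$, and the maximal |segment
sum| is exactly the *range* (max minus min) of that walk. The limiting law
of the normalized statistic $LS\sqrt n$ is therefore the range of a standard
Brownian motion on $[0,1]$, whose CDF we evaluate by Feller's reflection
series, truncated when a term falls below $10^{-12}$. Two finite-sample
effects make the raw asymptotic conservative: the score variance $v_n < 1$,
and the discrete walk undershooting the continuous range. Both are absorbed
into one effective scale,
$$\sigma_n = v_n\left(1 - \frac{0.58}{\sqrt n}\right),
\qquad p(LS) = 1 - F_{\text{range}}\!\left(\frac{LS\sqrt n}{\sigma_n}\right),$$
with the constant 0.58 calibrated once against large permutation-null
simulations at $n \in \{30, 50, 80, 120, 160, 200\}$ (tail quantiles
0.90–0.999; the per-quantile estimates ranged 0.51–0.69 with no trend in
$n$). The test suite verifies the result against 20,000-permutation
estimates at $n = 50$ and $n = 120$ across tail probabilities
$5\times10^{-4}$–$5\times10^{-2}$, and verifies empirical type-I error at
the 0.05 and 0.01 levels. The approximation is built and validated for
rank-normalized, essentially tie-free series of length roughly $n \ge 30$;
for heavy ties or very short series use the permutation method
(`p_method = "perm"`).

For $D > 0$ the offsets are treated as approximately independent,
$p = 1 - F(x)^{2D+1}$; this is a convenience the package exposes but the
default pipeline does not exercise.

`ls_significance_cutoff()` inverts the tail on a 2-decimal grid: the
smallest score significant at $p \le 0.001$ for $n = 120$. Because the
theoretical tail is anchored to the *permutation truth* (the exact null
probability of exceeding a score near 0.28 at $n = 120$ is about 0.002),
this inversion lands at 0.30. Analyses of real data that also apply a
data-dependent q-value cutoff can report a smaller empirical score
threshold — the smallest score among surviving pairs — which should not be
confused with the pure p-inversion computed here.

### The pairwise screen

All $F(F-1)/2$ pairs are scored; q-values are computed over that whole
family; survivors must satisfy $p \le 0.001$, $q \le 0.05$, and an optimal
segment spanning strictly more than half the series (the span rule removes
associations confined to a short episode). Filters are applied in that
order and per-stage counts are logged.

## Liquid association

For each surviving pair and every other factor $z$ as candidate mediator,
$$\widehat{LA}(x; y \mid z) = \frac1m \sum_{i=1}^m x_i y_i z_i,$$
the empirical third moment of the normalized triple. The statistic is fully
symmetric in its arguments; the *pair* is what breaks the symmetry and
designates $z$ the mediator. Significance comes from permuting only $z$
(N = 1000 by default) with the pseudocounted two-sided p-value
$(1 + \#\{|LA^\pi| \ge |LA|\})/(N+1)$. Two-sided is the default because
both LA signs are scientifically meaningful; a one-sided variant (permuted
scores higher than observed) is available via `one_sided = TRUE`. The
pseudocount avoids p = 0; with N = 1000 the attainable minimum is
$1/1001 \approx 0.000999$, which still passes the $p \le 0.001$ filter.

Triplet q-values are pooled across all (pair, mediator) tests in the run —
one family per screening experiment — and the same $p \le 0.001$,
$q \le 0.05$ cutoffs apply, plus an optional effect filter
`la_effect_cut` on $|LA|$ (off by default; useful to restrict a dense
subnetwork to strong mediations).

Kept triplets are typed by the two signs:

| pair LS | LA | type | reading |
|---|---|---|-----------------------------|
| + | + | A | high Z enhances the positive correlation |
| − | + | B | low Z enhances the negative correlation |
| + | − | C | low Z enhances the positive correlation |
| − | − | D | high Z enhances the negative correlation |

since $LA = E(XYZ)$ weights the X–Y product by the zero-centred level of Z.

### A resolution limit worth knowing

With N permutations, no triplet p-value can fall below $1/(N+1)$, so in a
family of $m$ triplet tests the smallest attainable q is about
$\pi_0\, m / ((N+1)\, r)$ for $r$ tests at the floor. With N = 1000 and
$q \le 0.05$, a run needs roughly $r \gtrsim m/50$ floor-level triplets for
*any* to survive. Sparse planted signal in a large scanned family is
therefore invisible at N = 1000 — not a defect of the scoring but of the
permutation resolution; raise `n_perm` (the per-test cost is linear) when
scanning many candidates for few expected mediators. The package keeps
N = 1000 as the default analysis setting and logs per-stage counts so the
effect is visible in the run log.

## Multiple testing

`storey_qvalues()` uses the single-$\lambda$ plug-in
$\hat\pi_0 = \#\{p > \lambda\} / ((1-\lambda) m)$ at $\lambda = 0.5$,
capped at 1 and clamped below at $1/m$, followed by the
Benjamini–Hochberg step-up scaled by $\hat\pi_0$. The single-$\lambda$ form
(rather than a spline over a $\lambda$ grid) stays well-defined on the
discrete lattice of permutation p-values. Forcing $\pi_0 = 1$
(`pi0_method = "one"`) reproduces BH exactly, which the tests verify
against a longhand implementation.

## Synthetic communities

`simulate_community()` embeds planted structure among iid Gaussian null
factors (a log-normal option changes marginals without changing ranks):

* **Pairs**: $y = \rho x + \sqrt{1-\rho^2}\,\varepsilon$, optionally
  sign-flipped.
* **Mediated triplets**: $x = \sigma\,\beta\,h(z)\,y + \text{noise}$, with
  the rectified gate $h(z) = \max(z, 0)$ for high-Z-enhancing types (A, D),
  $h(z) = \max(-z, 0)$ for low-Z-enhancing types (B, C), and
  $\sigma = \pm1$ setting the correlation direction. The gate was chosen
  over a linear $g(z) = z$ coupling deliberately: a linear gate yields zero
  marginal X–Y correlation (the pair would enter the screen with a
  coin-flip LS sign), while the rectified gate confines the coupling to one
  mediator state, giving a stable LS sign *and* the intended LA sign.
  $\beta = 0$ embeds the exact null.

Missingness is injected completely at random at a stated rate, never
blanking an entire series. A manifest (factor count, length, seed, plants,
noise, missing rate) fully determines the dataset.

What the generator does *not* emulate: temporal autocorrelation and
seasonality, compositional closure of relative abundances, and
block-structured missingness. Passing recovery tests therefore demonstrate
correctness of the statistical machinery under exchangeable nulls, not
robustness to autocorrelated or compositional data — on real series the
permutation null is optimistic to an extent the package does not quantify.

## Numerical and reproducibility choices

* Tail series truncation at $10^{-12}$ increments; p-values clipped to
  $[0,1]$.
* All permutation draws derive from one run seed through per-test
  substreams keyed by a string hash of the factor IDs involved, so adding a
  factor does not reshuffle unrelated tests and identical runs are
  byte-identical.
* Result tables sort by p, then |score| descending, then lexical IDs;
  floats print at 6 significant digits.
* Degenerate inputs: constant series warn and score zero; an all-missing
  series is a hard error naming the factor; a degenerate (all-zero)
  mediator gives p = 1.

## Problem sizes in the shipped experiments

The test suite works at desk scale, chosen to keep a full run in minutes:
oracle equivalence on 1000 pairs with $n \le 30$; null calibration with
20,000 permutation draws at $n \in \{50, 120\}$ and 2000 null triplets at
$m = 120$; type recovery over 200 seeds per type at $m = 120$,
$\beta = 1$, noise 0.5; and end-to-end recovery on 100 factors × 120
timepoints with 5 planted pairs and 3 planted triplets over 10 seeds. The
acceptance script recomputes the LS cutoff inversion at $n = 120$.

## Known limitations

* The theoretical LS tail is specific to rank-normalized input; feeding
  unnormalized data into `theoretical_pvalue()` voids its calibration.
* Permutation resolution bounds attainable q-values (see above).
* Lagged associations are supported by the scoring core but not reported by
  the default pipeline configuration.
* One imputation rule applies to all rows, OTU and environmental alike.
* Factor IDs must be globally unique across the OTU and environmental
  blocks.
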