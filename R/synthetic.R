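#' Simulate a null factor-by-timepoint matrix
#'
#' Independent series for every factor: Gaussian by default, or log-normal
#' (`exp` of the Gaussian draw) to mimic the right skew of relative-abundance
#' data. Because the pipeline rank-normalizes every row, the two variants
#' yield identical normalized scores — a testable invariance.
#'
#' @param n_factors number of factors (>= 2).
#' @param n_time number of timepoints (>= 10).
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param distribution `"gaussian"` or `"lognormal"`.
#' @param n_env how many of the factors are labelled `environment`
#'   (the last `n_env` rows); the rest are OTUs.
#' @return An [abundance_table()].
#' @export
simulate_null_matrix <- function(n_factors, n_time, seed = 1L,
                                 distribution = c("gaussian", "lognormal"),
                                 n_env = 0L) {
  distribution <- match.arg(distribution)
  if (n_factors < 2L) stop("n_factors must be >= 2")
  if (n_time < 10L) stop("n_time must be >= 10")
  vals <- .with_seed(seed,
    matrix(stats::rnorm(n_factors * n_time), nrow = n_factors))
  if (distribution == "lognormal") vals <- exp(vals)
  ids <- c(sprintf("OTU_%03d", seq_len(n_factors - n_env)),
           if (n_env > 0L) sprintf("ENV_%02d", seq_len(n_env)))
  cls <- stats::setNames(rep(c("OTU", "environment"), c(n_factors - n_env, n_env)), ids)
  abundance_table(vals, ids, factor_class = cls,
                  timepoint_labels = sprintf("T%03d", seq_len(n_time)))
}

# rectified mediation gate: h(z) selects the z-state in which the pair
# couples; the correlation sign sigma sets the direction of the coupling
.la_type_spec <- function(la_type) {
  switch(la_type,
    A = list(sigma = +1, gate = function(z) pmax(z, 0)),   # couple when Z high, corr +
    B = list(sigma = -1, gate = function(z) pmax(-z, 0)),  # couple when Z low,  corr -
    C = list(sigma = +1, gate = function(z) pmax(-z, 0)),  # couple when Z low,  corr +
    D = list(sigma = -1, gate = function(z) pmax(z, 0)),   # couple when Z high, corr -
    stop(sprintf("unknown liquid association type '%s'", la_type)))
}

#' Simulate one mediated triplet
#'
#' Draws Z and Y as iid standard normal and couples X to Y only in the
#' mediator state selected by the type: `x = sigma * beta * h(z) * y + noise`,
#' where the rectified gate `h(z)` is `max(z, 0)` for the high-Z-enhancing
#' types (A, D) and `max(-z, 0)` for the low-Z-enhancing types (B, C), and
#' `sigma` is +1 for positively correlated pairs (A, C) and -1 for negatively
#' correlated pairs (B, D). The gate makes the marginal X–Y correlation carry
#' the type's LS sign while `E(XYZ)` carries its LA sign, reproducing all
#' four mediated-correlation patterns. `beta = 0` embeds the null: the three
#' series are mutually independent.
#'
#' @param n_time series length.
#' @param la_type one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param beta coupling strength (>= 0).
#' @param noise_sd standard deviation of the additive noise on X.
#' @param seed integer seed.
#' @return A list with numeric series `x`, `y`, `z` and a `truth` record
#'   (`la_type`, `beta`, `noise_sd`, `expected_ls_sign`, `expected_la_sign`).
#' @export
simulate_mediated_triplet <- function(n_time, la_type = c("A", "B", "C", "D"),
                                      beta = 1, noise_sd = 0.5, seed = 1L) {
  la_type <- match.arg(la_type)
  if (beta < 0) stop("beta must be >= 0")
  spec <- .la_type_spec(la_type)
  out <- .with_seed(seed, {
    z <- stats::rnorm(n_time)
    y <- stats::rnorm(n_time)
    x <- spec$sigma * beta * spec$gate(z) * y + noise_sd * stats::rnorm(n_time)
    list(x = x, y = y, z = z)
  })
  out$truth <- list(
    la_type = la_type, beta = beta, noise_sd = noise_sd,
    expected_ls_sign = if (la_type %in% c("A", "C")) "+" else "-",
    expected_la_sign = if (la_type %in% c("A", "B")) "+" else "-")
  out
}

#' Define a simulation manifest
#'
#' A manifest fully determines a synthetic community given its seed: null
#' factors, planted correlated pairs, planted mediated triplets, and a
#' missing-data rate. Factors are named `F001 ... F<n>`; planted structures
#' reference factors by those names and no factor may take part in more than
#' one planted structure.
#'
#' @param n_factors total number of factors.
#' @param n_time number of timepoints.
#' @param seed integer seed.
#' @param planted_pairs data frame with columns `x`, `y`, `sign` (`"+"`/`"-"`)
#'   and `strength` (correlation in (0, 1)); may be `NULL`.
#' @param planted_triplets data frame with columns `x`, `y`, `z`,
#'   `la_type` and `beta`; may be `NULL`.
#' @param noise_sd additive noise on planted triplet X series (default 0.5).
#' @param missing_rate fraction of cells set missing at random (default 0).
#' @param n_env number of environmental factors (the last rows).
#' @return A list of class `simulation_manifest`.
#' @export
simulation_manifest <- function(n_factors, n_time, seed = 1L,
                                planted_pairs = NULL, planted_triplets = NULL,
                                noise_sd = 0.5, missing_rate = 0, n_env = 0L) {
  if (n_factors < 2L) stop("n_factors must be >= 2")
  ids <- sprintf("F%03d", seq_len(n_factors))
  used <- character(0)
  claim <- function(f, what) {
    bad <- setdiff(f, ids)
    if (length(bad)) stop("planted ", what, " references unknown factor(s): ",
                          paste(bad, collapse = ", "))
    clash <- intersect(f, used)
    if (length(clash)) stop("conflicting plants on factor(s): ",
                            paste(clash, collapse = ", "))
    used <<- c(used, f)
  }
  if (!is.null(planted_pairs) && nrow(planted_pairs)) {
    stopifnot(all(c("x", "y", "sign", "strength") %in% names(planted_pairs)))
    claim(c(planted_pairs$x, planted_pairs$y), "pair")
    stopifnot(all(planted_pairs$sign %in% c("+", "-")),
              all(planted_pairs$strength > 0 & planted_pairs$strength < 1))
  }
  if (!is.null(planted_triplets) && nrow(planted_triplets)) {
    stopifnot(all(c("x", "y", "z", "la_type", "beta") %in% names(planted_triplets)))
    claim(c(planted_triplets$x, planted_triplets$y, planted_triplets$z), "triplet")
    stopifnot(all(planted_triplets$la_type %in% c("A", "B", "C", "D")),
              all(planted_triplets$beta >= 0))
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(n_factors = n_factors, n_time = n_time, seed = as.integer(seed),
                 factor_ids = ids, planted_pairs = planted_pairs,
                 planted_triplets = planted_triplets, noise_sd = noise_sd,
                 missing_rate = missing_rate, n_env = as.integer(n_env)),
            class = "simulation_manifest")
}

#' Simulate a community with planted ground truth
#'
#' Embeds the manifest's planted pairs and mediated triplets among
#' independent Gaussian null factors, optionally injects missingness at
#' random, and returns truth tables for scoring recovery. A manifest with no
#' plants is equivalent to [simulate_null_matrix()].
#'
#' @param manifest a [simulation_manifest()].
#' @return A list with `table` (an [abundance_table()]) and `truth` (list of
#'   data frames `pairs` and `triplets` naming the planted structures and
#'   their expected signs/types).
#' @export
simulate_community <- function(manifest) {
  stopifnot(inherits(manifest, "simulation_manifest"))
  n <- manifest$n_time
  ids <- manifest$factor_ids
  vals <- .with_seed(manifest$seed, {
    m <- matrix(stats::rnorm(manifest$n_factors * n), nrow = manifest$n_factors,
                dimnames = list(ids, NULL))
    pp <- manifest$planted_pairs
    if (!is.null(pp) && nrow(pp)) {
      for (i in seq_len(nrow(pp))) {
        rho <- pp$strength[i]
        x <- m[pp$x[i], ]
        y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
        if (pp$sign[i] == "-") y <- -y
        m[pp$y[i], ] <- y
      }
    }
    pt <- manifest$planted_triplets
    if (!is.null(pt) && nrow(pt)) {
      for (i in seq_len(nrow(pt))) {
        spec <- .la_type_spec(pt$la_type[i])
        z <- m[pt$z[i], ]; y <- m[pt$y[i], ]
        m[pt$x[i], ] <- spec$sigma * pt$beta[i] * spec$gate(z) * y +
          manifest$noise_sd * stats::rnorm(n)
      }
    }
    if (manifest$missing_rate > 0) {
      mask <- stats::runif(length(m)) < manifest$missing_rate
      # never blank out a whole series
      for (r in seq_len(nrow(m))) {
        mr <- which(mask[(seq_len(n) - 1L) * nrow(m) + r])
        if (length(mr) >= n) mask[(mr[1L] - 1L) * nrow(m) + r] <- FALSE
      }
      m[mask] <- NA_real_
    }
    m
  })
  cls <- stats::setNames(
    rep(c("OTU", "environment"),
        c(manifest$n_factors - manifest$n_env, manifest$n_env)), ids)
  tab <- abundance_table(vals, ids, factor_class = cls,
                         timepoint_labels = sprintf("T%03d", seq_len(n)))
  pp <- manifest$planted_pairs
  pt <- manifest$planted_triplets
  truth_pairs <- if (!is.null(pp) && nrow(pp))
    data.frame(x_id = pp$x, y_id = pp$y, sign = pp$sign,
               strength = pp$strength, stringsAsFactors = FALSE)
  else data.frame(x_id = character(0), y_id = character(0),
                  sign = character(0), strength = numeric(0))
  truth_triplets <- if (!is.null(pt) && nrow(pt))
    data.frame(x_id = pt$x, y_id = pt$y, z_id = pt$z, la_type = pt$la_type,
               beta = pt$beta,
               expected_ls_sign = ifelse(pt$la_type %in% c("A", "C"), "+", "-"),
               expected_la_sign = ifelse(pt$la_type %in% c("A", "B"), "+", "-"),
               stringsAsFactors = FALSE)
  else data.frame(x_id = character(0), y_id = character(0), z_id = character(0),
                  la_type = character(0), beta = numeric(0),
                  expected_ls_sign = character(0), expected_la_sign = character(0))
  list(table = tab, truth = list(pairs = truth_pairs, triplets = truth_triplets))
}
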