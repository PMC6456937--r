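#' Pipeline run configuration
#'
#' Collects every tunable of the two-stage screen with defaults matching the
#' standard analysis settings: unlagged associations only (`max_delay = 0`),
#' theoretical pairwise p-values (`p_method = "theo"`), `p_cut = 0.001`,
#' `q_cut = 0.05`, a strict segment span above 50% of the series, and 1000
#' permutations for the liquid association tests.
#'
#' @param impute_method missing-value handling, see [impute_missing()].
#' @param max_delay maximal LS alignment offset D.
#' @param p_method pairwise p-value method, `"theo"` or `"perm"`.
#' @param p_cut,q_cut significance cutoffs applied at both stages.
#' @param min_span_fraction minimal pair segment span (strict) fraction.
#' @param n_perm permutations for the LA test (and pairwise, under `"perm"`).
#' @param la_effect_cut optional minimal |LA| for kept triplets.
#' @param one_sided use the one-sided LA permutation p-value.
#' @param seed base seed for all permutation substreams.
#' @return A list of class `run_config`.
#' @export
run_config <- function(impute_method = "linear", max_delay = 0L,
                       p_method = "theo", p_cut = 0.001, q_cut = 0.05,
                       min_span_fraction = 0.5, n_perm = 1000L,
                       la_effect_cut = NULL, one_sided = FALSE, seed = 1L) {
  structure(list(impute_method = impute_method, max_delay = as.integer(max_delay),
                 p_method = p_method, p_cut = p_cut, q_cut = q_cut,
                 min_span_fraction = min_span_fraction, n_perm = as.integer(n_perm),
                 la_effect_cut = la_effect_cut, one_sided = one_sided,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full co-occurrence + mediation pipeline
#'
#' Normalization, pairwise local similarity screening, mediator scanning,
#' network construction and export, with a JSON run log capturing the
#' configuration, seed, package version and the counts at every filter
#' stage. Two runs with identical inputs, configuration and seed produce
#' byte-identical result tables.
#'
#' @param table an [abundance_table()] (or a path to a TSV readable by
#'   [read_abundance_table()]).
#' @param outdir output directory for result files.
#' @param config a [run_config()].
#' @param classes optional named class vector (defaults to the table's own).
#' @return Invisibly, a list with `pairs`, `triplets`, `network`, `log` and
#'   `outdir`.
#' @export
run_pipeline <- function(table, outdir, config = run_config(), classes = NULL) {
  if (is.character(table)) table <- read_abundance_table(table, factor_class = classes)
  stopifnot(inherits(table, "abundance_table"), inherits(config, "run_config"))
  if (is.null(classes)) classes <- table$factor_class
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  normalized <- stage("normalize", normalize_table(table, config$impute_method))
  pairs <- stage("screen_pairs", screen_pairs(
    normalized, p_cut = config$p_cut, q_cut = config$q_cut,
    min_span_fraction = config$min_span_fraction, max_delay = config$max_delay,
    p_method = config$p_method, n_perm = config$n_perm, seed = config$seed))
  triplets <- stage("scan_mediators", scan_mediators(
    pairs, normalized, n_perm = config$n_perm, p_cut = config$p_cut,
    q_cut = config$q_cut, la_effect_cut = config$la_effect_cut,
    seed = config$seed, one_sided = config$one_sided))
  network <- stage("build_network", build_network(pairs, triplets, classes))
  write_pair_table(pairs, file.path(outdir, "pairs.tsv"))
  write_triplet_table(triplets, file.path(outdir, "triplets.tsv"))
  write_cytoscape(network, outdir)
  pc <- attr(pairs, "counts"); tc <- attr(triplets, "counts")
  log <- list(
    package = "ela",
    version = as.character(utils::packageVersion("ela")),
    config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
    n_factors = length(table$factor_ids),
    n_timepoints = length(table$timepoint_labels),
    counts = list(
      pairs_tested = pc$pairs_tested, pairs_pass_p = pc$pass_p,
      pairs_pass_pq = pc$pass_pq, pairs_passing = pc$pass_all,
      triplets_tested = tc$triplets_tested, triplets_pass_p = tc$pass_p,
      triplets_pass_pq = tc$pass_pq, triplets_passing = tc$pass_all))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(pairs = pairs, triplets = triplets, network = network,
                 log = log, outdir = outdir))
}
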