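#' Build the combined pair + triplet association network
#'
#' Factor nodes (OTUs and environmental factors) are connected by solid
#' pairwise edges carrying the LS score and its sign. Each mediated triplet
#' adds a hub node (rendered as a gray triangle in Cytoscape) with exactly
#' three edges: solid edges to X and Y signed like the pair's LS score, and a
#' wavy edge to the mediator Z whose sign is `+` when the association is
#' strong at high Z (types A and D) and `-` when strong at low Z (types B
#' and C). Hub ids use the `LA:X|Y|Z` convention with X, Y in lexical order
#' so symmetric pairs deduplicate.
#'
#' @param pairs a `pair_table` of screened pairs.
#' @param triplets a `triplet_table` of significant triplets; every triplet's
#'   (X, Y) must appear among `pairs`.
#' @param classes named character vector mapping factor id to `"OTU"` or
#'   `"environment"` (see [read_factor_classes()]); factors without an entry
#'   default to OTU.
#' @return A list of class `association_network` with data frames `nodes`
#'   (`node_id`, `node_kind`, `label`) and `edges` (`source`, `target`,
#'   `edge_kind`, `sign`, `weight`, `line_style`).
#' @export
build_network <- function(pairs, triplets = NULL, classes = NULL) {
  if (is.null(triplets)) {
    triplets <- data.frame(x_id = character(0), y_id = character(0),
                           z_id = character(0), la = numeric(0),
                           la_type = character(0), stringsAsFactors = FALSE)
  }
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  if (nrow(triplets)) {
    known <- pair_key(pairs$x_id, pairs$y_id)
    want <- pair_key(triplets$x_id, triplets$y_id)
    bad <- which(!want %in% known)
    if (length(bad))
      stop(sprintf("triplet (%s, %s | %s) references a pair that was not screened",
                   triplets$x_id[bad[1L]], triplets$y_id[bad[1L]], triplets$z_id[bad[1L]]))
  }
  factor_ids <- unique(c(pairs$x_id, pairs$y_id,
                         triplets$x_id, triplets$y_id, triplets$z_id))
  kind <- rep("otu", length(factor_ids))
  if (!is.null(classes)) {
    cl <- classes[factor_ids]
    kind[!is.na(cl) & cl == "environment"] <- "environment"
  }
  nodes <- data.frame(node_id = factor_ids, node_kind = kind,
                      label = factor_ids, stringsAsFactors = FALSE)
  edges <- data.frame(source = character(0), target = character(0),
                      edge_kind = character(0), sign = character(0),
                      weight = numeric(0), line_style = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    edges <- rbind(edges, data.frame(
      source = pairs$x_id, target = pairs$y_id, edge_kind = "ls_edge",
      sign = pairs$sign, weight = abs(pairs$ls), line_style = "solid",
      stringsAsFactors = FALSE))
  }
  if (nrow(triplets)) {
    x1 <- pmin(triplets$x_id, triplets$y_id)
    y1 <- pmax(triplets$x_id, triplets$y_id)
    hub <- paste0("LA:", x1, "|", y1, "|", triplets$z_id)
    nodes <- rbind(nodes, data.frame(node_id = hub, node_kind = "la_hub",
                                     label = hub, stringsAsFactors = FALSE))
    wavy_sign <- ifelse(triplets$la_type %in% c("A", "D"), "+", "-")
    pair_sign <- if ("pair_ls_sign" %in% names(triplets)) triplets$pair_ls_sign else
      ifelse(triplets$la_type %in% c("A", "C"), "+", "-")
    edges <- rbind(edges,
      data.frame(source = hub, target = triplets$x_id, edge_kind = "la_mediation",
                 sign = pair_sign, weight = abs(triplets$la), line_style = "solid",
                 stringsAsFactors = FALSE),
      data.frame(source = hub, target = triplets$y_id, edge_kind = "la_mediation",
                 sign = pair_sign, weight = abs(triplets$la), line_style = "solid",
                 stringsAsFactors = FALSE),
      data.frame(source = hub, target = triplets$z_id, edge_kind = "la_mediation",
                 sign = wavy_sign, weight = abs(triplets$la), line_style = "wavy",
                 stringsAsFactors = FALSE))
  }
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("association_network: %d nodes (%d hubs), %d edges (%d wavy)\n",
              nrow(x$nodes), sum(x$nodes$node_kind == "la_hub"),
              nrow(x$edges), sum(x$edges$line_style == "wavy")))
  invisible(x)
}

.node_shape <- c(otu = "octagon", environment = "rectangle", la_hub = "triangle")
.node_color <- c(otu = "violet", environment = "green", la_hub = "gray")

#' Write Cytoscape-loadable network files
#'
#' Writes an edge table (`edges.tsv`), a node attribute table (`nodes.tsv`),
#' a GraphML file (`network.graphml`) carrying the same attributes, and a
#' plain SIF file (`network.sif`). The suggested node shapes/colors follow
#' the standard encoding: violet octagons for OTUs, green rectangles for
#' environmental factors, gray triangles for liquid-association hubs; the
#' wavy/solid distinction and the red (+) / blue (-) sign are emitted as
#' attribute columns for a Cytoscape style mapping, since SIF cannot encode
#' line style. Output is byte-deterministic for identical networks.
#'
#' @param network an `association_network` from [build_network()].
#' @param outdir output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cytoscape <- function(network, outdir) {
  stopifnot(inherits(network, "association_network"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(outdir, "edges.tsv"),
             nodes = file.path(outdir, "nodes.tsv"),
             graphml = file.path(outdir, "network.graphml"),
             sif = file.path(outdir, "network.sif"))
  edges <- network$edges
  out_e <- data.frame(source = edges$source, target = edges$target,
                      interaction = edges$edge_kind, sign = edges$sign,
                      weight = .fmt_num(edges$weight), line_style = edges$line_style,
                      stringsAsFactors = FALSE)
  utils::write.table(out_e, paths["edges"], sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- network$nodes
  out_n <- data.frame(node_id = nodes$node_id, node_kind = nodes$node_kind,
                      suggested_shape = unname(.node_shape[nodes$node_kind]),
                      suggested_color = unname(.node_color[nodes$node_kind]),
                      stringsAsFactors = FALSE)
  utils::write.table(out_n, paths["nodes"], sep = "\t", quote = FALSE, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(source = character(0), target = character(0)),
    directed = FALSE, vertices = out_n)
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  sif <- if (nrow(edges))
    paste(edges$source, edges$edge_kind, edges$target, sep = "\t") else character(0)
  writeLines(sif, paths["sif"])
  invisible(paths)
}
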