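#' Rescale a similarity rating to an edge weight
#'
#' Edge weights are an affine rescaling of the similarity rating s:
#' `e = 1 - (s - r_min) / (r_max - r_min)`, so a maximally related pair
#' (s = +7) gets weight 0, a maximally opposed pair (s = -7) gets weight 1,
#' and an unrelated pair (s = 0) gets 0.5. Interpreted as a distance:
#' smaller weight = stronger association.
#'
#' @param s rating(s) in `[r_min, r_max]`.
#' @param r_min,r_max scale endpoints (default -7 and +7).
#' @return edge weight(s) in `[0, 1]`.
#' @export
rating_to_edge_weight <- function(s, r_min = RATING_MIN, r_max = RATING_MAX) {
  if (r_min >= r_max) stopf("r_min must be < r_max")
  if (any(!is.na(s) & (s < r_min | s > r_max)))
    stopf("rating out of range [%s, %s]", format(r_min), format(r_max))
  1 - (s - r_min) / (r_max - r_min)
}

#' Inverse of [rating_to_edge_weight()]
#'
#' @param e edge weight(s) in `[0, 1]`.
#' @param r_min,r_max scale endpoints.
#' @return rating(s) on the original scale.
#' @export
edge_weight_to_rating <- function(e, r_min = RATING_MIN, r_max = RATING_MAX) {
  if (any(!is.na(e) & (e < 0 | e > 1)))
    stopf("edge weight out of range [0, 1]")
  r_min + (1 - e) * (r_max - r_min)
}

#' Per-participant edge-weight matrix of a cohort
#'
#' @param cohort a [concept_cohort()].
#' @return numeric matrix, participants x pairs, weights in `[0, 1]`.
#' @export
edge_weights <- function(cohort) {
  rating_to_edge_weight(cohort$ratings)
}

new_concept_graph <- function(concepts, edges, n_participants = NA_integer_) {
  structure(list(concepts = concepts, edges = edges,
                 n_participants = n_participants),
            class = "concept_graph")
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf("Concept graph: %d concepts, %d edges\n",
              length(x$concepts), nrow(x$edges)))
  invisible(x)
}

#' Mean concept graph
#'
#' Averages per-participant edge weights over a participant subset, giving
#' the group- or sample-level weighted concept graph.
#'
#' @param weights participants x pairs edge-weight matrix
#'   (see [edge_weights()]), or a [concept_cohort()].
#' @param pairs the `pair_index` (taken from the cohort when one is given).
#' @param subset row indices or logical mask selecting participants
#'   (default: all).
#' @return a `concept_graph` whose `edges` data frame carries the per-pair
#'   mean weight.
#' @export
mean_graph <- function(weights, pairs = NULL, subset = NULL) {
  if (inherits(weights, "concept_cohort")) {
    pairs <- weights$pairs
    weights <- edge_weights(weights)
  }
  if (is.null(pairs)) stopf("pairs index required when passing a raw matrix")
  if (is.null(subset)) subset <- seq_len(nrow(weights))
  w <- weights[subset, , drop = FALSE]
  if (nrow(w) == 0) stopf("participant subset is empty")
  edges <- data.frame(
    concept_a = pairs$concept_a, concept_b = pairs$concept_b,
    pair = pairs$pair, weight = colMeans(w),
    stringsAsFactors = FALSE, row.names = NULL)
  new_concept_graph(attr(pairs, "concepts"), edges, nrow(w))
}

#' Subgraph of significant edges
#'
#' Retains the edges flagged significant for a predictor after FDR
#' correction and tags each with the direction of the group difference. A
#' positive coefficient on the edge weight means a larger distance (weaker
#' association) for the coded group (e.g., Black = 1), so the group with the
#' stronger association is group 1 when the coefficient is negative.
#'
#' @param results an `edgewise_result` (see [run_edgewise()]).
#' @param predictor predictor name, e.g. `"race"` or `"news_bias"`.
#' @param graph optional [mean_graph()] whose weights are merged onto the
#'   retained edges.
#' @return a `concept_graph`; `edges` has columns `concept_a`, `concept_b`,
#'   `pair`, `beta`, `q_value`, `direction` (+1 = stronger association for
#'   group 1, -1 = group 0), and `weight` when `graph` is supplied. An empty
#'   subgraph is allowed.
#' @export
subgraph_from_flags <- function(results, predictor, graph = NULL) {
  tab <- results[results$predictor == predictor, , drop = FALSE]
  if (!nrow(tab))
    stopf("results carry no rows for predictor '%s'", predictor)
  sig <- tab[tab$significant, , drop = FALSE]
  edges <- data.frame(
    concept_a = sig$concept_a, concept_b = sig$concept_b, pair = sig$pair,
    beta = sig$beta, q_value = sig$q,
    direction = ifelse(sig$beta < 0, 1, -1),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(graph))
    edges$weight <- graph$edges$weight[match(edges$pair, graph$edges$pair)]
  new_concept_graph(attr(results, "concepts") %||%
                      unique(c(tab$concept_a, tab$concept_b)), edges)
}

#' Degree centrality of subgraph nodes
#'
#' For a subgraph of group-differing edges, a node's centrality is its
#' degree divided by the maximum possible degree. By default the denominator
#' is (number of nodes participating in the subgraph - 1); with
#' `denominator = "all_nodes"` it is (number of concepts in the full set - 1).
#'
#' @param graph a `concept_graph`.
#' @param denominator `"subgraph_nodes"` (default) or `"all_nodes"`.
#' @return named numeric vector of centralities in `[0, 1]` for nodes with
#'   at least one edge (isolated subgraph nodes never appear; pass them
#'   through `graph$concepts` if needed).
#' @export
degree_centrality <- function(graph,
                              denominator = c("subgraph_nodes", "all_nodes")) {
  denominator <- match.arg(denominator)
  if (!nrow(graph$edges))
    return(stats::setNames(numeric(0), character(0)))
  deg <- table(c(graph$edges$concept_a, graph$edges$concept_b))
  denom <- if (denominator == "subgraph_nodes") length(deg) - 1L
           else length(graph$concepts) - 1L
  out <- as.numeric(deg) / denom
  names(out) <- names(deg)
  sort(out, decreasing = TRUE)
}

#' Convert a concept graph to an igraph object
#'
#' @param graph a `concept_graph`.
#' @param all_nodes include concepts without edges as isolated vertices.
#' @return an `igraph` graph with edge attributes carried over.
#' @export
as_igraph <- function(graph, all_nodes = TRUE) {
  verts <- if (all_nodes) data.frame(name = graph$concepts) else NULL
  igraph::graph_from_data_frame(
    graph$edges[, setdiff(names(graph$edges), "pair"), drop = FALSE],
    directed = FALSE, vertices = verts)
}

#' Export a concept graph
#'
#' Writes a plain CSV edge list and, optionally, GraphML. Node coordinates
#' for force-directed drawings are intentionally not exported: layouts are
#' non-deterministic and belong to the plotting layer.
#'
#' @param graph a `concept_graph`.
#' @param csv_path path of the CSV edge list (or `NULL` to skip).
#' @param graphml_path path of a GraphML export (or `NULL` to skip).
#' @return invisibly, the written paths.
#' @export
write_graph_files <- function(graph, csv_path = NULL, graphml_path = NULL) {
  written <- character(0)
  if (!is.null(csv_path)) {
    utils::write.csv(graph$edges, csv_path, row.names = FALSE, quote = TRUE)
    written <- c(written, csv_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(graph), graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}
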