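#' Build the static interaction graph of a colony
#'
#' Collapses the time-ordered schedule into a simple undirected graph: nodes
#' are the ants appearing in any event, one edge per unordered pair that
#' interacted at least once. The number of events between a pair is retained
#' as the edge attribute `multiplicity` but ignored by all statistics; SOURCE
#' feedings are excluded.
#'
#' @param schedule a `colony_schedule`.
#' @return an [igraph][igraph::igraph-package] undirected simple graph with
#'   edge attribute `multiplicity`.
#' @export
build_static_graph <- function(schedule) {
  stopifnot(inherits(schedule, "colony_schedule"))
  ev <- schedule$events
  aa <- ev[ev$donor != SOURCE_LABEL, , drop = FALSE]
  nodes <- sort(unique(c(aa$donor, aa$recipient,
                         ev$recipient[ev$donor == SOURCE_LABEL])))
  if (nrow(aa) == 0) {
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(nodes))
  }
  pair <- t(apply(cbind(aa$donor, aa$recipient), 1, sort))
  key <- paste(pair[, 1], pair[, 2], sep = "\r")
  mult <- table(key)
  uniq <- do.call(rbind, strsplit(names(mult), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = uniq[, 1], to = uniq[, 2],
               multiplicity = as.integer(mult), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g
}

#' Community structure and clustering statistics of the contact graph
#'
#' Finds a maximally modular partition with greedy agglomerative modularity
#' maximisation (Clauset-Newman-Moore, via
#' [igraph::cluster_fast_greedy()]; deterministic for a given vertex order,
#' and vertices are entered in sorted label order). Reports the modularity
#' \eqn{Q} (fraction of within-community edges minus its expectation under
#' random edge placement), the number of communities, intra-/inter-community
#' edge counts, the global transitivity (3 x triangles / connected triples)
#' and, as an informational extra, the partition performance (fraction of
#' vertex pairs classified consistently with the partition). Greedy
#' maximisation is a heuristic, so community counts and Q are approximate
#' maxima; transitivity is exact.
#'
#' @param graph an undirected simple igraph, e.g. from
#'   [build_static_graph()].
#' @return list with `membership` (named integer vector), `n_communities`,
#'   `modularity`, `intra_edges`, `inter_edges`, `transitivity`,
#'   `performance`.
#' @export
community_stats <- function(graph) {
  if (igraph::ecount(graph) == 0) stop("graph has no edges")
  cl <- igraph::cluster_fast_greedy(graph)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(graph, memb)
  crossing <- igraph::crossing(cl, graph)
  inter <- sum(crossing)
  intra <- igraph::ecount(graph) - inter
  n <- igraph::vcount(graph)
  sizes <- as.integer(table(memb))
  same_pairs <- sum(choose(sizes, 2))
  total_pairs <- choose(n, 2)
  performance <- (intra + (total_pairs - same_pairs - inter)) / total_pairs
  list(
    membership = memb,
    n_communities = length(sizes),
    modularity = q,
    intra_edges = as.integer(intra),
    inter_edges = as.integer(inter),
    transitivity = igraph::transitivity(graph, type = "global"),
    performance = performance
  )
}
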