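#' Hop distances from one source node
#'
#' Breadth-first hop counts from `source` to every node. On unweighted graphs
#' this is the exact single-source shortest path; unreachable nodes get `Inf`.
#' An optional hop cutoff truncates the search frontier, the standard
#' large-network optimisation for distance-sum centralities: nodes beyond
#' `max_hops` are reported as `Inf` and thus contribute nothing to downstream
#' inverse-distance sums.
#'
#' @param g An undirected igraph graph.
#' @param source A vertex name (or index) present in `g`.
#' @param max_hops Optional non-negative hop cutoff; default `Inf` (exact).
#' @return Named numeric vector of distances, one entry per node; `dist` to
#'   the source itself is 0, unreachable nodes are `Inf`.
#' @export
bfs_distances <- function(g, source, max_hops = Inf) {
  v <- .resolve_vertex(g, source)
  d <- igraph::distances(g, v = v, algorithm = "unweighted")[1, ]
  names(d) <- .node_labels(g)
  if (is.finite(max_hops)) d[d > max_hops] <- Inf
  d
}

#' All-pairs hop distances
#'
#' Per-source BFS over the whole graph: a symmetric `N x N` matrix of hop
#' counts with `Inf` marking unreachable pairs and zeros on the diagonal.
#'
#' @inheritParams bfs_distances
#' @return Numeric matrix with node labels as dimnames.
#' @export
all_pairs_distances <- function(g, max_hops = Inf) {
  d <- igraph::distances(g, algorithm = "unweighted")
  dimnames(d) <- list(.node_labels(g), .node_labels(g))
  if (is.finite(max_hops)) d[d > max_hops] <- Inf
  d
}

.resolve_vertex <- function(g, v) {
  labels <- .node_labels(g)
  idx <- match(as.character(v), labels)
  if (is.na(idx)) stop("unknown node: ", v)
  idx
}

#' Degree of one node
#'
#' @inheritParams bfs_distances
#' @param v A vertex name present in `g`.
#' @return Integer degree (count of one-hop neighbours).
#' @export
node_degree <- function(g, v) {
  idx <- .resolve_vertex(g, v)
  as.integer(igraph::degree(g)[idx])
}
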