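#' Neighbour-degree probability distribution of a node
#'
#' The distribution underlying node entropy: each neighbour \eqn{u} of `v`
#' gets mass \eqn{p(u) = deg(u) / \sum_{k \in \Gamma(v)} deg(k)}. Probabilities
#' sum to 1 by construction.
#'
#' @param g An undirected igraph graph.
#' @param v A vertex name present in `g`, with degree \eqn{\ge 1}.
#' @return Named numeric vector of probabilities over `v`'s neighbours.
#' @export
neighbor_probabilities <- function(g, v) {
  idx <- .resolve_vertex(g, v)
  deg <- igraph::degree(g)
  nb <- as.integer(igraph::neighbors(g, idx))
  if (length(nb) == 0) stop("node ", v, " is isolated: no neighbour distribution")
  p <- deg[nb] / sum(deg[nb])
  names(p) <- .node_labels(g)[nb]
  p
}

#' Node entropy: Shannon entropy of the neighbour-degree distribution
#'
#' \deqn{e(v) = -\sum_{u \in \Gamma(v)} p(u) \log_2 p(u)} with \eqn{p} from
#' [neighbor_probabilities()]. Degree-0 nodes score 0 by convention (empty
#' sum); degree-1 nodes score 0 because their distribution is a point mass.
#' Always \eqn{0 \le e(v) \le \log_2 deg(v)}, with the maximum attained
#' exactly when all neighbour degrees are equal.
#'
#' @inheritParams neighbor_probabilities
#' @param v A vertex name, or `NULL` (default) for all nodes.
#' @return Entropy in bits: a single value, or a named vector over all nodes
#'   when `v` is `NULL`.
#' @export
node_entropy <- function(g, v = NULL) {
  if (!is.null(v)) {
    idx <- .resolve_vertex(g, v)
    return(.entropy_vector(g)[[idx]])
  }
  e <- .entropy_vector(g)
  names(e) <- .node_labels(g)
  e
}

.entropy_vector <- function(g) {
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  vapply(seq_along(adj), function(i) {
    nb <- as.integer(adj[[i]])
    if (length(nb) < 2) return(0) # point mass or empty sum
    p <- deg[nb] / sum(deg[nb])
    -sum(p * log2(p))
  }, numeric(1))
}

#' Assemble one EDDC score from its ingredients
#'
#' The pure aggregation
#' \deqn{\frac{deg_v}{N} \sum_j \frac{\sqrt{e_v + e_j}}{d_j},}
#' independent of any graph: `entropies` and `distances` supply the
#' \eqn{(e_j, d_j)} pairs for every other node. Entries at infinite distance
#' contribute 0.
#'
#' @param deg_v Degree of the focal node.
#' @param n Node count \eqn{N \ge 1} of the network.
#' @param e_v Entropy of the focal node (non-negative).
#' @param entropies Non-negative entropies \eqn{e_j} of the other nodes.
#' @param distances Hop distances \eqn{d_j \ge 1} (or `Inf`), aligned with
#'   `entropies`.
#' @return The EDDC score, a single non-negative number.
#' @export
eddc_aggregate <- function(deg_v, n, e_v, entropies, distances) {
  stopifnot(n >= 1, length(entropies) == length(distances))
  if (e_v < 0 || any(entropies < 0)) stop("entropies must be non-negative")
  if (any(distances < 1)) stop("distances must be >= 1 (or Inf)")
  fin <- is.finite(distances)
  (deg_v / n) * sum(sqrt(e_v + entropies[fin]) / distances[fin])
}

#' EDDC: Entropy Degree Distance Combination centrality
#'
#' Scores every node by combining its degree (local connectivity), the
#' entropy of its own and every other node's neighbour-degree distribution
#' (information diversity), and inverse shortest-path weighting (global
#' reach):
#' \deqn{EDDC(v) = \frac{deg(v)}{N} \sum_{j \ne v}
#'       \frac{\sqrt{e(v) + e(j)}}{dist(v, j)}.}
#' The square root makes the pairwise entropy contribution grow sublinearly,
#' preventing high-entropy clusters from dominating the ranking. Unreachable
#' pairs contribute 0; isolated nodes score 0.
#'
#' @param g An undirected igraph graph.
#' @param max_hops Optional BFS hop cutoff: distances beyond it are treated
#'   as unreachable, trading exactness for speed on large graphs. Default
#'   `Inf` (exact).
#' @return A [score_table()] with method `"eddc"`.
#' @examples
#' g <- toy_network()
#' head(rank_nodes(eddc(g)))
#' @export
eddc <- function(g, max_hops = Inf) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  e <- .entropy_vector(g)
  w <- .inv_dist(g, max_hops)
  # sqrt(e_i + e_j) for all pairs; diagonal and unreachable pairs are already
  # zeroed in w.
  s <- sqrt(outer(e, e, "+"))
  sc <- (deg / n) * rowSums(s * w)
  score_table(.node_labels(g), sc, "eddc",
              if (is.finite(max_hops)) list(max_hops = max_hops) else list())
}
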