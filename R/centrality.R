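#' Baseline node-importance measures
#'
#' The eight measures EDDC is conventionally compared against, all on simple
#' undirected graphs and all returning a [score_table()]:
#'
#' * `degree_centrality()` — direct influence, \eqn{DC(v) = |\Gamma(v)|}.
#' * `betweenness_centrality()` — fraction of shortest paths through the
#'   node, summed over unordered pairs; pairs with no connecting path
#'   contribute 0.
#' * `closeness_centrality()` — \eqn{(N-1) / \sum_j dist(v, j)}, the sum over
#'   reachable nodes only; isolated nodes score 0. `normalization =
#'   "component"` additionally scales by the reachable fraction
#'   \eqn{(n_r - 1)/(N - 1)} (Wasserman–Faust), useful on disconnected
#'   graphs.
#' * `clustering_coefficient()` — local clustering
#'   \eqn{2|E(v)| / (deg(v)(deg(v)-1))}; degree \eqn{\le 1} nodes score 0.
#' * `isolating_centrality()` — \eqn{|\{u \in \Gamma(v): deg(u) \ge
#'   \delta\}| \times deg(v)}: a hub is only critical when its neighbours
#'   themselves clear the degree threshold \eqn{\delta}.
#' * `lgc()` — local-and-global centrality
#'   \eqn{(deg(v)/N) \sum_{j \ne v} \sqrt{deg(j)} / dist(v, j)}.
#' * `k_shell()` — shell index from iterative peeling of residual degree.
#' * `clgc()` — clustering-based local-and-global:
#'   \eqn{CLC(v) \sum_{j \ne v} \sqrt{CLC(j)} / dist(v, j)}.
#' * `eclgc()` — extended CLGC: the local term
#'   \eqn{CLC(v) + \sum_{u \in \Gamma(v)} \sqrt{CLC(u)} / deg(v)} plus the
#'   same quantity of every other node, square-rooted and inverse-distance
#'   weighted.
#'
#' In every distance sum, unreachable pairs contribute 0 (\eqn{1/\infty = 0}).
#'
#' @param g An undirected igraph graph.
#' @param delta Degree threshold \eqn{\delta \ge 0} for isolating centrality
#'   (default 2).
#' @param normalization Closeness variant; see above.
#' @param max_hops Optional BFS hop cutoff for the distance-sum measures;
#'   default exact.
#' @return A [score_table()] with one row per node.
#' @name baselines
NULL

#' @rdname baselines
#' @export
degree_centrality <- function(g) {
  score_table(.node_labels(g), igraph::degree(g), "dc")
}

#' @rdname baselines
#' @export
betweenness_centrality <- function(g) {
  score_table(.node_labels(g), igraph::betweenness(g, directed = FALSE), "bc")
}

#' @rdname baselines
#' @export
closeness_centrality <- function(g, normalization = c("classic", "component")) {
  normalization <- match.arg(normalization)
  d <- all_pairs_distances(g)
  n <- nrow(d)
  cc <- apply(d, 1, function(row) {
    fin <- is.finite(row)
    s <- sum(row[fin])
    nr <- sum(fin) # includes self at distance 0
    if (s == 0) return(0) # isolated node (or N = 1)
    base <- (n - 1) / s
    if (normalization == "component") base * (nr - 1) / (n - 1) else base
  })
  score_table(.node_labels(g), cc, "cc", list(normalization = normalization))
}

#' @rdname baselines
#' @export
clustering_coefficient <- function(g) {
  clc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  score_table(.node_labels(g), clc, "clc")
}

.clc_vector <- function(g) {
  igraph::transitivity(g, type = "localundirected", isolates = "zero")
}

#' @rdname baselines
#' @export
isolating_centrality <- function(g, delta = 2) {
  stopifnot(delta >= 0)
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  # Deg_delta membership predicate; kept in one place so the convention
  # (neighbours with degree >= delta) can be swapped if needed.
  in_deg_delta <- function(idx) deg[idx] >= delta
  sc <- vapply(seq_along(adj), function(i) {
    sum(in_deg_delta(as.integer(adj[[i]]))) * deg[[i]]
  }, numeric(1))
  score_table(.node_labels(g), sc, "isc", list(delta = delta))
}

# Inverse-distance weight matrix: 1/dist off-diagonal, 0 on the diagonal and
# for unreachable pairs. Shared by every distance-sum measure.
.inv_dist <- function(g, max_hops = Inf) {
  d <- all_pairs_distances(g, max_hops = max_hops)
  w <- 1 / d
  diag(w) <- 0
  w[!is.finite(w)] <- 0
  w
}

#' @rdname baselines
#' @export
lgc <- function(g, max_hops = Inf) {
  deg <- igraph::degree(g)
  n <- igraph::vcount(g)
  w <- .inv_dist(g, max_hops)
  sc <- (deg / n) * as.numeric(w %*% sqrt(deg))
  score_table(.node_labels(g), sc, "lgc")
}

#' @rdname baselines
#' @export
k_shell <- function(g) {
  score_table(.node_labels(g), igraph::coreness(g), "kshell")
}

#' @rdname baselines
#' @export
clgc <- function(g, max_hops = Inf) {
  clc <- .clc_vector(g)
  w <- .inv_dist(g, max_hops)
  sc <- clc * as.numeric(w %*% sqrt(clc))
  score_table(.node_labels(g), sc, "clgc")
}

#' @rdname baselines
#' @export
eclgc <- function(g, max_hops = Inf) {
  clc <- .clc_vector(g)
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  local <- vapply(seq_along(adj), function(i) {
    nb <- as.integer(adj[[i]])
    clc[[i]] + if (deg[[i]] > 0) sum(sqrt(clc[nb])) / deg[[i]] else 0
  }, numeric(1))
  w <- .inv_dist(g, max_hops)
  sc <- local + as.numeric(w %*% sqrt(local))
  score_table(.node_labels(g), sc, "eclgc")
}

#' Registered centrality methods
#'
#' Maps the short method identifiers accepted throughout the package (and by
#' the command line) to the functions implementing them.
#'
#' @return Named list of functions taking `(g, ...)`.
#' @export
centrality_methods <- function() {
  list(
    dc = function(g, ...) degree_centrality(g),
    bc = function(g, ...) betweenness_centrality(g),
    cc = function(g, ...) closeness_centrality(g),
    clc = function(g, ...) clustering_coefficient(g),
    isc = function(g, delta = 2, ...) isolating_centrality(g, delta = delta),
    lgc = function(g, max_hops = Inf, ...) lgc(g, max_hops = max_hops),
    kshell = function(g, ...) k_shell(g),
    clgc = function(g, max_hops = Inf, ...) clgc(g, max_hops = max_hops),
    eclgc = function(g, max_hops = Inf, ...) eclgc(g, max_hops = max_hops),
    eddc = function(g, max_hops = Inf, ...) eddc(g, max_hops = max_hops)
  )
}

#' Compute a centrality by name
#'
#' @param g An undirected igraph graph.
#' @param method One of `names(centrality_methods())`.
#' @param ... Method parameters (`delta` for `"isc"`, `max_hops` for the
#'   distance-sum measures).
#' @return A [score_table()].
#' @export
centrality <- function(g, method, ...) {
  reg <- centrality_methods()
  if (!method %in% names(reg)) {
    stop("unknown method '", method, "'; registered methods: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[method]](g, ...)
}
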