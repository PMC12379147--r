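# Independent oracles used to cross-check the implementation. None of these
# call the package's own code paths or igraph's algorithmic routines: graphs
# come in as adjacency matrices and everything is recomputed from scratch.

adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# O(N^3) Floyd-Warshall hop distances.
fw_distances <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  dimnames(d) <- dimnames(a)
  d
}

# Exhaustive betweenness for tiny graphs: enumerate every simple path between
# each unordered pair with DFS, keep the shortest ones, and count pass-through
# nodes.
brute_betweenness <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  bc <- numeric(n)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(path) {
      cur <- path[length(path)]
      if (cur == to) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (nxt in which(a[cur, ] > 0)) {
        if (!(nxt %in% path)) walk(c(path, nxt))
      }
    }
    walk(from)
    paths
  }
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      paths <- all_paths(j, k)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      total <- length(shortest)
      for (p in shortest) {
        inner <- p[-c(1, length(p))]
        bc[inner] <- bc[inner] + 1 / total
      }
    }
  }
  bc
}

# Polynomial betweenness oracle for mid-sized graphs: per-pair shortest-path
# counts by dynamic programming over BFS levels (no path enumeration, no
# igraph::betweenness).
dp_betweenness <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  d <- fw_distances(g)
  # sp[i, j]: number of shortest i-j paths, by DP on distance.
  sp <- matrix(0, n, n)
  diag(sp) <- 1
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    for (j in ord) {
      if (j == i || !is.finite(d[i, j])) next
      preds <- which(a[, j] > 0 & d[i, ] == d[i, j] - 1)
      sp[i, j] <- sum(sp[i, preds])
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (j in seq_len(n - 1)) {
      for (k in (j + 1):n) {
        if (v == j || v == k || !is.finite(d[j, k])) next
        if (d[j, v] + d[v, k] == d[j, k]) {
          bc[v] <- bc[v] + sp[j, v] * sp[v, k] / sp[j, k]
        }
      }
    }
  }
  bc
}

# Naive iterative peeling: recompute residual degrees from scratch each pass.
naive_kshell <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  shell <- rep(NA_real_, n)
  alive <- rep(TRUE, n)
  k <- 0
  while (any(alive)) {
    repeat {
      deg <- rowSums(a[, alive, drop = FALSE])[alive]
      victims <- which(alive)[deg <= k]
      if (length(victims) == 0) break
      shell[victims] <- k
      alive[victims] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1
  }
  shell
}

naive_clustering <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] > 0)
    if (length(nb) < 2) return(0)
    links <- sum(a[nb, nb]) / 2
    2 * links / (length(nb) * (length(nb) - 1))
  }, numeric(1))
}

naive_entropy <- function(g) {
  a <- adj_matrix(g)
  deg <- rowSums(a)
  vapply(seq_len(nrow(a)), function(v) {
    nb <- which(a[v, ] > 0)
    if (length(nb) < 2) return(0)
    p <- deg[nb] / sum(deg[nb])
    -sum(p * log2(p))
  }, numeric(1))
}

# Distance-sum measures by per-node double loops over the FW distance table.
naive_lgc <- function(g) {
  a <- adj_matrix(g)
  deg <- rowSums(a)
  n <- nrow(a)
  d <- fw_distances(g)
  vapply(seq_len(n), function(v) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != v && is.finite(d[v, j])) s <- s + sqrt(deg[j]) / d[v, j]
    }
    deg[v] / n * s
  }, numeric(1))
}

naive_clgc <- function(g) {
  clc <- naive_clustering(g)
  n <- length(clc)
  d <- fw_distances(g)
  vapply(seq_len(n), function(v) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != v && is.finite(d[v, j])) s <- s + sqrt(clc[j]) / d[v, j]
    }
    clc[v] * s
  }, numeric(1))
}

naive_eclgc <- function(g) {
  a <- adj_matrix(g)
  clc <- naive_clustering(g)
  deg <- rowSums(a)
  n <- nrow(a)
  d <- fw_distances(g)
  loc <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] > 0)
    clc[v] + if (deg[v] > 0) sum(sqrt(clc[nb])) / deg[v] else 0
  }, numeric(1))
  vapply(seq_len(n), function(v) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != v && is.finite(d[v, j])) s <- s + sqrt(loc[j]) / d[v, j]
    }
    loc[v] + s
  }, numeric(1))
}

naive_eddc <- function(g) {
  a <- adj_matrix(g)
  deg <- rowSums(a)
  n <- nrow(a)
  e <- naive_entropy(g)
  d <- fw_distances(g)
  vapply(seq_len(n), function(v) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != v && is.finite(d[v, j])) s <- s + sqrt(e[v] + e[j]) / d[v, j]
    }
    deg[v] / n * s
  }, numeric(1))
}

# Brute-force Kendall tau-a: explicit pair loop.
kendall_brute <- function(x, y) {
  n <- length(x)
  nc <- 0
  nd <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      prod <- (x[j] - x[i]) * (y[j] - y[i])
      if (prod > 0) nc <- nc + 1
      if (prod < 0) nd <- nd + 1
    }
  }
  (nc - nd) / (0.5 * n * (n - 1))
}

# Small named graphs used across tests (vertex names "1".."n").
named_graph <- function(el, n = max(el)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
}

path_graph <- function(n) named_graph(cbind(1:(n - 1), 2:n))
star_graph <- function(n) named_graph(cbind(1, 2:n), n) # centre is node 1
complete_graph <- function(n) named_graph(t(utils::combn(n, 2)), n)
cycle_graph <- function(n) named_graph(cbind(1:n, c(2:n, 1)), n)

# Seeded ER test graph with vertex names (wrapper over the package generator;
# used only to *produce* fixtures, never as the oracle).
er_fixture <- function(n, p, seed) erdos_renyi(n, p, seed = seed)
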