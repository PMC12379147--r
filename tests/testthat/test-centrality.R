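two_triangles <- function() {
  # 1-2-3 triangle and 4-5-6 triangle, bridged by edge 3-4
  named_graph(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4)))
}

test_that("degree centrality: toy node 2, stars, cliques, adjacency row sums", {
  expect_equal(node_degree(toy_network(), 2), 4)
  s <- degree_centrality(star_graph(5))
  expect_equal(s$score[s$node == "1"], 4)
  expect_true(all(s$score[s$node != "1"] == 1))
  expect_true(all(degree_centrality(complete_graph(5))$score == 4))
  g <- er_fixture(30, 0.1, seed = 1)
  expect_equal(degree_centrality(g)$score, unname(rowSums(adj_matrix(g))))
})

test_that("betweenness: path midpoints, cliques, and the enumeration oracle", {
  s <- betweenness_centrality(path_graph(3))
  expect_equal(s$score[s$node == "2"], 1)
  expect_equal(s$score[s$node %in% c("1", "3")], c(0, 0))
  expect_true(all(betweenness_centrality(complete_graph(4))$score == 0))
  for (seed in 1:8) {
    g <- er_fixture(7, 0.4, seed = seed)
    expect_equal(betweenness_centrality(g)$score, brute_betweenness(g),
                 tolerance = 1e-9)
  }
})

test_that("closeness: path, cliques, disconnected convention, oracle", {
  s <- closeness_centrality(path_graph(3))
  expect_equal(s$score[s$node == "2"], 1.0)
  expect_true(all(closeness_centrality(complete_graph(6))$score == 1.0))
  # isolated node scores 0, others normalise by N - 1 as printed
  g <- named_graph(rbind(c(1, 2)), n = 3)
  s <- closeness_centrality(g)
  expect_equal(s$score[s$node == "3"], 0)
  expect_equal(s$score[s$node == "1"], 2 / 1) # (N-1)/dist sum over reachable
  # component normalization scales by reachable fraction
  sc <- closeness_centrality(g, normalization = "component")
  expect_equal(sc$score[sc$node == "1"], (2 / 1) * (1 / 2))
  g <- er_fixture(25, 0.15, seed = 2)
  d <- fw_distances(g)
  expected <- apply(d, 1, function(r) {
    s <- sum(r[is.finite(r)])
    if (s == 0) 0 else (nrow(d) - 1) / s
  })
  expect_equal(closeness_centrality(g)$score, unname(expected))
})

test_that("local clustering: triangles, stars, brute-force neighbour pairs", {
  expect_true(all(clustering_coefficient(complete_graph(3))$score == 1.0))
  s <- clustering_coefficient(star_graph(5))
  expect_true(all(s$score == 0))
  g <- er_fixture(30, 0.2, seed = 4)
  expect_equal(clustering_coefficient(g)$score, naive_clustering(g),
               tolerance = 1e-12)
})

test_that("isolating centrality follows the degree-threshold convention", {
  s <- isolating_centrality(star_graph(5), delta = 2)
  expect_equal(s$score[s$node == "1"], 0) # no neighbour has degree >= 2
  expect_true(all(isolating_centrality(complete_graph(4), delta = 2)$score == 9))
  g <- er_fixture(20, 0.2, seed = 5)
  s0 <- isolating_centrality(g, delta = 0)
  expect_equal(s0$score, unname(igraph::degree(g)^2)) # Deg_0 holds every node
  expect_equal(attr(s0, "params")$delta, 0)
  expect_error(isolating_centrality(g, delta = -1))
})

test_that("LGC: closed forms on K2 and a star, naive oracle on random graphs", {
  expect_equal(lgc(complete_graph(2))$score, c(0.5, 0.5))
  s <- lgc(star_graph(3))
  expect_equal(s$score[s$node == "1"], (2 / 3) * (sqrt(1) + sqrt(1)))
  g <- er_fixture(25, 0.15, seed = 6)
  expect_equal(lgc(g)$score, naive_lgc(g), tolerance = 1e-9)
})

test_that("k-shell peeling: cycles, stars, naive peeling oracle", {
  expect_true(all(k_shell(cycle_graph(6))$score == 2))
  expect_true(all(k_shell(star_graph(5))$score == 1))
  g <- er_fixture(40, 0.1, seed = 7)
  expect_equal(k_shell(g)$score, naive_kshell(g))
  expect_true(all(k_shell(g)$score <= igraph::degree(g)))
})

test_that("CLGC: zero on trees, hand value on bridged triangles, oracle", {
  expect_true(all(clgc(path_graph(5))$score == 0))
  expect_true(all(clgc(star_graph(6))$score == 0))
  s <- clgc(two_triangles())
  r3 <- sqrt(1 / 3)
  # node 1: CLC 1; others at distances (1,1,2,3,3) with CLC (1, 1/3, 1/3, 1, 1)
  expect_equal(s$score[s$node == "1"],
               1 * (1 / 1 + r3 / 1 + r3 / 2 + 1 / 3 + 1 / 3))
  # node 3: CLC 1/3; others at distances (1,1,1,2,2) with CLC (1, 1, 1/3, 1, 1)
  expect_equal(s$score[s$node == "3"],
               (1 / 3) * (1 + 1 + r3 + 1 / 2 + 1 / 2))
  g <- er_fixture(25, 0.2, seed = 8)
  expect_equal(clgc(g)$score, naive_clgc(g), tolerance = 1e-9)
})

test_that("ECLGC: zero on trees, closed form on a triangle, oracle", {
  expect_true(all(eclgc(path_graph(4))$score == 0))
  expect_equal(eclgc(complete_graph(3))$score,
               rep(1 + 1 + 2 * sqrt(2), 3))
  g <- er_fixture(20, 0.2, seed = 9)
  expect_equal(eclgc(g)$score, naive_eclgc(g), tolerance = 1e-9)
})

test_that("rank_nodes orders by descending score with label tie-break", {
  s <- score_table(c("a", "b", "c"), c(2, 1, 3), "toy")
  expect_equal(rank_nodes(s)$node, c("c", "a", "b"))
  s <- score_table(c("10", "2", "1"), c(1, 1, 1), "toy")
  expect_equal(rank_nodes(s)$node, c("1", "2", "10")) # numeric label order
  # round-trip: ranking a permuted table gives the same order
  set.seed(11)
  s <- score_table(as.character(1:20), runif(20), "toy")
  perm <- sample(20)
  s2 <- score_table(s$node[perm], s$score[perm], "toy")
  expect_equal(rank_nodes(s), rank_nodes(s2))
})

test_that("centrality registry dispatches and rejects unknown names", {
  g <- toy_network()
  expect_equal(centrality(g, "dc")$score, degree_centrality(g)$score)
  expect_equal(centrality(g, "isc", delta = 3)$score,
               isolating_centrality(g, 3)$score)
  expect_error(centrality(g, "pagerank"), "registered methods")
})

test_that("distance-sum centralities are invariant under node relabeling", {
  g <- er_fixture(20, 0.2, seed = 10)
  set.seed(1)
  new_labels <- sample(sprintf("x%02d", 1:20))
  h <- igraph::set_vertex_attr(g, "name", value = new_labels)
  for (fn in list(closeness_centrality, lgc, clgc, eclgc, eddc)) {
    s1 <- fn(g)
    s2 <- fn(h)
    expect_equal(s2$score[match(new_labels, s2$node)],
                 s1$score[match(igraph::V(g)$name, s1$node)],
                 tolerance = 1e-12)
  }
})

test_that("every measure is constant on vertex-transitive graphs", {
  for (g in list(cycle_graph(7), complete_graph(5))) {
    for (m in names(centrality_methods())) {
      sc <- centrality(g, m)$score
      expect_lt(diff(range(sc)), 1e-12)
    }
  }
})
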