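test_that("build_graph induces, dedupes, drops loops and isolates", {
  et <- data.frame(node_a = c("A", "B", "C", "A"),
                   node_b = c("B", "A", "C", "X"),
                   score = NA_real_, stringsAsFactors = FALSE)
  g <- build_graph(et, risk_genes = c("A", "B", "C"))
  expect_equal(g$nodes, c("A", "B"))   # C only had a loop, X not a risk gene
  expect_equal(g$n_edges, 1L)
  expect_equal(g$adj$A, "B")
  # handshake: sum of degrees = 2E
  set.seed(3)
  for (i in 1:10) {
    et <- random_edge_table(10, 0.3)
    g <- build_graph(et)
    expect_equal(sum(graph_degree(g)), 2L * g$n_edges)
    expect_equal(2 * g$n_edges / length(g$nodes),
                 network_summary(g)$mean_degree)
  }
})

test_that("clustering coefficient matches the closed forms on canonical graphs", {
  k3 <- graph_of("A-B", "B-C", "A-C")
  expect_equal(unname(clustering_coefficient(k3)), rep(1, 3))
  expect_equal(network_summary(k3)$network_clustering_coefficient, 1)
  path <- graph_of("A-B", "B-C")
  expect_equal(clustering_coefficient(path, "B"), c(B = 0))
  expect_error(clustering_coefficient(path, "Z"), "unknown node")
})

test_that("shortest-path census and characteristic path length match enumeration", {
  k3 <- graph_of("A-B", "B-C", "A-C")
  expect_equal(shortest_path_census(k3)$characteristic_path_length, 1)
  path <- graph_of("A-B", "B-C")
  cen <- shortest_path_census(path)
  expect_equal(cen$dist["A", "C"], 2L)
  expect_equal(cen$characteristic_path_length, 4 / 3)
  # star S4: one path of length 2 between two leaves, through the center
  s4 <- graph_of("hub-L1", "hub-L2", "hub-L3")
  cs <- shortest_path_census(s4)
  expect_equal(cs$sigma["L1", "L2"], 1)
  expect_equal(cs$dist["L1", "L2"], 2L)
  expect_equal(paths_through(cs, "L1", "L2", "hub"), 1)
  expect_equal(paths_through(cs, "L1", "L2", "L3"), 0)
})

test_that("betweenness matches hand enumeration on canonical graphs", {
  path <- graph_of("A-B", "B-C")
  expect_equal(betweenness_centrality(path, "B"), c(B = 2))
  expect_equal(betweenness_centrality(path, "A"), c(A = 0))
  k3 <- graph_of("A-B", "B-C", "A-C")
  expect_equal(unname(betweenness_centrality(k3)), rep(0, 3))
  # 4-cycle: each middle pair has 2 shortest paths, each ordered pair
  # contributes 1/2 through a given node -> B(v) = 1 for all
  c4 <- graph_of("A-B", "B-C", "C-D", "D-A")
  expect_equal(unname(betweenness_centrality(c4)), rep(1, 4))
})

test_that("topology metrics equal brute-force enumeration on random small graphs", {
  set.seed(11)
  n_checked <- 0L
  while (n_checked < 60L) {
    n <- sample(4:7, 1)
    et <- random_edge_table(n, stats::runif(1, 0.3, 0.8))
    if (nrow(et) == 0) next
    g <- build_graph(et)
    if (length(g$nodes) < 3) next
    A <- adj_matrix(et, g$nodes)
    if (!is_connected_matrix(A)) next
    n_checked <- n_checked + 1L
    cen <- shortest_path_census(g)
    for (v in g$nodes) {
      expect_equal(unname(clustering_coefficient(g, v)), bf_clustering(A, v))
      expect_equal(unname(betweenness_centrality(g, v)), bf_betweenness(A, v))
      expect_equal(unname(topological_coefficient(g, v)),
                   bf_topological_coefficient(A, v))
    }
    expect_equal(cen$characteristic_path_length,
                 bf_characteristic_path_length(A))
    # spot-check the full path census on one random pair
    st <- sample(g$nodes, 2)
    bf <- bf_path_census(A, st[1], st[2])
    expect_equal(unname(cen$dist[st[1], st[2]]), bf$length)
    expect_equal(unname(cen$sigma[st[1], st[2]]), bf$count)
  }
})

test_that("betweenness and clustering agree with igraph conventions", {
  set.seed(21)
  et <- random_edge_table(15, 0.25)
  g <- build_graph(et)
  ig <- igraph::graph_from_data_frame(et[et$node_a %in% g$nodes &
                                           et$node_b %in% g$nodes, 1:2],
                                      directed = FALSE,
                                      vertices = g$nodes)
  ig <- igraph::simplify(ig)
  # ordered-pair betweenness is twice igraph's unordered convention
  expect_equal(unname(betweenness_centrality(g)),
               unname(2 * igraph::betweenness(ig)[g$nodes]))
  cc_ig <- igraph::transitivity(ig, type = "localundirected",
                                vids = g$nodes, isolates = "zero")
  expect_equal(unname(clustering_coefficient(g)), unname(cc_ig))
})

test_that("betweenness sums match the tree identity when paths are unique", {
  # on a tree every pair has exactly one shortest path, so
  # sum_v B(v) = sum over ordered connected pairs of (path length - 1)
  tree <- graph_of("A-B", "B-C", "B-D", "D-E", "D-F")
  cen <- shortest_path_census(tree)
  lhs <- sum(betweenness_centrality(tree))
  D <- cen$dist
  off <- D[row(D) != col(D)]
  rhs <- sum(off[!is.na(off)] - 1L)
  expect_equal(lhs, rhs)
})

test_that("topological coefficient matches hand evaluation on stars and cliques", {
  k3 <- graph_of("A-B", "B-C", "A-C")
  expect_equal(unname(topological_coefficient(k3)), rep(1, 3))
  s4 <- graph_of("hub-L1", "hub-L2", "hub-L3")
  expect_equal(topological_coefficient(s4, "L1"), c(L1 = 0))  # degree 1
  # two leaves sharing the hub, leaf degree 1 -> convention 0; hub has
  # degree 3 but shares no neighbor with anyone (leaves have only the hub)
  expect_equal(topological_coefficient(s4, "hub"), c(hub = 0))
  # square with a diagonal: hand evaluation
  g <- graph_of("A-B", "B-C", "C-D", "D-A", "A-C")
  # N(B) = {A, C}; partners sharing a neighbor with B: A (shares C),
  # C (shares A), D (shares A and C)
  # J(B,A) = |{A,C} n {B,C,D}| + 1 = 2; J(B,C) = 2; J(B,D) = 2
  expect_equal(topological_coefficient(g, "B"), c(B = 1))
})

test_that("degree distribution histogram and slope behave as specified", {
  k4 <- graph_of("A-B", "A-C", "A-D", "B-C", "B-D", "C-D")
  dd <- degree_distribution(k4)
  expect_equal(dd$histogram, data.frame(degree = 3L, count = 4L))
  expect_true(is.na(dd$loglog_slope))
  expect_equal(sum(dd$histogram$count), length(k4$nodes))
  # preferential-attachment graphs have decreasing degree histograms
  spec <- sim_spec(seed = 9, n_snps = 500, n_causal = 10, n_genes = 600,
                   ppi_background_nodes = 500,
                   planted_modules = list(list(size = 4, density = 1.0)))
  ppi <- simulate_ppi(spec)
  g <- build_graph(ppi$edge_table)
  slope <- degree_distribution(g)$loglog_slope
  expect_true(slope < 0)
  expect_equal(sum(degree_distribution(g)$histogram$count), length(g$nodes))
})

test_that("hub selection applies the strict degree threshold with stable order", {
  # A has degree 18, B degree 17, C low
  spokes_a <- sprintf("a%02d", 1:18)
  spokes_b <- sprintf("b%02d", 1:17)
  et <- data.frame(node_a = c(rep("A", 18), rep("B", 17), "C"),
                   node_b = c(spokes_a, spokes_b, "a01"),
                   score = NA_real_, stringsAsFactors = FALSE)
  g <- build_graph(et)
  hubs <- select_hubs(g, 17)
  expect_equal(hubs$gene_id, "A")   # strict: degree 17 excluded
  all_nodes <- select_hubs(g, 0)
  expect_equal(nrow(all_nodes), length(g$nodes))
  expect_equal(all_nodes$gene_id[1:2], c("A", "B"))  # desc degree, then id
})
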