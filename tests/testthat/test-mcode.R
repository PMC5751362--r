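complete_graph <- function(ids) {
  prs <- utils::combn(ids, 2)
  build_graph(data.frame(node_a = prs[1, ], node_b = prs[2, ],
                         score = NA_real_, stringsAsFactors = FALSE))
}

test_that("k-core numbers match hand peeling", {
  k4 <- complete_graph(c("A", "B", "C", "D"))
  expect_equal(unname(core_numbers(k4)), rep(3L, 4))
  path <- graph_of("A-B", "B-C")
  expect_equal(unname(core_numbers(path)), rep(1L, 3))
  # K5 plus a pendant: clique nodes core 4, pendant core 1
  et <- utils::combn(c("A", "B", "C", "D", "E"), 2)
  edges <- data.frame(node_a = c(et[1, ], "E"), node_b = c(et[2, ], "P"),
                      score = NA_real_, stringsAsFactors = FALSE)
  g <- build_graph(edges)
  cn <- core_numbers(g)
  expect_equal(unname(cn[c("A", "B", "C", "D", "E")]), rep(4L, 5))
  expect_equal(cn[["P"]], 1L)
  # cross-check against igraph's coreness on a random graph
  set.seed(8)
  et2 <- random_edge_table(20, 0.2)
  g2 <- build_graph(et2)
  ig <- igraph::simplify(igraph::graph_from_data_frame(
    et2[, 1:2], directed = FALSE, vertices = g2$nodes))
  expect_equal(unname(core_numbers(g2)),
               unname(igraph::coreness(ig)[g2$nodes]))
})

test_that("vertex weights equal hand evaluation of the closed-neighborhood core", {
  k4 <- complete_graph(c("A", "B", "C", "D"))
  expect_equal(unname(vertex_weight(k4)), rep(3, 4))
  pair <- graph_of("A-B")
  expect_equal(vertex_weight(pair, "A"), c(A = 1))
  # isolated node inside a subset-induced graph
  g <- gwashub:::.induced(graph_of("A-B", "C-D"), c("A", "B", "C"))
  expect_equal(vertex_weight(g, "C"), c(C = 0))
  # isomorphism invariance: relabeled graph gives identical sorted weights
  set.seed(14)
  et <- random_edge_table(12, 0.3)
  g1 <- build_graph(et)
  perm <- setNames(sprintf("z%02d", sample(seq_along(g1$nodes))), g1$nodes)
  et2 <- data.frame(node_a = unname(perm[et$node_a]),
                    node_b = unname(perm[et$node_b]),
                    score = NA_real_, stringsAsFactors = FALSE)
  g2 <- build_graph(et2)
  w1 <- vertex_weight(g1); w2 <- vertex_weight(g2)
  expect_equal(unname(w2[unname(perm[names(w1)])]), unname(w1))
})

test_that("cluster score reproduces the published module scores", {
  # density x size on the five printed (nodes, edges) pairs
  expect_equal(cluster_score(20, 190), 20)
  expect_equal(round(cluster_score(21, 61), 1), 6.1)
  expect_equal(round(cluster_score(13, 33), 1), 5.5)
  expect_equal(round(cluster_score(12, 23), 3), 4.182)
  expect_equal(cluster_score(3, 3), 3)
  expect_error(cluster_score(1, 0), "n_nodes >= 2")
  expect_error(cluster_score(4, 7), "exceeds")
})

test_that("find_complexes separates disjoint triangles and handles empty graphs", {
  g <- graph_of("A-B", "B-C", "A-C", "X-Y", "Y-Z", "X-Z")
  cl <- find_complexes(g)
  expect_length(cl, 2L)
  expect_equal(sort(vapply(cl, function(x) paste(x$members, collapse = ""), "")),
               c("ABC", "XYZ"))
  expect_equal(vapply(cl, function(x) x$score, 0), c(3, 3))
  # a standalone triangle is fully symmetric: tie -> no core hub
  expect_true(all(is.na(vapply(cl, function(x) x$core_hub, ""))))
  expect_equal(cl[[1]]$tied, cl[[1]]$members)
  expect_equal(find_complexes(build_graph(data.frame(node_a = character(),
                                                     node_b = character()))),
               list())
})

test_that("reported cluster bookkeeping is internally consistent", {
  set.seed(31)
  spec <- sim_spec(seed = 31, n_snps = 800, n_causal = 30, n_genes = 400,
                   ppi_background_nodes = 250)
  g <- build_graph(simulate_ppi(spec)$edge_table)
  cl <- find_complexes(g)
  expect_true(length(cl) >= 1)
  seen <- character(0)
  scores <- vapply(cl, function(x) x$score, 0)
  expect_equal(scores, sort(scores, decreasing = TRUE))
  for (x in cl) {
    expect_equal(x$n_nodes, length(x$members))
    expect_equal(x$n_edges, gwashub:::.edge_count(g, x$members))
    expect_equal(x$score, x$density * x$n_nodes)
    expect_equal(x$density, 2 * x$n_edges / (x$n_nodes * (x$n_nodes - 1)))
    if (!is.na(x$core_hub)) expect_true(x$core_hub %in% x$members)
    # no overlap without fluff
    expect_length(intersect(seen, x$members), 0L)
    seen <- c(seen, x$members)
    # every cluster contains a 2-core (default k_core = 2)
    expect_true(max(core_numbers(gwashub:::.induced(g, x$members))) >= 2)
  }
})

test_that("planted K8 is recovered nearly exactly in a scale-free background", {
  spec <- sim_spec(seed = 4, n_snps = 800, n_causal = 30, n_genes = 600,
                   ppi_background_nodes = 300,
                   planted_modules = list(list(size = 8, density = 1.0)))
  ppi <- simulate_ppi(spec)
  g <- build_graph(ppi$edge_table)
  cl <- find_complexes(g)
  planted <- ppi$truth$modules[[1]]$members
  jacc <- vapply(cl, function(x)
    length(intersect(x$members, planted)) / length(union(x$members, planted)),
    0)
  expect_true(max(jacc) >= 0.9)
})

test_that("core hub designation requires a strict maximum", {
  # path A-B-C: the endpoints see a K2 neighborhood (weight 1) while B sees
  # the whole path (weight 2/3) -> A and C tie at the maximum, no core hub
  path <- graph_of("A-B", "B-C")
  ch <- core_hub(path, c("A", "B", "C"))
  expect_true(is.na(ch$core_hub))
  expect_equal(ch$tied, c("A", "C"))
  # distinct weights: unique winner (triangle member A weighs 2, pendant D 1)
  g <- graph_of("A-B", "B-C", "A-C", "C-D")
  ch2 <- core_hub(g, c("A", "D"))
  expect_equal(ch2$core_hub, "A")
  # singleton cluster designates its only member
  ch3 <- core_hub(g, "D")
  expect_equal(ch3$core_hub, "D")
})

test_that("with node_score_cutoff 0 every cluster stays in the seed's component", {
  set.seed(17)
  et <- rbind(random_edge_table(8, 0.5),
              data.frame(node_a = c("q1", "q2", "q1"), node_b = c("q2", "q3", "q3"),
                         score = NA_real_, stringsAsFactors = FALSE))
  g <- build_graph(et)
  cl <- find_complexes(g, mcode_params(node_score_cutoff = 0))
  for (x in cl) {
    comps <- unique(g$components[x$members])
    expect_length(comps, 1L)
  }
})
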