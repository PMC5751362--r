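#' MCODE parameters
#'
#' Defaults mirror the Cytoscape MCODE plugin defaults: loops excluded,
#' degree cutoff 2, node score cutoff 0.2, k-core 2, haircut on, fluff off,
#' maximum search depth 100.
#'
#' @param include_loops ignored placeholder (graphs here are always simple).
#' @param degree_cutoff minimum degree for a node to seed a cluster.
#' @param node_score_cutoff fraction in \[0, 1\]; a neighbor joins a cluster
#'   when its vertex weight is at least `(1 - node_score_cutoff)` times the
#'   seed weight.
#' @param k_core a reported cluster must contain a k-core of this order.
#' @param haircut iteratively remove singly-connected cluster members.
#' @param fluff add boundary neighbors whose closed-neighborhood density
#'   exceeds `fluff_density_cutoff` (may create overlapping clusters).
#' @param fluff_density_cutoff density threshold for fluff.
#' @param max_depth maximum breadth-first expansion depth from the seed.
#' @return list of parameters with class `mcode_params`.
#' @export
mcode_params <- function(include_loops = FALSE, degree_cutoff = 2,
                         node_score_cutoff = 0.2, k_core = 2,
                         haircut = TRUE, fluff = FALSE,
                         fluff_density_cutoff = 0.0, max_depth = 100) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1,
            degree_cutoff >= 0, k_core >= 0, max_depth >= 1)
  structure(list(include_loops = include_loops, degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff, k_core = k_core,
                 haircut = haircut, fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff,
                 max_depth = max_depth),
            class = "mcode_params")
}

#' k-core numbers
#'
#' Standard k-core decomposition by iterative minimum-degree peeling: the
#' core number of a node is the largest k such that it belongs to a subgraph
#' in which every node has degree >= k.
#'
#' @param graph an `interaction_graph`.
#' @return named integer vector of core numbers.
#' @export
core_numbers <- function(graph) {
  deg <- graph_degree(graph)
  core <- stats::setNames(rep(0L, length(deg)), names(deg))
  alive <- names(deg)
  k <- 0L
  while (length(alive)) {
    repeat {
      low <- alive[deg[alive] <= k]
      if (length(low) == 0L) break
      core[low] <- k
      for (v in low) {
        nb <- intersect(graph$adj[[v]], alive)
        deg[nb] <- deg[nb] - 1L
      }
      alive <- setdiff(alive, low)
    }
    k <- k + 1L
  }
  core
}

.density <- function(n_nodes, n_edges) {
  if (n_nodes < 2L) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

.edge_count <- function(graph, nodes) {
  sum(vapply(nodes, function(v)
    sum(graph$adj[[v]] %in% nodes), 0L)) %/% 2L
}

#' MCODE vertex weight (node score)
#'
#' The weight of v is computed on the subgraph induced by its closed
#' neighborhood N\[v\]: find that subgraph's highest k-core; the weight is
#' k_max times the density of the k_max-core subgraph.  An isolated node
#' scores 0.
#'
#' @param graph an `interaction_graph`.
#' @param v node ids (default: all nodes).
#' @return named numeric vector of weights.
#' @export
vertex_weight <- function(graph, v = graph$nodes) {
  .check_nodes(graph, v)
  out <- vapply(v, function(u) {
    nb <- graph$adj[[u]]
    if (length(nb) == 0L) return(0)
    sub <- .induced(graph, c(u, nb))
    cn <- core_numbers(sub)
    kmax <- max(cn)
    if (kmax == 0L) return(0)
    core_nodes <- names(cn)[cn == kmax]
    e <- .edge_count(sub, core_nodes)
    kmax * .density(length(core_nodes), e)
  }, 0)
  stats::setNames(out, v)
}

#' MCODE cluster score
#'
#' Density times size: score = (2E / (N (N - 1))) * N, where N is the
#' number of cluster members and E the number of edges among them.
#'
#' @param n_nodes number of cluster members (>= 2).
#' @param n_edges number of edges within the cluster.
#' @return numeric score.
#' @examples
#' cluster_score(20, 190)  # complete module: 20
#' cluster_score(3, 3)     # triangle: 3
#' @export
cluster_score <- function(n_nodes, n_edges) {
  if (any(n_nodes < 2L)) stop("cluster_score requires n_nodes >= 2")
  if (any(n_edges > choose(n_nodes, 2))) {
    stop("n_edges exceeds the maximum for n_nodes")
  }
  .density(n_nodes, n_edges) * n_nodes
}

#' Core hub of a cluster
#'
#' The member with strictly maximal MCODE vertex weight, weights computed on
#' the full analyzed graph.  When the maximum is attained by two or more
#' members there is no core hub (a tie designates nothing); the tied set is
#' returned for reporting.
#'
#' @param graph the `interaction_graph` the clusters were detected on.
#' @param members character vector of cluster member node ids.
#' @param weights optional precomputed vertex weights (named, covering
#'   `members`).
#' @return list with `core_hub` (gene id or `NA`) and `tied` (character
#'   vector of tied members when no unique maximum exists).
#' @export
core_hub <- function(graph, members, weights = NULL) {
  stopifnot(length(members) >= 1L)
  if (is.null(weights)) weights <- vertex_weight(graph, members)
  w <- weights[members]
  top <- members[w == max(w)]
  if (length(top) == 1L) list(core_hub = top, tied = character(0))
  else list(core_hub = NA_character_, tied = sort(top))
}

.haircut <- function(graph, members) {
  repeat {
    deg_in <- vapply(members, function(v)
      sum(graph$adj[[v]] %in% members), 0L)
    drop <- members[deg_in < 2L]
    if (length(drop) == 0L || length(members) <= 1L) break
    members <- setdiff(members, drop)
    if (length(members) == 0L) break
  }
  members
}

#' MCODE-style molecular complex detection
#'
#' Nodes are weighted with [vertex_weight()] and visited in descending
#' weight order (ties by node id) as cluster seeds, skipping nodes already
#' claimed by an earlier cluster.  From each seed, neighbors whose weight is
#' at least `(1 - node_score_cutoff)` times the seed weight are included
#' breadth-first up to `max_depth`.  Post-processing: clusters that do not
#' contain a k-core of order `k_core` are discarded; haircut iteratively
#' removes singly-connected members; fluff (off by default) adds boundary
#' neighbors whose closed-neighborhood density exceeds
#' `fluff_density_cutoff`.  Clusters are reported in descending score order,
#' ties broken by the ascending smallest member id.  Each node belongs to at
#' most one cluster (first claim wins) unless fluff adds overlap.
#'
#' @param graph an `interaction_graph`.
#' @param params an [mcode_params()] object.
#' @return list of clusters; each is a list with `members`, `n_nodes`,
#'   `n_edges`, `density`, `score`, `seed_node`, `core_hub`, `tied`.
#' @export
find_complexes <- function(graph, params = mcode_params()) {
  if (length(graph$nodes) == 0L) return(list())
  w <- vertex_weight(graph)
  deg <- graph_degree(graph)
  seeds <- graph$nodes[order(-w[graph$nodes], graph$nodes)]
  seeds <- seeds[deg[seeds] >= params$degree_cutoff & w[seeds] > 0]
  assigned <- character(0)
  clusters <- list()
  for (seed in seeds) {
    if (seed %in% assigned) next
    threshold <- (1 - params$node_score_cutoff) * w[[seed]]
    members <- seed
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      cand <- unique(unlist(graph$adj[frontier], use.names = FALSE))
      cand <- setdiff(cand, c(members, assigned))
      cand <- cand[w[cand] >= threshold]
      members <- c(members, cand)
      frontier <- cand
      depth <- depth + 1L
    }
    assigned <- c(assigned, members)
    # k-core containment check
    sub_cn <- core_numbers(.induced(graph, members))
    if (max(c(sub_cn, 0L)) < params$k_core) {
      if (!(length(members) == 1L && params$k_core <= 1L)) next
    }
    if (params$haircut) members <- .haircut(graph, members)
    if (length(members) == 0L) next
    if (params$fluff) {
      boundary <- setdiff(unique(unlist(graph$adj[members], use.names = FALSE)),
                          members)
      add <- boundary[vapply(boundary, function(v) {
        nbv <- c(v, graph$adj[[v]])
        .density(length(nbv), .edge_count(graph, nbv)) >
          params$fluff_density_cutoff
      }, TRUE)]
      members <- c(members, add)
    }
    members <- sort(members)
    n <- length(members)
    e <- .edge_count(graph, members)
    ch <- core_hub(graph, members, weights = w)
    clusters[[length(clusters) + 1L]] <- list(
      members = members, n_nodes = n, n_edges = e,
      density = .density(n, e),
      score = if (n >= 2L) cluster_score(n, e) else 0,
      seed_node = seed, core_hub = ch$core_hub, tied = ch$tied
    )
  }
  if (length(clusters) == 0L) return(clusters)
  sc <- vapply(clusters, function(x) x$score, 0)
  first <- vapply(clusters, function(x) x$members[[1L]], "")
  clusters[order(-sc, first)]
}
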