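# Simple undirected graph stored as sorted adjacency lists keyed by node id.
# No self-loops, no parallel edges; adjacency is symmetric by construction.

.new_graph <- function(adj) {
  if (length(adj) == 0L) adj <- structure(list(), names = character(0))
  adj <- adj[order(names(adj))]
  adj <- lapply(adj, sort)
  g <- structure(list(nodes = names(adj), adj = adj,
                      n_edges = sum(lengths(adj)) %/% 2L),
                 class = "interaction_graph")
  g$components <- .components(g)
  g
}

.components <- function(g) {
  comp <- stats::setNames(rep(NA_integer_, length(g$nodes)), g$nodes)
  label <- 0L
  for (v in g$nodes) {
    if (!is.na(comp[[v]])) next
    label <- label + 1L
    queue <- v
    comp[[v]] <- label
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      nb <- g$adj[[u]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- label
      queue <- c(queue, new)
    }
  }
  comp
}

# induced subgraph on a node subset (keeps isolates within the subset)
.induced <- function(g, nodes) {
  nodes <- intersect(g$nodes, nodes)
  adj <- lapply(g$adj[nodes], function(nb) intersect(nb, nodes))
  names(adj) <- nodes
  .new_graph(adj)
}

#' Build the risk-gene interaction subgraph
#'
#' Takes the induced subgraph of an edge table on a gene set: edges with
#' either endpoint outside `risk_genes` are excluded, self-loops dropped,
#' duplicate and reversed edges merged, and nodes left without any edge are
#' dropped (genes with no interaction partner do not enter the network).
#'
#' @param edge_table data frame with columns `node_a`, `node_b` (e.g. from
#'   [read_edge_list()]).
#' @param risk_genes character vector of gene ids to induce on; `NULL` keeps
#'   all nodes.
#' @return an `interaction_graph`: list with `nodes`, `adj` (named list of
#'   sorted neighbor vectors), `n_edges`, `components` (named component
#'   labels).
#' @export
build_graph <- function(edge_table, risk_genes = NULL) {
  a <- as.character(edge_table$node_a)
  b <- as.character(edge_table$node_b)
  if (!is.null(risk_genes)) {
    keep <- a %in% risk_genes & b %in% risk_genes
    a <- a[keep]; b <- b[keep]
  }
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]
  nodes <- sort(unique(c(lo, hi)))
  adj <- split(c(hi, lo), factor(c(lo, hi), levels = nodes))
  .new_graph(adj)
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges, %d component(s)\n",
              length(x$nodes), x$n_edges,
              if (length(x$components)) max(x$components) else 0L))
  invisible(x)
}

#' Node degrees
#' @param graph an `interaction_graph`.
#' @return named integer vector of degrees.
#' @export
graph_degree <- function(graph) {
  stats::setNames(lengths(graph$adj), graph$nodes)
}

.check_nodes <- function(graph, v) {
  bad <- setdiff(v, graph$nodes)
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
}

#' Local clustering coefficient
#'
#' For node i with k_i neighbors of which n_i pairs are connected,
#' CC_i = 2 n_i / (k_i (k_i - 1)); nodes with fewer than two neighbors get 0.
#' The network clustering coefficient is the unweighted mean over all nodes.
#'
#' @param graph an `interaction_graph`.
#' @param v node ids (default: all nodes).
#' @return named numeric vector of clustering coefficients.
#' @export
clustering_coefficient <- function(graph, v = graph$nodes) {
  .check_nodes(graph, v)
  out <- vapply(v, function(u) {
    nb <- graph$adj[[u]]
    k <- length(nb)
    if (k < 2L) return(0)
    ni <- sum(vapply(nb, function(w)
      sum(graph$adj[[w]] %in% nb), 0L)) / 2
    2 * ni / (k * (k - 1))
  }, 0)
  stats::setNames(out, v)
}

# BFS from source s: distances, shortest-path counts (sigma), predecessors,
# and the visit order (stack) for Brandes accumulation.
.bfs_paths <- function(graph, s) {
  nodes <- graph$nodes
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  sigma <- stats::setNames(rep(0, length(nodes)), nodes)
  preds <- stats::setNames(vector("list", length(nodes)), nodes)
  dist[[s]] <- 0L
  sigma[[s]] <- 1
  queue <- s
  order <- character(0)
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, u)
    du <- dist[[u]]
    for (w in graph$adj[[u]]) {
      if (is.na(dist[[w]])) {
        dist[[w]] <- du + 1L
        queue <- c(queue, w)
      }
      if (dist[[w]] == du + 1L) {
        sigma[[w]] <- sigma[[w]] + sigma[[u]]
        preds[[w]] <- c(preds[[w]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order)
}

#' Shortest-path census
#'
#' Unweighted breadth-first shortest-path lengths and counts of distinct
#' shortest paths for all ordered node pairs, plus the characteristic path
#' length (mean length over connected unordered pairs; disconnected pairs
#' are excluded).
#'
#' @param graph an `interaction_graph`.
#' @return list with `dist` and `sigma` matrices (NA / 0 for disconnected
#'   pairs) and `characteristic_path_length`.
#' @export
shortest_path_census <- function(graph) {
  n <- length(graph$nodes)
  dist <- matrix(NA_integer_, n, n, dimnames = list(graph$nodes, graph$nodes))
  sigma <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  for (s in graph$nodes) {
    b <- .bfs_paths(graph, s)
    dist[s, ] <- b$dist[graph$nodes]
    sigma[s, ] <- b$sigma[graph$nodes]
  }
  d <- dist[upper.tri(dist)]
  d <- d[!is.na(d)]
  cpl <- if (length(d)) mean(d) else NA_real_
  list(dist = dist, sigma = sigma, characteristic_path_length = cpl)
}

#' Count shortest paths through an intermediate node
#'
#' delta_st(v): the number of distinct shortest s-t paths passing through v,
#' obtained from the census by the composition identity
#' sigma(s,v) * sigma(v,t) when dist(s,v) + dist(v,t) = dist(s,t), else 0.
#'
#' @param census result of [shortest_path_census()].
#' @param s,t,v node ids.
#' @return numeric path count.
#' @export
paths_through <- function(census, s, t, v) {
  dst <- census$dist[s, t]
  if (is.na(dst)) return(0)
  dsv <- census$dist[s, v]; dvt <- census$dist[v, t]
  if (is.na(dsv) || is.na(dvt) || dsv + dvt != dst) return(0)
  census$sigma[s, v] * census$sigma[v, t]
}

#' Betweenness centrality (ordered pairs, unnormalized)
#'
#' B(v) = sum over ordered pairs (s, t), with s, t and v pairwise distinct,
#' of delta_st(v) / delta_st where delta_st is the number of shortest s-t
#' paths and delta_st(v) the number passing through v.  Computed by Brandes'
#' dependency accumulation; because the sum ranges over ordered pairs the
#' values are twice the common unordered (halved) convention for undirected
#' graphs.
#'
#' @param graph an `interaction_graph`.
#' @param v node ids (default: all nodes).
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(graph, v = graph$nodes) {
  .check_nodes(graph, v)
  bc <- stats::setNames(rep(0, length(graph$nodes)), graph$nodes)
  for (s in graph$nodes) {
    b <- .bfs_paths(graph, s)
    delta <- stats::setNames(rep(0, length(graph$nodes)), graph$nodes)
    for (w in rev(b$order)) {
      for (u in b$preds[[w]]) {
        delta[[u]] <- delta[[u]] + b$sigma[[u]] / b$sigma[[w]] * (1 + delta[[w]])
      }
      if (w != s) bc[[w]] <- bc[[w]] + delta[[w]]
    }
  }
  bc[v]
}

#' Topological coefficient
#'
#' For node v with degree k_v, over all nodes j != v sharing at least one
#' neighbor with v: J(v, j) = |N(v) intersect N(j)| plus 1 if v and j are
#' adjacent; TC(v) = mean_j J(v, j) / k_v.  Nodes with degree < 2 or with no
#' neighbor-sharing partner get 0 (the NetworkAnalyzer convention).
#'
#' @param graph an `interaction_graph`.
#' @param v node ids (default: all nodes).
#' @return named numeric vector in \[0, 1\].
#' @export
topological_coefficient <- function(graph, v = graph$nodes) {
  .check_nodes(graph, v)
  out <- vapply(v, function(u) {
    nb <- graph$adj[[u]]
    k <- length(nb)
    if (k < 2L) return(0)
    partners <- setdiff(unique(unlist(graph$adj[nb], use.names = FALSE)), u)
    if (length(partners) == 0L) return(0)
    j_vals <- vapply(partners, function(j) {
      length(intersect(nb, graph$adj[[j]])) + as.integer(j %in% nb)
    }, 0)
    mean(j_vals) / k
  }, 0)
  stats::setNames(out, v)
}

#' Degree histogram and log-log slope
#'
#' Histogram of node counts per degree and the least-squares slope of
#' log10(count) on log10(degree) over degrees with count >= 1.  The slope is
#' `NA` when fewer than two distinct positive degrees are present.
#'
#' @param graph an `interaction_graph`.
#' @return list with `histogram` (data frame `degree`, `count`) and
#'   `loglog_slope`.
#' @export
degree_distribution <- function(graph) {
  deg <- graph_degree(graph)
  tab <- table(deg)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab))
  pos <- hist[hist$degree > 0, , drop = FALSE]
  slope <- NA_real_
  if (nrow(pos) >= 2L) {
    fit <- stats::lm(log10(count) ~ log10(degree), data = pos)
    slope <- unname(stats::coef(fit)[2L])
  }
  list(histogram = hist, loglog_slope = slope)
}

#' Select hub genes by degree
#'
#' Nodes with degree strictly greater than the threshold, sorted by
#' descending degree with ties broken by gene id.
#'
#' @param graph an `interaction_graph`.
#' @param degree_min_exclusive exclusive degree threshold (default 17, so a
#'   hub needs degree >= 18).
#' @return data frame with columns `gene_id`, `degree`.
#' @export
select_hubs <- function(graph, degree_min_exclusive = 17) {
  deg <- graph_degree(graph)
  keep <- deg > degree_min_exclusive
  out <- data.frame(gene_id = names(deg)[keep], degree = unname(deg[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Whole-network topology summary
#'
#' @param graph an `interaction_graph`.
#' @return list with `n_nodes`, `n_edges`, `mean_degree` (2E/N),
#'   `network_clustering_coefficient` (mean of node CCs),
#'   `characteristic_path_length`, `degree_histogram`, `loglog_slope`,
#'   `component_sizes`.
#' @export
network_summary <- function(graph) {
  n <- length(graph$nodes)
  dd <- degree_distribution(graph)
  cpl <- shortest_path_census(graph)$characteristic_path_length
  list(
    n_nodes = n,
    n_edges = graph$n_edges,
    mean_degree = if (n > 0) 2 * graph$n_edges / n else NA_real_,
    network_clustering_coefficient =
      if (n > 0) mean(clustering_coefficient(graph)) else NA_real_,
    characteristic_path_length = cpl,
    degree_histogram = dd$histogram,
    loglog_slope = dd$loglog_slope,
    component_sizes = if (length(graph$components))
      as.integer(sort(table(graph$components), decreasing = TRUE)) else integer(0)
  )
}
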