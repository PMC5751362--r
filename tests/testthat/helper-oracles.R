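# Brute-force graph oracles, deliberately independent of the package's
# algorithms: everything here works on a plain adjacency matrix by direct
# enumeration, at sizes where exhaustion is cheap.

# random (Erdos-Renyi) graph as an edge data frame over letter node ids
random_edge_table <- function(n, p) {
  ids <- sprintf("n%02d", seq_len(n))
  prs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(prs)) < p
  data.frame(node_a = prs[1, keep], node_b = prs[2, keep],
             score = rep(NA_real_, sum(keep)), stringsAsFactors = FALSE)
}

adj_matrix <- function(edge_table, nodes) {
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edge_table))) {
    a <- edge_table$node_a[i]; b <- edge_table$node_b[i]
    if (a != b) { A[a, b] <- 1L; A[b, a] <- 1L }
  }
  A
}

is_connected_matrix <- function(A) {
  n <- nrow(A)
  if (n == 0) return(FALSE)
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(rowSums(A[, frontier, drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == n
}

# enumerate ALL simple paths s -> t by depth-first search
bf_all_paths <- function(A, s, t) {
  nodes <- rownames(A)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nb in nodes[A[last, ] == 1L]) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(s)
  paths
}

# shortest-path length, count, and per-intermediate counts by enumeration
bf_path_census <- function(A, s, t) {
  paths <- bf_all_paths(A, s, t)
  if (length(paths) == 0L) {
    return(list(length = NA_integer_, count = 0, through = NULL))
  }
  lens <- vapply(paths, length, 0L) - 1L
  dmin <- min(lens)
  short <- paths[lens == dmin]
  through <- sapply(rownames(A), function(v)
    sum(vapply(short, function(p) v %in% p[-c(1, length(p))], TRUE)))
  list(length = dmin, count = length(short), through = through)
}

bf_betweenness <- function(A, v) {
  nodes <- rownames(A)
  total <- 0
  for (s in nodes) for (t in nodes) {
    if (s == t || s == v || t == v) next
    cen <- bf_path_census(A, s, t)
    if (cen$count > 0) total <- total + cen$through[[v]] / cen$count
  }
  total
}

bf_clustering <- function(A, v) {
  nb <- which(A[v, ] == 1L)
  k <- length(nb)
  if (k < 2) return(0)
  sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
}

bf_topological_coefficient <- function(A, v) {
  nodes <- rownames(A)
  k <- sum(A[v, ])
  if (k < 2) return(0)
  js <- c()
  for (j in nodes) {
    if (j == v) next
    shared <- sum(A[v, ] & A[j, ])
    if (shared >= 1) js <- c(js, shared + A[v, j])
  }
  if (length(js) == 0) return(0)
  mean(js) / k
}

bf_characteristic_path_length <- function(A) {
  nodes <- rownames(A)
  lens <- c()
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j) {
      l <- bf_path_census(A, nodes[i], nodes[j])$length
      if (!is.na(l)) lens <- c(lens, l)
    }
  }
  mean(lens)
}

# tiny named edge-table builder: graph_of("A-B", "B-C")
graph_of <- function(...) {
  spec <- unlist(list(...))
  parts <- strsplit(spec, "-", fixed = TRUE)
  build_graph(data.frame(node_a = vapply(parts, `[`, "", 1L),
                         node_b = vapply(parts, `[`, "", 2L),
                         score = NA_real_, stringsAsFactors = FALSE))
}
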