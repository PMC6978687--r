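# Independent brute-force oracles for the graph metrics, kept free of igraph
# and of the package's own code paths.

# All simple paths between two nodes of a small undirected weighted graph.
# `adj` is a symmetric matrix of edge lengths with NA where no edge exists.
bf_all_paths <- function(len, from, to) {
  n <- nrow(len)
  paths <- list()
  walk <- function(node, visited, dist) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- list(path = visited, dist = dist)
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!is.na(len[node, nxt]) && !(nxt %in% visited)) {
        walk(nxt, c(visited, nxt), dist + len[node, nxt])
      }
    }
  }
  walk(from, from, 0)
  paths
}

# Geodesic matrix by exhaustive simple-path enumeration.
bf_geodesics <- function(len) {
  n <- nrow(len)
  out <- matrix(Inf, n, n)
  diag(out) <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- bf_all_paths(len, i, j)
      if (length(p)) {
        d <- min(vapply(p, `[[`, numeric(1), "dist"))
        out[i, j] <- out[j, i] <- d
      }
    }
  }
  out
}

# Brute-force weighted strength, unweighted local clustering coefficient and
# weighted shortest-path betweenness (pair-normalized by (n-1)(n-2)/2).
# `weight` symmetric COR weights with NA for non-edges; lengths are 1 - weight.
bf_metrics <- function(weight, tol = 1e-9) {
  n <- nrow(weight)
  len <- 1 - weight
  strength <- vapply(seq_len(n), function(i) sum(weight[i, ], na.rm = TRUE), numeric(1))
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(!is.na(weight[i, ]))
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (!is.na(weight[nb[a], nb[b]])) links <- links + 1
      }
    }
    links / choose(k, 2)
  }, numeric(1))
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      p <- bf_all_paths(len, s, t)
      if (!length(p)) next
      d <- vapply(p, `[[`, numeric(1), "dist")
      shortest <- p[d <= min(d) + tol]
      through <- vapply(seq_len(n), function(v) {
        if (v == s || v == t) return(0)
        sum(vapply(shortest, function(sp) v %in% sp$path, logical(1)))
      }, numeric(1))
      btw <- btw + through / length(shortest)
    }
  }
  list(strength = strength, cc = cc,
       betweenness = btw / ((n - 1) * (n - 2) / 2))
}

# Adjusted Rand index from the contingency table (closed form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_idx <- (s_a + s_b) / 2
  if (max_idx == expected) return(1)
  (s_ij - expected) / (max_idx - expected)
}

# Enumerate all connected labeled graphs on n nodes (edge subsets of K_n).
bf_connected_graphs <- function(n) {
  pairs <- t(combn(n, 2))
  m <- nrow(pairs)
  graphs <- list()
  for (code in seq_len(2^m) - 1L) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1L)))
    if (sum(sel) < n - 1) next
    adj <- matrix(FALSE, n, n)
    for (r in which(sel)) adj[pairs[r, 1], pairs[r, 2]] <- adj[pairs[r, 2], pairs[r, 1]] <- TRUE
    # connectivity by BFS
    seen <- logical(n)
    queue <- 1L
    seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (all(seen)) graphs[[length(graphs) + 1L]] <- adj
  }
  graphs
}

# Build a radiomic_graph directly from a COR weight matrix (NA = no edge).
graph_from_weights <- function(weight) {
  n <- nrow(weight)
  adj <- weight
  adj[is.na(adj)] <- 0
  diag(adj) <- 1
  adj <- structure(adj, cluster_ids = seq_len(n),
                   dimnames = list(seq_len(n), seq_len(n)),
                   class = c("adjacency_matrix", "matrix"))
  build_graph(adj, edge_threshold = 0)
}
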