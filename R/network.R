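# Cluster-cluster correlation network.
#
# The adjacency entry (i, j) is the Pearson correlation between the statistic
# vectors of clusters i and j, computed after z-scoring each statistic column
# across clusters (so large-magnitude statistics such as min/max do not
# dominate), with negative values clipped to 0 so that entries live in
# [0, 1]: no correlation -> no edge. Edge weight = COR; edge length
# D = 1 - COR, so strongly correlated clusters sit close together.

#' Cluster-cluster correlation adjacency matrix
#'
#' @param profiles a `cluster_profiles` object (>= 2 clusters).
#' @param use one of `"all"` (default: the full 6-statistics-per-feature
#'   vector) or `"mean"` (per-feature means only).
#' @return an `adjacency_matrix`: square symmetric matrix in \[0, 1\] with
#'   unit diagonal and `cluster_ids` attribute; negative correlations are
#'   clipped to 0.
#' @export
correlation_matrix <- function(profiles, use = c("all", "mean")) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  use <- match.arg(use)
  p <- profiles$stats
  if (nrow(p) < 2L) stopf("need at least 2 cluster profiles")
  if (use == "mean") p <- p[, grepl("_mean$", colnames(p)), drop = FALSE]

  # z-score each statistic across clusters; constant statistics carry no
  # between-cluster information and are dropped from the correlation.
  mu <- colMeans(p)
  sdv <- sqrt(pmax(colMeans(p^2) - mu^2, 0))
  keep <- sdv > .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  z <- sweep(sweep(p[, keep, drop = FALSE], 2, mu[keep], `-`), 2, sdv[keep], `/`)

  # Clusters with identical raw stat vectors are perfectly correlated by
  # definition (duplicated profiles -> COR = 1, D = 0).
  dup <- outer(seq_len(nrow(p)), seq_len(nrow(p)), Vectorize(function(i, j) {
    max(abs(p[i, ] - p[j, ])) <= 1e-12 * max(1, max(abs(p[i, ])))
  }))

  if (ncol(z) == 0L) {
    if (all(dup)) {
      cor_mat <- matrix(1, nrow(p), nrow(p))
    } else {
      stopf("all statistics are constant across clusters; correlation undefined")
    }
  } else {
    row_sd <- apply(z, 1, stats::sd)
    flat <- row_sd <= 1e-12
    if (any(flat)) {
      # a flat z-scored row is only legal when the cluster duplicates another
      # profile exactly (then COR = 1 is forced below)
      offender <- which(flat & rowSums(dup) < 2L)
      if (length(offender)) {
        stopf("cluster(s) %s have zero-variance statistic vectors; correlation undefined",
              paste(profiles$cluster_ids[offender], collapse = ", "))
      }
    }
    suppressWarnings(cor_mat <- stats::cor(t(z)))
    cor_mat[!is.finite(cor_mat)] <- 0
  }
  cor_mat[dup] <- 1
  cor_mat[cor_mat < 0] <- 0
  cor_mat[cor_mat > 1] <- 1
  cor_mat <- (cor_mat + t(cor_mat)) / 2
  diag(cor_mat) <- 1
  dimnames(cor_mat) <- list(profiles$cluster_ids, profiles$cluster_ids)
  structure(cor_mat, cluster_ids = profiles$cluster_ids, class = c("adjacency_matrix", "matrix"))
}

#' Pick an edge threshold from a target edge density
#'
#' Returns the threshold under which `cor > threshold` yields approximately
#' the requested fraction of all node pairs as edges (tissue networks are
#' typically sparse; with clipped-negative adjacencies
#' the achievable density is capped by the fraction of positive pairs).
#'
#' @param adj an `adjacency_matrix`.
#' @param target_density desired edges / possible pairs, in (0, 1\].
#' @return a threshold in \[0, 1).
#' @export
auto_edge_threshold <- function(adj, target_density = 0.20) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  if (!is_scalar_number(target_density) || target_density <= 0 || target_density > 1) {
    stopf("target_density must be in (0, 1]")
  }
  v <- adj[upper.tri(adj)]
  m <- round(target_density * length(v))
  if (m >= length(v)) return(0)
  vs <- sort(v, decreasing = TRUE)
  if (m < 1L) return(min(1 - 1e-9, max(0, vs[1] - 1e-12)))
  thr <- (vs[m] + vs[m + 1L]) / 2
  if (thr >= vs[m]) thr <- vs[m + 1L] # ties: err on the dense side
  max(0, min(thr, 1 - 1e-9))
}

#' Build the weighted cluster graph
#'
#' Node per cluster; an edge joins clusters i and j iff `cor(i, j) >
#' edge_threshold`, with weight = COR and length = D = 1 - COR. The graph may
#' be disconnected; downstream metrics treat components independently.
#'
#' @param adj an `adjacency_matrix`.
#' @param edge_threshold number in \[0, 1), or `"auto"` to target
#'   `target_density`.
#' @param sizes optional cluster sizes (voxel counts) stored as node
#'   attribute.
#' @param target_density used when `edge_threshold = "auto"` (default 0.20).
#' @return a `radiomic_graph`: list with `graph` (igraph), `adjacency`,
#'   `edge_threshold`.
#' @export
build_graph <- function(adj, edge_threshold = 0.5, sizes = NULL,
                        target_density = 0.20) {
  stopifnot(inherits(adj, "adjacency_matrix"))
  if (identical(edge_threshold, "auto")) {
    edge_threshold <- auto_edge_threshold(adj, target_density)
  }
  if (!is_scalar_number(edge_threshold) || edge_threshold < 0 || edge_threshold >= 1) {
    stopf("edge_threshold must be in [0, 1)")
  }
  ids <- attr(adj, "cluster_ids")
  n <- nrow(adj)
  keep <- which(upper.tri(adj) & adj > edge_threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(ids)
  if (!is.null(sizes)) igraph::V(g)$size <- sizes
  if (nrow(keep)) {
    w <- adj[keep]
    g <- igraph::add_edges(g, as.vector(t(keep)))
    igraph::E(g)$weight <- w
    igraph::E(g)$length <- 1 - w
  }
  structure(list(graph = g, adjacency = adj, edge_threshold = edge_threshold),
            class = "radiomic_graph")
}

#' @export
print.radiomic_graph <- function(x, ...) {
  cat(sprintf("<radiomic_graph> %d nodes, %d edges (cor > %.4g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$edge_threshold))
  invisible(x)
}

#' Geodesic (shortest-path) distances between nodes
#'
#' Shortest paths use the edge lengths D = 1 - COR, so that two clusters can
#' be strong interactors indirectly via intermediate nodes. Disconnected
#' pairs are `Inf`; the diagonal is 0.
#'
#' @param rg a `radiomic_graph`.
#' @return square numeric matrix ordered like the adjacency.
#' @export
geodesic_distances <- function(rg) {
  stopifnot(inherits(rg, "radiomic_graph"))
  w <- if (igraph::ecount(rg$graph)) igraph::E(rg$graph)$length else numeric(0)
  d <- igraph::distances(rg$graph, weights = w)
  diag(d) <- 0
  d
}

#' Export the graph
#'
#' @param rg a `radiomic_graph`.
#' @param graphml_path optional GraphML output path.
#' @param edgelist_path optional TSV output path (`source`, `target`,
#'   `weight`, `length`).
#' @return invisibly, the edge list data.frame.
#' @export
export_graph <- function(rg, graphml_path = NULL, edgelist_path = NULL) {
  stopifnot(inherits(rg, "radiomic_graph"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(rg$graph, graphml_path, format = "graphml")
  }
  el <- igraph::as_edgelist(rg$graph)
  df <- data.frame(
    source = el[, 1], target = el[, 2],
    weight = if (igraph::ecount(rg$graph)) igraph::E(rg$graph)$weight else numeric(0),
    length = if (igraph::ecount(rg$graph)) igraph::E(rg$graph)$length else numeric(0)
  )
  if (!is.null(edgelist_path)) {
    utils::write.table(df, edgelist_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}
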