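# Node-level topology: normalized metrics, the node taxonomy
# (cluster-member / authority / hub / bridge), subnetwork extraction by
# bridge removal, the intra-tumor degree hierarchy, and the cluster-number
# sweep with its random-network overfitting diagnostic.

#' Normalized node metrics
#'
#' Degree is the weighted strength (sum of incident COR weights), min-max
#' normalized over nodes. The local clustering coefficient is computed on the
#' unweighted thresholded graph (its standard definition domain) and already
#' lies in \[0, 1\]. Betweenness uses shortest paths under the edge lengths
#' D = 1 - COR, is divided by (n-1)(n-2)/2 and then min-max normalized, so
#' the role thresholds (high betweenness > 0.80, low degree < 0.20)
#' are meaningful as relative values. Isolated nodes score 0 everywhere.
#'
#' @param rg a `radiomic_graph` with >= 2 nodes.
#' @return a `node_metrics` data.frame: `node`, `degree_raw`, `degree`, `cc`,
#'   `betweenness_raw`, `betweenness`.
#' @export
node_metrics <- function(rg) {
  stopifnot(inherits(rg, "radiomic_graph"))
  g <- rg$graph
  n <- igraph::vcount(g)
  if (n < 2L) stopf("node metrics need a graph with at least 2 nodes")
  has_edges <- igraph::ecount(g) > 0L
  strength <- if (has_edges) {
    igraph::strength(g, weights = igraph::E(g)$weight)
  } else {
    rep(0, n)
  }
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  btw <- if (has_edges) {
    igraph::betweenness(g, weights = igraph::E(g)$length, directed = FALSE)
  } else {
    rep(0, n)
  }
  btw_norm <- btw / ((n - 1) * (n - 2) / 2)
  data.frame(
    node = igraph::V(g)$name,
    degree_raw = as.numeric(strength),
    degree = minmax(strength),
    cc = as.numeric(cc),
    betweenness_raw = as.numeric(btw_norm),
    betweenness = minmax(btw_norm),
    stringsAsFactors = FALSE
  )
}

DEFAULT_ROLE_THRESHOLDS <- list(cc_hi = 0.75, bet_hi = 0.80, deg_lo = 0.20,
                                deg_hi = 0.80, authority_q = 0.75)

#' Classify nodes into the topological taxonomy
#'
#' Mutually exclusive roles with precedence bridge > hub > authority >
#' cluster_member > unclassified:
#' * bridge: betweenness > `bet_hi` and degree < `deg_lo` (high-betweenness,
#'   low-degree connectors between subnetworks);
#' * hub: degree > `deg_hi` (aggregates authorities);
#' * authority: degree above the `authority_q` quantile of node degrees;
#' * cluster_member: clustering coefficient > `cc_hi` (densely interconnected
#'   neighborhoods where every node has the same importance);
#' * unclassified otherwise (including isolated nodes).
#'
#' The bridge/cluster-member cutoffs (0.80/0.20, 0.75) are chosen to limit
#' network redundancy while keeping roles interpretable; the hub and authority cutoffs are documented extrapolations (the
#' taxonomy defines them only pictorially) and are configurable.
#'
#' @param metrics a `node_metrics` data.frame (normalized).
#' @param thresholds named list overriding any of `cc_hi`, `bet_hi`,
#'   `deg_lo`, `deg_hi`, `authority_q` (all in \[0, 1\]).
#' @return a `node_classification` data.frame: `node`, `role` (factor),
#'   plus the metric columns.
#' @export
classify_nodes <- function(metrics, thresholds = list()) {
  stopifnot(is.data.frame(metrics),
            all(c("node", "degree", "cc", "betweenness") %in% names(metrics)))
  th <- utils::modifyList(DEFAULT_ROLE_THRESHOLDS, thresholds)
  for (nm in names(DEFAULT_ROLE_THRESHOLDS)) {
    if (!is_scalar_number(th[[nm]]) || th[[nm]] < 0 || th[[nm]] > 1) {
      stopf("threshold `%s` must be a number in [0, 1]", nm)
    }
  }
  deg_q <- stats::quantile(metrics$degree, th$authority_q, names = FALSE, type = 7)
  isolated <- metrics$degree_raw == 0 & metrics$cc == 0 & metrics$betweenness == 0
  role <- rep("unclassified", nrow(metrics))
  role[metrics$cc > th$cc_hi] <- "cluster_member"
  role[metrics$degree > deg_q & !isolated] <- "authority"
  role[metrics$degree > th$deg_hi] <- "hub"
  role[metrics$betweenness > th$bet_hi & metrics$degree < th$deg_lo] <- "bridge"
  out <- metrics
  out$role <- factor(role, levels = c("bridge", "hub", "authority",
                                      "cluster_member", "unclassified"))
  out$subnetwork_id <- NA_integer_
  class(out) <- c("node_classification", "data.frame")
  out
}

#' Extract subnetworks by bridge removal
#'
#' Removing the bridge nodes separates the network into its constituent
#' subnetworks (that is exactly the mechanism that makes bridges bridges).
#' Connected components of the remainder with at least `min_size` nodes
#' become subnetworks, ids assigned by descending size (1 = largest); smaller
#' components are flagged as satellite groups. Bridges keep
#' `subnetwork_id = NA`.
#'
#' @param rg a `radiomic_graph`.
#' @param classification a `node_classification` for the same graph.
#' @param min_size minimum component size for a major subnetwork (default 3).
#' @return the classification with `subnetwork_id` and `is_satellite` filled.
#' @export
extract_subnetworks <- function(rg, classification, min_size = 3L) {
  stopifnot(inherits(rg, "radiomic_graph"),
            inherits(classification, "node_classification"))
  g <- rg$graph
  stopifnot(nrow(classification) == igraph::vcount(g))
  bridges <- classification$node[classification$role == "bridge"]
  g_rm <- igraph::delete_vertices(g, bridges)
  comp <- igraph::components(g_rm)
  comp_sizes <- comp$csize
  ord <- order(comp_sizes, decreasing = TRUE)
  rank_of <- integer(length(comp_sizes))
  rank_of[ord] <- seq_along(ord)
  member_rank <- rank_of[comp$membership]

  classification$subnetwork_id <- NA_integer_
  classification$is_satellite <- FALSE
  idx <- match(igraph::V(g_rm)$name, classification$node)
  classification$subnetwork_id[idx] <- member_rank
  classification$is_satellite[idx] <- comp_sizes[comp$membership] < min_size
  classification
}

#' Stratify subnetwork nodes into degree groups
#'
#' Splits the nodes of one subnetwork into `n_groups` groups by degree
#' (weighted strength) quartile rank, ordered from low to high degree; this
#' is the intra-tumor hierarchy that back-projects to a heterogeneity map.
#' Ties are broken by node id, so all groups are non-empty whenever the
#' subnetwork has at least `n_groups` nodes. If every degree is equal a
#' single group is returned with a warning; if the subnetwork is smaller
#' than `n_groups` fewer groups are returned with a warning.
#'
#' @param rg a `radiomic_graph`.
#' @param classification a `node_classification` with subnetwork ids (see
#'   [extract_subnetworks()]).
#' @param subnetwork_id which subnetwork to stratify.
#' @param n_groups number of degree groups (default 4).
#' @return data.frame `node`, `degree_raw`, `group` (1 = lowest degree).
#' @export
degree_stratify <- function(rg, classification, subnetwork_id, n_groups = 4L) {
  stopifnot(inherits(rg, "radiomic_graph"))
  members <- classification$node[!is.na(classification$subnetwork_id) &
                                   classification$subnetwork_id == subnetwork_id]
  if (!length(members)) stopf("subnetwork %s is empty", subnetwork_id)
  deg <- classification$degree_raw[match(members, classification$node)]
  n <- length(members)
  if (length(unique(deg)) == 1L && n > 1L) {
    warnf("all %d nodes of subnetwork %s have equal degree; single group returned",
          n, subnetwork_id)
    return(data.frame(node = members, degree_raw = deg, group = 1L,
                      stringsAsFactors = FALSE))
  }
  groups_eff <- min(n_groups, n)
  if (groups_eff < n_groups) {
    warnf("subnetwork %s has %d nodes (< %d); returning %d groups",
          subnetwork_id, n, n_groups, groups_eff)
  }
  ord <- order(deg, members) # ties broken by node id
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  group <- ceiling(rank * groups_eff / n)
  data.frame(node = members, degree_raw = deg, group = as.integer(group),
             stringsAsFactors = FALSE)
}

#' Cluster-number sweep with overfitting diagnostic
#'
#' Reruns clustering -> profiles -> network -> metrics over a grid of cluster
#' counts k. Past the informative resolution the surviving edges behave like
#' those of a random graph; operationally this is scored as
#' `randomness_score = C_ER / max(C_obs, eps)` where `C_obs` is the observed
#' mean local clustering coefficient and `C_ER = edge density` is the
#' Erdos-Renyi expectation for the same size and density (a structured
#' network has `C_obs >> C_ER`, a random one `C_obs ~ C_ER`, so the score
#' rises toward 1 as structure is lost). `stability` is the mean edge-set
#' Jaccard similarity between the reference network and `n_stability`
#' reseeded reruns, with clusters matched greedily by voxel overlap. The
#' flagged overfitting onset is the smallest k with
#' `randomness_score >= rs_flag` or `stability < stability_flag`.
#'
#' @param table a `voxel_table`.
#' @param k_values at least 2 cluster counts (sorted increasing).
#' @param seed integer seed; the whole report is deterministic given it.
#' @param method clustering method (see [cluster_voxels()]).
#' @param edge_threshold fixed threshold in \[0, 1) (a density-targeting
#'   "auto" threshold would hold density constant and mask the diagnostic).
#' @param n_stability reseeded reruns per k (default 5).
#' @param rs_flag,stability_flag onset thresholds (defaults 0.8, 0.5).
#' @param eps guard for zero observed clustering (default 1e-6).
#' @return a `ksweep_report` data.frame: `k`, `n_nodes`, `edge_count`,
#'   `density`, `mean_cc`, `randomness_score`, `stability`; attribute
#'   `overfit_k` holds the flagged onset (NA if never flagged).
#' @export
k_sweep <- function(table, k_values, seed = 1L, method = "kmeans",
                    edge_threshold = 0.5, n_stability = 5L,
                    rs_flag = 0.8, stability_flag = 0.5, eps = 1e-6) {
  stopifnot(inherits(table, "voxel_table"))
  k_values <- sort(unique(as.integer(k_values)))
  if (length(k_values) < 2L) stopf("k_sweep needs at least 2 distinct k values")
  if (any(k_values >= nrow(table$features))) {
    stopf("all k values must be below the voxel count (%d)", nrow(table$features))
  }
  std <- standardize_features(table)

  run_net <- function(k, run_seed) {
    assign <- cluster_voxels(std, k, seed = run_seed, method = method,
                             standardize = FALSE)
    prof <- cluster_profiles(table, assign)
    adj <- correlation_matrix(prof)
    rg <- build_graph(adj, edge_threshold = edge_threshold, sizes = prof$sizes)
    list(assign = assign, rg = rg)
  }

  rows <- vector("list", length(k_values))
  for (i in seq_along(k_values)) {
    k <- k_values[i]
    ref <- run_net(k, derive_seed(seed, k, 0))
    g <- ref$rg$graph
    n <- igraph::vcount(g)
    m <- igraph::ecount(g)
    gr <- graph_randomness(ref$rg, eps = eps)
    density <- gr$density
    mean_cc <- gr$mean_cc
    rs <- gr$randomness_score
    jac <- vapply(seq_len(n_stability), function(r) {
      rerun <- run_net(k, derive_seed(seed, k, r))
      edge_jaccard(ref, rerun)
    }, numeric(1))
    rows[[i]] <- data.frame(
      k = k, n_nodes = n, edge_count = m, density = density,
      mean_cc = mean_cc, randomness_score = rs, stability = mean(jac)
    )
  }
  report <- do.call(rbind, rows)
  flagged <- report$k[report$randomness_score >= rs_flag |
                        report$stability < stability_flag]
  attr(report, "overfit_k") <- if (length(flagged)) min(flagged) else NA_integer_
  class(report) <- c("ksweep_report", "data.frame")
  report
}

#' Random-network score of a graph
#'
#' `randomness_score = C_ER / max(C_obs, eps)` where `C_obs` is the mean
#' local clustering coefficient and `C_ER` the edge density (the
#' Erdos-Renyi expectation of the clustering coefficient at the same size
#' and density). Structured networks score near 0, random ones near 1; a
#' complete graph scores exactly 1 (`C_obs = C_ER = 1`). An edgeless graph
#' scores 0.
#'
#' @param rg a `radiomic_graph`.
#' @param eps guard against a zero observed clustering coefficient; a graph
#'   with edges but no triangles at all scores `density / eps` (very large:
#'   tree-like wiring is itself random-graph-like at low density).
#' @return list with `density`, `mean_cc`, `randomness_score`.
#' @export
graph_randomness <- function(rg, eps = 1e-6) {
  stopifnot(inherits(rg, "radiomic_graph"))
  g <- rg$graph
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  density <- if (n > 1) 2 * m / (n * (n - 1)) else 0
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  mean_cc <- if (n) mean(cc) else 0
  list(density = density, mean_cc = mean_cc,
       randomness_score = density / max(mean_cc, eps))
}

# Jaccard similarity of the two runs' edge sets after greedily matching the
# rerun's clusters to the reference clusters by voxel overlap.
edge_jaccard <- function(ref, rerun) {
  map <- match_clusters(ref$assign$labels, rerun$assign$labels)
  ref_edges <- edge_keys(ref$rg$graph, identity_map = TRUE)
  el <- igraph::as_edgelist(rerun$rg$graph, names = FALSE)
  if (nrow(el)) {
    a <- map[el[, 1]]; b <- map[el[, 2]]
    ok <- !is.na(a) & !is.na(b) & a != b
    rerun_edges <- unique(paste(pmin(a[ok], b[ok]), pmax(a[ok], b[ok])))
  } else {
    rerun_edges <- character(0)
  }
  un <- union(ref_edges, rerun_edges)
  if (!length(un)) return(1) # empty vs empty: identical
  length(intersect(ref_edges, rerun_edges)) / length(un)
}

edge_keys <- function(g, identity_map = FALSE) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!nrow(el)) return(character(0))
  unique(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
}

# Greedy one-to-one cluster matching on the contingency table (largest
# overlaps first). Returns map[rerun_label] = ref_label (NA if unmatched).
match_clusters <- function(ref_labels, new_labels) {
  tab <- table(new_labels, ref_labels)
  map <- rep(NA_integer_, max(new_labels))
  used_ref <- logical(max(ref_labels))
  ord <- order(tab, decreasing = TRUE)
  ri <- as.integer(rownames(tab))
  ci <- as.integer(colnames(tab))
  for (o in ord) {
    if (tab[o] == 0) break
    i <- ri[(o - 1) %% nrow(tab) + 1]
    j <- ci[(o - 1) %/% nrow(tab) + 1]
    if (is.na(map[i]) && !used_ref[j]) {
      map[i] <- j
      used_ref[j] <- TRUE
    }
  }
  map
}
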