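test_that("triangle and star graphs give the textbook metric values", {
  w <- matrix(NA_real_, 3, 3)
  w[upper.tri(w)] <- 0.5
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  m <- node_metrics(graph_from_weights(w))
  expect_equal(m$cc, rep(1, 3))
  expect_equal(m$betweenness_raw, rep(0, 3))

  star <- matrix(NA_real_, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.6
  ms <- node_metrics(graph_from_weights(star))
  expect_equal(ms$betweenness_raw[1], 1) # center lies on every leaf pair
  expect_equal(ms$betweenness_raw[2:5], rep(0, 4))
  expect_equal(ms$cc[1], 0)
  expect_equal(ms$degree[1], 1)       # min-max: center is the max
  expect_equal(ms$degree[2:5], rep(0, 4))
  expect_error(node_metrics(build_graph(structure(matrix(1, 1, 1), cluster_ids = 1,
                                                  dimnames = list(1, 1),
                                                  class = c("adjacency_matrix", "matrix")),
                                        0)),
               "at least 2")
})

test_that("metrics agree with the brute-force oracle on random weighted graphs", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    w <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < 0.55) w[i, j] <- w[j, i] <- runif(1, 0.05, 0.95)
    }
    if (all(is.na(w))) next
    m <- node_metrics(graph_from_weights(w))
    o <- bf_metrics(w)
    expect_equal(m$degree_raw, o$strength, tolerance = 1e-12)
    expect_equal(m$cc, o$cc, tolerance = 1e-12)
    expect_equal(m$betweenness_raw, o$betweenness, tolerance = 1e-9)
  }
})

test_that("node roles follow the default thresholds with correct precedence", {
  mk <- function(degree, cc, bet) {
    data.frame(node = as.character(seq_along(degree)), degree_raw = degree,
               degree = degree, cc = cc, betweenness_raw = bet, betweenness = bet)
  }
  # spread of degrees so the authority quantile sits high
  m <- mk(degree = c(0.15, 0.40, 0.45, 0.50, 0.55, 0.95, 0.10, 0.00),
          cc     = c(0.10, 0.90, 0.20, 0.30, 0.10, 0.50, 0.95, 0.00),
          bet    = c(0.85, 0.10, 0.30, 0.10, 0.10, 0.60, 0.10, 0.00))
  cl <- classify_nodes(m)
  expect_identical(as.character(cl$role[1]), "bridge")         # bet > .8, deg < .2
  expect_identical(as.character(cl$role[2]), "cluster_member") # cc > .75
  expect_identical(as.character(cl$role[6]), "hub")            # deg > .8
  expect_identical(as.character(cl$role[7]), "cluster_member") # cc > .75, low degree
  expect_identical(as.character(cl$role[8]), "unclassified")   # isolated
  expect_identical(sum(table(cl$role)), nrow(m))               # total and exclusive
  # authority: above the 75th degree percentile but below the hub cutoff
  expect_identical(as.character(cl$role[5]), "authority")
  # precedence: a would-be hub that qualifies as bridge stays bridge
  m2 <- mk(degree = c(0.10, 0.5, 0.6), cc = c(0.9, 0.9, 0.2), bet = c(0.9, 0.2, 0.1))
  expect_identical(as.character(classify_nodes(m2)$role[1]), "bridge")
  expect_error(classify_nodes(m, thresholds = list(cc_hi = 1.5)), "cc_hi")
})

test_that("bridge removal separates the barbell into two subnetworks", {
  # two triangles joined through node 7
  w <- matrix(NA_real_, 7, 7)
  link <- function(i, j, v) w[i, j] <<- w[j, i] <<- v
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    link(p[1], p[2], 0.9)
  }
  link(1, 7, 0.4); link(4, 7, 0.4)
  rg <- graph_from_weights(w)
  cl <- classify_nodes(node_metrics(rg))
  expect_identical(as.character(cl$role[7]), "bridge")
  cl2 <- extract_subnetworks(rg, cl, min_size = 3)
  expect_true(is.na(cl2$subnetwork_id[7]))
  major <- unique(cl2$subnetwork_id[!is.na(cl2$subnetwork_id) & !cl2$is_satellite])
  expect_identical(sort(major), 1:2)
  # removing the bridge strictly increases the component count
  g_before <- igraph::components(rg$graph)$no
  g_after <- igraph::components(igraph::delete_vertices(rg$graph, "7"))$no
  expect_gt(g_after, g_before)
})

test_that("without bridges, subnetworks are the connected components", {
  w <- matrix(NA_real_, 6, 6)
  w[1, 2] <- w[2, 1] <- 0.9; w[2, 3] <- w[3, 2] <- 0.9; w[1, 3] <- w[3, 1] <- 0.9
  w[4, 5] <- w[5, 4] <- 0.8; w[5, 6] <- w[6, 5] <- 0.8; w[4, 6] <- w[6, 4] <- 0.8
  rg <- graph_from_weights(w)
  cl <- extract_subnetworks(rg, classify_nodes(node_metrics(rg)), min_size = 3)
  expect_identical(sum(is.na(cl$subnetwork_id)), 0L)
  expect_identical(length(unique(cl$subnetwork_id)), 2L)
  # components smaller than min_size become satellites
  w2 <- w
  w2[4, 5] <- w2[5, 4] <- NA; w2[4, 6] <- w2[6, 4] <- NA # node 4 isolated
  rg2 <- graph_from_weights(w2)
  cl2 <- extract_subnetworks(rg2, classify_nodes(node_metrics(rg2)), min_size = 3)
  expect_true(cl2$is_satellite[cl2$node == "4"])
})

test_that("degree stratification yields ordered, non-empty quartile groups", {
  # path graph with increasing edge weights -> 8 distinct strengths
  w <- matrix(NA_real_, 8, 8)
  for (i in 1:7) w[i, i + 1] <- w[i + 1, i] <- 0.1 * i
  rg <- graph_from_weights(w)
  cl <- extract_subnetworks(rg, classify_nodes(node_metrics(rg)), min_size = 2)
  strat <- degree_stratify(rg, cl, subnetwork_id = 1, n_groups = 4)
  expect_identical(sort(unique(strat$group)), 1:4)
  expect_identical(as.integer(table(strat$group)), rep(2L, 4))
  # groups ordered low -> high degree
  agg <- tapply(strat$degree_raw, strat$group, mean)
  expect_true(all(diff(agg) > 0))
})

test_that("degenerate stratification cases warn", {
  w <- matrix(NA_real_, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) w[i, j] <- w[j, i] <- 0.5
  rg <- graph_from_weights(w)
  cl <- extract_subnetworks(rg, classify_nodes(node_metrics(rg)), min_size = 2)
  expect_warning(strat <- degree_stratify(rg, cl, 1, n_groups = 4), "equal degree")
  expect_identical(unique(strat$group), 1L)
  # fewer nodes than groups
  w2 <- matrix(NA_real_, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 0.5; w2[2, 3] <- w2[3, 2] <- 0.7
  rg2 <- graph_from_weights(w2)
  cl2 <- extract_subnetworks(rg2, classify_nodes(node_metrics(rg2)), min_size = 2)
  expect_warning(strat2 <- degree_stratify(rg2, cl2, 1, n_groups = 4), "3 nodes")
  expect_identical(max(strat2$group), 3L)
})

test_that("ladder quartiles split exactly as {12}{34}{56}{78}", {
  w <- matrix(NA_real_, 8, 8)
  for (i in 1:7) w[i, i + 1] <- w[i + 1, i] <- 0.1 * i
  rg <- graph_from_weights(w)
  cl <- extract_subnetworks(rg, classify_nodes(node_metrics(rg)), min_size = 2)
  strat <- degree_stratify(rg, cl, 1, n_groups = 4)
  ord <- order(strat$degree_raw)
  expect_identical(strat$group[ord], rep(1:4, each = 2))
})
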