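test_that("duplicated profiles give COR = 1 and D = 0; anti-correlation clips to 0", {
  # two identical clusters among a varying set
  m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(2, 1, 4, 3))
  adj <- correlation_matrix(profiles_from_stats(m))
  expect_equal(adj[1, 2], 1)
  rg <- build_graph(adj, edge_threshold = 0)
  d <- geodesic_distances(rg)
  expect_equal(d["1", "2"], 0)
  # exactly opposed stat vectors -> Pearson -1 -> stored as 0
  m2 <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1), c(1, 3, 2, 4))
  adj2 <- correlation_matrix(profiles_from_stats(m2))
  expect_equal(adj2[1, 2], 0)
})

test_that("the two-cluster degenerate case still honors the duplicate rule", {
  m <- rbind(c(1, 2, 3), c(1, 2, 3))
  adj <- correlation_matrix(profiles_from_stats(m))
  expect_equal(unname(adj[1, 2]), 1)
  # a cluster sitting exactly at the per-statistic means has a flat z-scored
  # vector: correlation is undefined and the cluster must be named
  expect_error(
    correlation_matrix(profiles_from_stats(rbind(c(0, 0, 0), c(1, 2, 3), c(-1, -2, -3)))),
    "zero-variance.*1|1.*zero-variance"
  )
})

test_that("adjacency invariants hold for random profile sets", {
  for (s in 1:20) {
    pr <- random_profiles(n_clusters = 5 + (s %% 6), seed = s)
    adj <- correlation_matrix(pr)
    expect_true(isSymmetric(unclass(adj)))
    expect_equal(unname(diag(adj)), rep(1, nrow(adj)))
    expect_true(all(adj >= 0 & adj <= 1))
  }
})

test_that("edge thresholding enumerates pairs correctly", {
  m <- diag(4) * 0 # placeholder stats, adjacency built directly
  adj <- structure(
    rbind(c(1, 0.9, 0.1, 0.1),
          c(0.9, 1, 0.1, 0.1),
          c(0.1, 0.1, 1, 0.1),
          c(0.1, 0.1, 0.1, 1)),
    cluster_ids = 1:4, dimnames = list(1:4, 1:4),
    class = c("adjacency_matrix", "matrix")
  )
  expect_equal(igraph::ecount(build_graph(adj, 0.5)$graph), 1)
  expect_equal(igraph::ecount(build_graph(adj, 0)$graph), 6)
  # threshold just below the maximum keeps only the maximal pair
  expect_equal(igraph::ecount(build_graph(adj, 0.9 - 1e-9)$graph), 1)
  e <- igraph::as_edgelist(build_graph(adj, 0.5)$graph)
  expect_setequal(as.vector(e), c("1", "2"))
  expect_error(build_graph(adj, 1), "edge_threshold")
  # weight/length bookkeeping
  rg <- build_graph(adj, 0.5)
  expect_equal(igraph::E(rg$graph)$length, 1 - igraph::E(rg$graph)$weight)
})

test_that("edge sets are nested under increasing threshold", {
  for (s in 1:10) {
    pr <- random_profiles(6 + (s %% 5), seed = 100 + s)
    adj <- correlation_matrix(pr)
    prev <- NULL
    for (t in c(0, 0.2, 0.4, 0.6, 0.8)) {
      g <- build_graph(adj, t)$graph
      el <- igraph::as_edgelist(g)
      keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
      if (!is.null(prev)) expect_true(all(keys %in% prev))
      prev <- keys
    }
  }
})

test_that("auto threshold approaches the target edge density", {
  pr <- random_profiles(15, seed = 3)
  adj <- correlation_matrix(pr)
  thr <- auto_edge_threshold(adj, target_density = 0.2)
  g <- build_graph(adj, thr)$graph
  n_pairs <- choose(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g) / n_pairs, 0.2, tolerance = 0.05)
  # degenerate targets
  expect_identical(auto_edge_threshold(adj, 1), 0)
  expect_error(auto_edge_threshold(adj, 0), "target_density")
})

test_that("geodesics follow additive shortest paths, preferring indirect routes", {
  # path graph a-b-c with lengths 0.2 and 0.3
  w <- matrix(NA_real_, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.8 # length 0.2
  w[2, 3] <- w[3, 2] <- 0.7 # length 0.3
  rg <- graph_from_weights(w)
  d <- geodesic_distances(rg)
  expect_equal(d[1, 3], 0.5)
  # triangle where the two-hop route beats the direct edge
  w2 <- matrix(NA_real_, 3, 3)
  w2[1, 3] <- w2[3, 1] <- 0.1 # direct length 0.9
  w2[1, 2] <- w2[2, 1] <- 0.9 # 0.1
  w2[2, 3] <- w2[3, 2] <- 0.8 # 0.2
  d2 <- geodesic_distances(graph_from_weights(w2))
  expect_equal(d2[1, 3], 0.3)
  # disconnected pairs are Inf
  w3 <- matrix(NA_real_, 4, 4)
  w3[1, 2] <- w3[2, 1] <- 0.5
  d3 <- geodesic_distances(graph_from_weights(w3))
  expect_identical(d3[1, 3], Inf)
  expect_identical(unname(diag(d3)), rep(0, 4))
})

test_that("geodesic matrix matches exhaustive path enumeration on random small graphs", {
  set.seed(42)
  for (rep in 1:15) {
    n <- sample(3:6, 1)
    w <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < 0.6) w[i, j] <- w[j, i] <- runif(1, 0.05, 0.95)
      }
    }
    if (all(is.na(w))) next
    rg <- graph_from_weights(w)
    got <- geodesic_distances(rg)
    want <- bf_geodesics(1 - w)
    expect_equal(unname(unclass(got)), want, tolerance = 1e-10)
    # triangle inequality and geodesic <= direct edge length
    for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
      if (is.finite(got[i, k]) && is.finite(got[k, j])) {
        expect_lte(got[i, j], got[i, k] + got[k, j] + 1e-12)
      }
    }
    direct <- 1 - w
    ok <- !is.na(direct)
    expect_true(all(got[ok] <= direct[ok] + 1e-12))
  }
})

test_that("graph exports write GraphML and a well-formed edge list", {
  pr <- random_profiles(6, seed = 10)
  adj <- correlation_matrix(pr)
  rg <- build_graph(adj, 0)
  expect_gt(igraph::ecount(rg$graph), 0)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- export_graph(rg, graphml_path = gml, edgelist_path = tsv)
  expect_true(file.exists(gml))
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), as.integer(igraph::ecount(rg$graph)))
  expect_named(back, c("source", "target", "weight", "length"))
  expect_equal(back$length, 1 - back$weight)
})
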