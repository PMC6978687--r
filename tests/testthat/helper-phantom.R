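# Small fixtures built in code.

# A small 3-tissue phantom spec (fast to generate; same structure as the
# default: healthy background + tumor ellipsoid + 1-voxel interface).
small_phantom_spec <- function(seed = 7L, n_features = 4L, noise_sd = 2,
                               grid = c(16L, 16L, 4L), interface_width = 1L,
                               healthy_sd = 5, tumor_sd = 8) {
  healthy <- rep(100, n_features)
  contrast <- rep(c(20, -15, 12, -18), length.out = n_features)
  phantom_spec(
    grid_shape = grid,
    voxel_spacing = c(1, 1, 2),
    n_features = n_features,
    tissue_classes = list(
      tissue_class("healthy", list(type = "background"),
                   healthy, rep(healthy_sd, n_features)),
      tissue_class("tumor",
                   list(type = "ellipsoid",
                        center = (grid + 1) / 2, radii = grid * 0.3),
                   healthy + contrast, rep(tumor_sd, n_features))
    ),
    interface_width = interface_width,
    noise_sd = noise_sd,
    seed = seed
  )
}

# Zero-variance spec: every voxel carries exactly its class mean.
exact_phantom_spec <- function(seed = 1L, n_features = 4L, grid = c(12L, 12L, 4L)) {
  sp <- small_phantom_spec(seed = seed, n_features = n_features, grid = grid,
                           noise_sd = 0, healthy_sd = 0, tumor_sd = 0)
  sp
}

# A voxel table synthesized directly from a feature matrix (grid is a line of
# voxels; coordinates are irrelevant to feature-space operations).
table_from_matrix <- function(x, feature_names = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(feature_names)) {
    feature_names <- colnames(x)
    if (is.null(feature_names)) feature_names <- sprintf("f%02d", seq_len(ncol(x)))
  }
  colnames(x) <- feature_names
  structure(
    list(coords = cbind(x = seq_len(n), y = rep(1L, n), z = rep(1L, n)),
         features = x, feature_names = feature_names,
         grid = c(n, 1L, 1L), spacing = c(1, 1, 1), affine = diag(4)),
    class = "voxel_table"
  )
}

# Cluster profiles built directly from a stats matrix (bypassing clustering)
# for adjacency-level tests.
profiles_from_stats <- function(stats_mat, sizes = NULL) {
  stats_mat <- as.matrix(stats_mat)
  if (is.null(colnames(stats_mat))) {
    colnames(stats_mat) <- sprintf("s%02d", seq_len(ncol(stats_mat)))
  }
  structure(
    list(stats = stats_mat,
         sizes = if (is.null(sizes)) rep(1L, nrow(stats_mat)) else sizes,
         cluster_ids = seq_len(nrow(stats_mat)),
         degenerate = rep(FALSE, nrow(stats_mat))),
    class = "cluster_profiles"
  )
}

# Random cluster profiles: per-cluster Gaussian stat vectors with enough
# spread that no statistic is constant.
random_profiles <- function(n_clusters, n_stats = 24, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_clusters * n_stats), n_clusters, n_stats)
  profiles_from_stats(m)
}
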