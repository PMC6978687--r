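# Voxel clustering and per-cluster statistic profiles.
#
# Voxels are grouped in feature space (k-means by default, Ward agglomerative
# as an option) on z-scored features, because the feature maps carry mixed
# units. The cluster profile then summarizes the *raw* (unstandardized)
# intra-cluster distribution of every feature with six statistics: mean,
# standard deviation, excess kurtosis, Fisher skewness, minimum and maximum.

STAT_NAMES <- c("mean", "std", "kurtosis", "skewness", "min", "max")

#' Z-score the feature columns of a voxel table
#'
#' Each column is centered and scaled to unit *population* standard deviation
#' over the masked voxels. Zero-variance columns are set to 0 and reported
#' with a warning (not an error: a flat feature map is uninformative but
#' legal). Standardizing twice is a no-op.
#'
#' @param table a `voxel_table`.
#' @return the table with standardized `features` and attribute
#'   `standardized = TRUE`.
#' @export
standardize_features <- function(table) {
  stopifnot(inherits(table, "voxel_table"))
  x <- table$features
  if (nrow(x) < 2L) stopf("standardization needs at least 2 voxels")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(x^2) - mu^2)
  sdv[sdv < 0] <- 0 # numerical guard
  zero_var <- sdv <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  if (any(zero_var)) {
    warnf("zero-variance feature column(s) set to 0: %s",
          paste(colnames(x)[zero_var], collapse = ", "))
  }
  scale_by <- ifelse(zero_var, 1, sdv)
  z <- sweep(sweep(x, 2, mu, `-`), 2, scale_by, `/`)
  z[, zero_var] <- 0
  out <- table
  out$features <- z
  attr(out, "standardized") <- TRUE
  out
}

#' Cluster masked voxels in feature space
#'
#' @param table a `voxel_table` (raw features; standardization for the
#'   clustering metric is applied internally unless `standardize = FALSE`).
#' @param k number of clusters, `2 <= k < nrow`.
#' @param seed integer seed; the result is deterministic given
#'   `(table, k, seed, method)`.
#' @param method `"kmeans"` (default; 10 restarts) or `"agglomerative"`
#'   (Ward.D2 on Euclidean distance; O(n^2) memory, intended for small
#'   tables).
#' @param standardize z-score features before clustering (default TRUE).
#' @param nstart number of k-means restarts.
#' @return a `cluster_assignment`: list with `labels` (1..k per row), `k`,
#'   `method`, `seed`. Empty clusters are compacted (labels stay contiguous)
#'   with a warning.
#' @export
cluster_voxels <- function(table, k, seed = 1L,
                           method = c("kmeans", "agglomerative"),
                           standardize = TRUE, nstart = 10L) {
  stopifnot(inherits(table, "voxel_table"))
  method <- match.arg(method)
  n <- nrow(table$features)
  if (!is_scalar_number(k) || k < 2) stopf("k must be an integer >= 2")
  k <- as.integer(k)
  if (k >= n) stopf("k = %d must be smaller than the number of voxels (%d)", k, n)

  x <- if (standardize && !isTRUE(attr(table, "standardized"))) {
    standardize_features(table)$features
  } else {
    table$features
  }

  if (method == "kmeans") {
    distinct <- unique(x)
    if (nrow(distinct) <= k) {
      # fewer distinct points than requested clusters: every distinct feature
      # vector becomes its own (deterministic) cluster
      if (nrow(distinct) < k) {
        warnf("only %d distinct feature vectors; k reduced from %d", nrow(distinct), k)
        k <- nrow(distinct)
      }
      fit <- with_seed(seed, suppressWarnings(
        stats::kmeans(x, centers = distinct, iter.max = 100L)
      ))
    } else {
      fit <- with_seed(seed, suppressWarnings(
        stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L)
      ))
    }
    labels <- fit$cluster
  } else {
    if (n > 20000L) {
      stopf("agglomerative clustering is O(n^2); %d voxels is too many (limit 20000)", n)
    }
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    labels <- stats::cutree(hc, k = k)
  }

  present <- sort(unique(labels))
  if (length(present) < max(labels) || length(present) < k) {
    if (length(present) < k) {
      warnf("clustering produced %d non-empty clusters (k = %d requested)",
            length(present), k)
    }
    labels <- match(labels, present)
  }
  structure(
    list(labels = as.integer(labels), k = length(present),
         method = method, seed = as.integer(seed)),
    class = "cluster_assignment"
  )
}

#' Per-cluster statistic profiles
#'
#' For every cluster and every feature, six statistics of the raw
#' (unstandardized) intra-cluster distribution: mean, population standard
#' deviation, excess kurtosis (normal -> 0), Fisher moment skewness, minimum
#' and maximum. Kurtosis and skewness of singleton or zero-variance clusters
#' are set to 0 and the cluster flagged.
#'
#' @param table the *raw* `voxel_table` the assignment was computed from.
#' @param assignment a `cluster_assignment` with one label per table row.
#' @return a `cluster_profiles` object: list with `stats` (k x 6N matrix,
#'   columns `f<name>_<stat>` grouped per feature in the order mean, std,
#'   kurtosis, skewness, min, max), `sizes` (voxel counts), `cluster_ids`,
#'   and `degenerate` (logical flag per cluster).
#' @export
cluster_profiles <- function(table, assignment) {
  stopifnot(inherits(table, "voxel_table"), inherits(assignment, "cluster_assignment"))
  labels <- assignment$labels
  if (length(labels) != nrow(table$features)) {
    stopf("assignment has %d labels for %d table rows",
          length(labels), nrow(table$features))
  }
  ids <- sort(unique(labels))
  n_feat <- ncol(table$features)
  stat_cols <- as.vector(t(outer(table$feature_names, STAT_NAMES, paste, sep = "_")))
  stats_mat <- matrix(NA_real_, nrow = length(ids), ncol = 6L * n_feat,
                      dimnames = list(ids, stat_cols))
  sizes <- integer(length(ids))
  degenerate <- logical(length(ids))
  for (i in seq_along(ids)) {
    rows <- labels == ids[i]
    sizes[i] <- sum(rows)
    sub <- table$features[rows, , drop = FALSE]
    if (sizes[i] < 2L) degenerate[i] <- TRUE
    for (f in seq_len(n_feat)) {
      v <- sub[, f]
      base <- (f - 1L) * 6L
      stats_mat[i, base + 1L] <- mean(v)
      stats_mat[i, base + 2L] <- pop_sd(v)
      stats_mat[i, base + 3L] <- pop_kurtosis(v)
      stats_mat[i, base + 4L] <- pop_skewness(v)
      stats_mat[i, base + 5L] <- min(v)
      stats_mat[i, base + 6L] <- max(v)
    }
  }
  structure(
    list(stats = stats_mat, sizes = sizes, cluster_ids = ids,
         degenerate = degenerate),
    class = "cluster_profiles"
  )
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("<cluster_profiles> %d clusters x %d statistics (%d features x 6)\n",
              nrow(x$stats), ncol(x$stats), ncol(x$stats) / 6L))
  invisible(x)
}

#' Export cluster profiles as a data frame
#'
#' @param x a `cluster_profiles` object.
#' @param ... unused.
#' @return data.frame with `cluster_id`, `size` and one labeled column per
#'   statistic.
#' @export
as.data.frame.cluster_profiles <- function(x, ...) {
  cbind(data.frame(cluster_id = x$cluster_ids, size = x$sizes),
        as.data.frame(x$stats, row.names = FALSE))
}

#' Export a cluster assignment as a label volume
#'
#' @param assignment a `cluster_assignment`.
#' @param table the `voxel_table` it was computed from.
#' @return a `label_volume` whose voxel values are cluster ids (0 outside the
#'   mask).
#' @export
assignment_to_volume <- function(assignment, table) {
  stopifnot(inherits(assignment, "cluster_assignment"), inherits(table, "voxel_table"))
  legend <- stats::setNames(seq_len(assignment$k),
                            sprintf("cluster_%d", seq_len(assignment$k)))
  label_volume(scatter_to_grid(table, assignment$labels), legend = legend,
               spacing = table$spacing, affine = table$affine)
}
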