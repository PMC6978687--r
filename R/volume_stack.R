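# Feature-volume assembly: NIfTI stacking, grid resampling and the masked
# voxel table that all downstream stages operate on.

#' Construct a feature volume
#'
#' A feature volume is a 4D stack of co-registered scalar volumes on one voxel
#' grid, indexed (x, y, z, feature). Voxels holding a non-finite value in any
#' feature are excluded from the mask: the intra-cluster statistics computed
#' later (kurtosis, skewness) are fragile under imputation, so exclusion is
#' the only NaN policy offered.
#'
#' @param data numeric 4D array (x, y, z, feature).
#' @param spacing voxel spacing in mm (triple, strictly positive).
#' @param feature_names character vector, one name per feature slice.
#' @param affine optional 4x4 grid-to-world matrix (default: diagonal
#'   spacing). Maps 0-based voxel indices to world mm.
#' @param mask optional logical 3D array; combined (AND) with the finiteness
#'   mask.
#' @return a `feature_volume` object.
#' @export
feature_volume <- function(data, spacing, feature_names = NULL, affine = NULL,
                           mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stopf("`data` must be a 4D array (x, y, z, feature)")
  }
  spacing <- check_triple(spacing, "spacing", positive = TRUE)
  n_feat <- dim(data)[4]
  if (is.null(feature_names)) feature_names <- sprintf("feature_%02d", seq_len(n_feat))
  if (length(feature_names) != n_feat) {
    stopf("feature axis has length %d but %d feature names were given",
          n_feat, length(feature_names))
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  finite_mask <- apply(is.finite(data), c(1, 2, 3), all)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(data)[1:3])) stopf("mask grid does not match data grid")
    finite_mask <- finite_mask & (mask > 0)
  }
  structure(
    list(data = data, spacing = spacing, feature_names = as.character(feature_names),
         affine = affine, mask = finite_mask),
    class = "feature_volume"
  )
}

#' Construct a label volume
#'
#' @param data integer 3D array on the reference grid; 0 = outside mask.
#' @param legend named integer vector mapping meaning -> label value.
#' @param spacing mm triple.
#' @param affine optional 4x4 grid-to-world matrix.
#' @return a `label_volume` object.
#' @export
label_volume <- function(data, legend = NULL, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) stopf("`data` must be a 3D array")
  spacing <- check_triple(spacing, "spacing", positive = TRUE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  storage.mode(data) <- "integer"
  present <- setdiff(unique(as.vector(data)), 0L)
  if (!is.null(legend) && length(setdiff(present, legend))) {
    stopf("label volume contains labels missing from the legend: %s",
          paste(setdiff(present, legend), collapse = ", "))
  }
  structure(list(data = data, legend = legend, spacing = spacing, affine = affine),
            class = "label_volume")
}

#' @export
print.feature_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<feature_volume> %d x %d x %d grid, %d features, spacing %s mm, %d masked voxels\n",
              d[1], d[2], d[3], d[4], paste(signif(x$spacing, 3), collapse = " x "),
              sum(x$mask)))
  invisible(x)
}

#' Read a feature manifest
#'
#' A manifest is a plain-text file with one `name<TAB>path` line per feature
#' (paths relative to the manifest's directory unless absolute).
#'
#' @param path manifest file.
#' @return data.frame with columns `name`, `path`.
#' @export
read_feature_manifest <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stopf("manifest lines must be 'name<TAB>path'")
  name <- vapply(parts, `[[`, character(1), 1L)
  p <- vapply(parts, `[[`, character(1), 2L)
  rel <- !grepl("^(/|[A-Za-z]:)", p)
  p[rel] <- file.path(dirname(path), p[rel])
  data.frame(name = name, path = p, stringsAsFactors = FALSE)
}

#' Load co-registered feature volumes
#'
#' Reads >= 2 NIfTI-1 scalar volumes, optionally resamples each to a target
#' spacing, verifies they share one grid, and stacks them into a
#' [feature_volume()]. Feature names come from `feature_names`, else from file
#' stems. Voxels outside the mask or carrying NaN in any feature are excluded.
#'
#' @param paths character vector of NIfTI file paths, or a single manifest
#'   path (see [read_feature_manifest()]).
#' @param mask_path optional NIfTI binary mask on the same grid.
#' @param feature_names optional explicit names.
#' @param target_spacing optional mm triple; every input is resampled to it
#'   before stacking.
#' @param allow_single allow a single feature volume (default FALSE: one
#'   feature is rejected as uninformative for a correlation network).
#' @return a `feature_volume`.
#' @export
load_feature_volumes <- function(paths, mask_path = NULL, feature_names = NULL,
                                 target_spacing = NULL, allow_single = FALSE) {
  if (length(paths) == 1L && !grepl("\\.nii(\\.gz)?$", paths)) {
    man <- read_feature_manifest(paths)
    paths <- man$path
    if (is.null(feature_names)) feature_names <- man$name
  }
  if (length(paths) < 2L && !allow_single) {
    stopf("at least 2 feature volumes are required (got %d); set allow_single = TRUE to override",
          length(paths))
  }
  if (is.null(feature_names)) {
    feature_names <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  }
  vols <- lapply(paths, read_nifti)
  if (!is.null(target_spacing)) {
    vols <- lapply(vols, function(v) {
      fv <- feature_volume(array(v$data, dim = c(dim(v$data), 1L)),
                           spacing = v$spacing, affine = v$affine)
      rv <- resample_to_grid(fv, target_spacing)
      list(data = rv$data[, , , 1, drop = TRUE], spacing = rv$spacing, affine = rv$affine)
    })
  }
  shapes <- vapply(vols, function(v) paste(dim(v$data), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L) {
    bad <- paste(sprintf("%s [%s]", basename(paths), shapes), collapse = ", ")
    stopf("feature volumes are not on one grid after resampling: %s", bad)
  }
  gs <- dim(vols[[1]]$data)
  data <- array(NA_real_, dim = c(gs, length(vols)))
  for (i in seq_along(vols)) data[, , , i] <- vols[[i]]$data
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_nifti(mask_path)
    if (!all(dim(m$data) == gs)) {
      stopf("mask grid (%s) does not match feature grid (%s)",
            paste(dim(m$data), collapse = "x"), paste(gs, collapse = "x"))
    }
    mask <- m$data > 0
  }
  feature_volume(data, spacing = vols[[1]]$spacing, feature_names = feature_names,
                 affine = vols[[1]]$affine, mask = mask)
}

#' Resample a feature volume to a target spacing
#'
#' Trilinear interpolation per feature (use [resample_label_volume()] for
#' nearest-neighbor label resampling). The world-space extent is preserved to
#' within one voxel; resampling to the current spacing is the identity.
#'
#' @param volume a `feature_volume`.
#' @param target_spacing mm triple, strictly positive.
#' @return a resampled `feature_volume`.
#' @export
resample_to_grid <- function(volume, target_spacing) {
  stopifnot(inherits(volume, "feature_volume"))
  target_spacing <- check_triple(target_spacing, "target_spacing", positive = TRUE)
  if (all(abs(target_spacing - volume$spacing) < 1e-9)) return(volume)

  in_dim <- dim(volume$data)[1:3]
  scale <- volume$spacing / target_spacing
  out_dim <- pmax(1L, as.integer(round(in_dim * scale)))
  grids <- lapply(1:3, function(k) {
    # voxel-center alignment: world(i_out) = (i_out - 1) * new spacing
    idx <- ((seq_len(out_dim[k]) - 1) * target_spacing[k]) / volume$spacing[k] + 1
    pmin(pmax(idx, 1), in_dim[k])
  })
  n_feat <- dim(volume$data)[4]
  out <- array(NA_real_, dim = c(out_dim, n_feat))
  interp <- trilinear_weights(grids, in_dim)
  for (f in seq_len(n_feat)) {
    vol_f <- volume$data[, , , f, drop = TRUE]
    vol_f[!is.finite(vol_f)] <- 0 # excluded voxels contribute 0; mask handled below
    out[, , , f] <- apply_trilinear(vol_f, interp, out_dim)
  }
  new_affine <- volume$affine
  for (k in 1:3) new_affine[, k] <- volume$affine[, k] * target_spacing[k] / volume$spacing[k]
  mask_num <- array(as.numeric(volume$mask), dim = in_dim)
  mask_out <- apply_trilinear(mask_num, interp, out_dim) > 0.999
  feature_volume(out, spacing = target_spacing, feature_names = volume$feature_names,
                 affine = new_affine, mask = mask_out)
}

# Precompute per-axis floor indices and fractional weights.
trilinear_weights <- function(grids, in_dim) {
  lapply(1:3, function(k) {
    g <- grids[[k]]
    lo <- pmin(floor(g), in_dim[k] - ifelse(in_dim[k] > 1, 1, 0))
    lo <- pmax(lo, 1)
    frac <- g - lo
    hi <- pmin(lo + 1, in_dim[k])
    list(lo = as.integer(lo), hi = as.integer(hi), frac = frac)
  })
}

apply_trilinear <- function(vol, interp, out_dim) {
  xs <- interp[[1]]; ys <- interp[[2]]; zs <- interp[[3]]
  out <- array(0, dim = out_dim)
  for (dz in 0:1) {
    zi <- if (dz == 0) zs$lo else zs$hi
    wz <- if (dz == 0) 1 - zs$frac else zs$frac
    if (all(wz == 0)) next
    for (dy in 0:1) {
      yi <- if (dy == 0) ys$lo else ys$hi
      wy <- if (dy == 0) 1 - ys$frac else ys$frac
      if (all(wy == 0)) next
      for (dx in 0:1) {
        xi <- if (dx == 0) xs$lo else xs$hi
        wx <- if (dx == 0) 1 - xs$frac else xs$frac
        if (all(wx == 0)) next
        sub <- vol[xi, yi, zi, drop = FALSE]
        w <- outer(outer(wx, wy), wz)
        out <- out + sub * array(w, dim = out_dim)
      }
    }
  }
  out
}

#' Resample a label volume (nearest neighbor)
#'
#' @param labels a `label_volume`.
#' @param target_spacing mm triple.
#' @return a resampled `label_volume`.
#' @export
resample_label_volume <- function(labels, target_spacing) {
  stopifnot(inherits(labels, "label_volume"))
  target_spacing <- check_triple(target_spacing, "target_spacing", positive = TRUE)
  if (all(abs(target_spacing - labels$spacing) < 1e-9)) return(labels)
  in_dim <- dim(labels$data)
  out_dim <- pmax(1L, as.integer(round(in_dim * labels$spacing / target_spacing)))
  grids <- lapply(1:3, function(k) {
    idx <- round(((seq_len(out_dim[k]) - 1) * target_spacing[k]) / labels$spacing[k] + 1)
    as.integer(pmin(pmax(idx, 1), in_dim[k]))
  })
  out <- labels$data[grids[[1]], grids[[2]], grids[[3]], drop = FALSE]
  new_affine <- labels$affine
  for (k in 1:3) new_affine[, k] <- labels$affine[, k] * target_spacing[k] / labels$spacing[k]
  label_volume(out, legend = labels$legend, spacing = target_spacing, affine = new_affine)
}

#' Flatten masked voxels into the analysis table
#'
#' One row per masked, all-finite voxel; columns follow `feature_names`.
#' Coordinates are 1-based voxel indices in x-fastest order, so the
#' coordinate-to-row mapping is invertible (see [scatter_to_grid()]).
#'
#' @param volume a `feature_volume`.
#' @param mask optional `label_volume` (non-zero = keep) on the same grid.
#' @return a `voxel_table`: list with `coords` (n x 3 integer), `features`
#'   (n x N numeric), `feature_names`, `grid`, `spacing`, `affine`.
#' @export
build_voxel_table <- function(volume, mask = NULL) {
  stopifnot(inherits(volume, "feature_volume"))
  keep <- volume$mask
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "label_volume"))
    if (!all(dim(mask$data) == dim(keep))) stopf("mask grid does not match volume grid")
    keep <- keep & (mask$data != 0L)
  }
  if (!any(keep)) stopf("mask is empty: no voxels to analyze")
  coords <- which(keep, arr.ind = TRUE)
  colnames(coords) <- c("x", "y", "z")
  n_feat <- dim(volume$data)[4]
  flat <- matrix(volume$data, ncol = n_feat)
  features <- flat[which(keep), , drop = FALSE]
  colnames(features) <- volume$feature_names
  structure(
    list(coords = coords, features = features,
         feature_names = volume$feature_names,
         grid = dim(volume$data)[1:3], spacing = volume$spacing,
         affine = volume$affine),
    class = "voxel_table"
  )
}

#' @export
print.voxel_table <- function(x, ...) {
  cat(sprintf("<voxel_table> %d voxels x %d features on a %s grid\n",
              nrow(x$features), ncol(x$features), paste(x$grid, collapse = " x ")))
  invisible(x)
}

#' Scatter per-voxel values back onto the image grid
#'
#' Inverse of [build_voxel_table()]: places `values[i]` at `coords[i, ]` and
#' `fill` elsewhere.
#'
#' @param table a `voxel_table`.
#' @param values vector with one entry per table row.
#' @param fill value for voxels outside the mask (default 0).
#' @return a 3D array on the table's grid.
#' @export
scatter_to_grid <- function(table, values, fill = 0) {
  stopifnot(inherits(table, "voxel_table"))
  if (length(values) != nrow(table$coords)) {
    stopf("`values` has length %d but the table has %d rows",
          length(values), nrow(table$coords))
  }
  out <- array(fill, dim = table$grid)
  out[table$coords] <- values
  out
}
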