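# Synthetic multi-feature phantom with ground-truth tissue labels.
#
# The phantom stands in for a co-registered stack of MRI-derived feature maps:
# each tissue class has a mean vector and standard deviation per feature, and
# voxel values are class mean + within-class Gaussian scatter + global
# acquisition noise. A shell of configurable width between each focal class
# (e.g. tumor) and the background receives the arithmetic mean of the two
# adjacent class mean vectors, mimicking partial-volume interface tissue.

#' Define a tissue class for the phantom
#'
#' @param name class name (e.g. `"healthy"`, `"tumor"`).
#' @param geometry region descriptor: `list(type = "background")` claims all
#'   voxels not taken by any other class; `list(type = "ellipsoid", center =
#'   c(x, y, z), radii = c(rx, ry, rz))` (voxel units, 1-based continuous
#'   indices); `list(type = "box", min = c(...), max = c(...))`; or
#'   `list(type = "voxels", coords = <n x 3 integer matrix>)`.
#' @param feature_means numeric vector, one mean per feature.
#' @param feature_sds positive numeric vector, one within-class sd per feature.
#' @return a `tissue_class` object.
#' @export
tissue_class <- function(name, geometry, feature_means, feature_sds) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.list(geometry) || is.null(geometry$type)) {
    stopf("tissue class '%s': `geometry` must be a list with a `type`", name)
  }
  if (!geometry$type %in% c("background", "ellipsoid", "box", "voxels")) {
    stopf("tissue class '%s': unknown geometry type '%s'", name, geometry$type)
  }
  if (length(feature_means) != length(feature_sds)) {
    stopf("tissue class '%s': feature_means and feature_sds differ in length", name)
  }
  if (any(feature_sds < 0)) stopf("tissue class '%s': feature_sds must be >= 0", name)
  structure(
    list(name = name, geometry = geometry,
         feature_means = as.numeric(feature_means),
         feature_sds = as.numeric(feature_sds)),
    class = "tissue_class"
  )
}

#' Specify a synthetic phantom
#'
#' @param grid_shape integer triple, voxels per axis (all >= 4).
#' @param voxel_spacing mm triple.
#' @param n_features number of feature volumes (>= 2).
#' @param tissue_classes list of [tissue_class()] objects; a default spec must
#'   contain at least a background ("healthy") and one focal ("tumor") class.
#' @param interface_width non-negative integer; width in voxels of the
#'   partial-volume shell grown from each focal class into the background.
#' @param noise_sd global acquisition noise sd, scalar or per-feature vector.
#' @param seed integer RNG seed.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape, voxel_spacing, n_features, tissue_classes,
                         interface_width = 1L, noise_sd = 0, seed = 42L) {
  grid_shape <- as.integer(check_triple(grid_shape, "grid_shape", positive = TRUE))
  if (any(grid_shape < 4L)) stopf("grid_shape axes must all be >= 4")
  voxel_spacing <- check_triple(voxel_spacing, "voxel_spacing", positive = TRUE)
  if (!is_scalar_number(n_features) || n_features < 2) {
    stopf("n_features must be a single integer >= 2")
  }
  n_features <- as.integer(n_features)
  if (!length(tissue_classes)) stopf("at least one tissue class is required")
  for (cl in tissue_classes) {
    if (!inherits(cl, "tissue_class")) stopf("tissue_classes must be tissue_class objects")
    if (length(cl$feature_means) != n_features) {
      stopf("tissue class '%s': feature_means has length %d, expected n_features = %d",
            cl$name, length(cl$feature_means), n_features)
    }
  }
  if (length(noise_sd) == 1L) noise_sd <- rep(as.numeric(noise_sd), n_features)
  if (length(noise_sd) != n_features || any(noise_sd < 0)) {
    stopf("noise_sd must be a non-negative scalar or length-n_features vector")
  }
  if (!is_scalar_number(interface_width) || interface_width < 0) {
    stopf("interface_width must be a non-negative integer")
  }
  structure(
    list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
         n_features = n_features, tissue_classes = tissue_classes,
         interface_width = as.integer(interface_width),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default phantom: tumor ellipsoid in healthy background
#'
#' A 64 x 64 x 8 grid at 0.37 x 0.37 x 5.5 mm spacing with 21 features, one
#' tumor ellipsoid inside a healthy background and a 1-voxel partial-volume
#' interface shell. Per-feature tumor/healthy contrast varies between 0.6 and
#' 3 healthy standard deviations with alternating sign (features differ in how
#' well they discriminate tissue, as in real multimodal stacks), and the tumor
#' class has a larger within-class sd than healthy tissue (intratumor
#' heterogeneity). See the methods vignette for the rationale behind each
#' default value.
#'
#' @param seed RNG seed (default 42).
#' @param noise_sd global acquisition noise sd (default 3).
#' @param satellites if `TRUE`, add two small tumor-profile spots in the
#'   healthy region (off by default).
#' @return a `phantom_spec`.
#' @export
default_phantom_spec <- function(seed = 42L, noise_sd = 3, satellites = FALSE) {
  n <- 21L
  healthy_means <- 100 + 2 * (seq_len(n) - 1)
  # Fixed contrast pattern: magnitudes 5..24 intensity units (0.6-3 x healthy
  # sd of 8), signs alternating so features are not mutually redundant.
  contrast <- c(24, -16, 12, -24, 8, 20, -12, 16, -8, 22, 14,
                -20, 16, -12, 10, -18, 24, -8, 20, -24, 5)
  tumor_means <- healthy_means + contrast
  classes <- list(
    tissue_class("healthy", list(type = "background"),
                 healthy_means, rep(8, n)),
    tissue_class("tumor",
                 list(type = "ellipsoid", center = c(32.5, 32.5, 4.5),
                      radii = c(22, 22, 3)),
                 tumor_means, rep(14, n))
  )
  if (satellites) {
    classes <- c(classes, list(
      tissue_class("satellite_a",
                   list(type = "ellipsoid", center = c(10, 52, 4), radii = c(3, 3, 1.2)),
                   tumor_means, rep(14, n)),
      tissue_class("satellite_b",
                   list(type = "ellipsoid", center = c(55, 12, 5), radii = c(2.5, 2.5, 1.2)),
                   tumor_means, rep(14, n))
    ))
  }
  phantom_spec(
    grid_shape = c(64L, 64L, 8L),
    voxel_spacing = c(0.37, 0.37, 5.5),
    n_features = n,
    tissue_classes = classes,
    interface_width = 1L,
    noise_sd = noise_sd,
    seed = seed
  )
}

# Rasterize one geometry into a logical mask on the grid.
rasterize_geometry <- function(geometry, grid_shape) {
  if (geometry$type == "background") {
    return(NULL) # resolved after all explicit classes
  }
  idx <- array(FALSE, dim = grid_shape)
  if (geometry$type == "ellipsoid") {
    ctr <- check_triple(geometry$center, "center")
    rad <- check_triple(geometry$radii, "radii", positive = TRUE)
    x <- (seq_len(grid_shape[1]) - ctr[1]) / rad[1]
    y <- (seq_len(grid_shape[2]) - ctr[2]) / rad[2]
    z <- (seq_len(grid_shape[3]) - ctr[3]) / rad[3]
    d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
    idx[d2 <= 1] <- TRUE
  } else if (geometry$type == "box") {
    lo <- pmax(1L, as.integer(geometry$min))
    hi <- pmin(grid_shape, as.integer(geometry$max))
    if (any(lo > hi)) stopf("box geometry is empty on this grid")
    idx[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  } else if (geometry$type == "voxels") {
    co <- as.matrix(geometry$coords)
    if (ncol(co) != 3L) stopf("voxels geometry needs an n x 3 coordinate matrix")
    idx[co] <- TRUE
  }
  idx
}

# One 6-connected binary dilation step.
dilate_once <- function(mask) {
  d <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

dilate <- function(mask, width) {
  for (i in seq_len(width)) mask <- dilate_once(mask)
  mask
}

#' Generate a synthetic phantom
#'
#' Draws the feature stack and ground-truth label volume described by a
#' [phantom_spec()]. Every voxel belongs to exactly one class; interface
#' voxels (the shell of width `interface_width` grown from each focal class
#' into the background) form an extra class labeled `"interface"` whose mean
#' vector is the arithmetic mean of the two adjacent classes and whose
#' within-class sd is their average. Identical spec + seed reproduces
#' bit-identical output.
#'
#' @param spec a `phantom_spec`.
#' @return list with `volume` (a [feature_volume()]) and `truth` (a
#'   `label_volume` whose legend maps label integers to class names).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  n_feat <- spec$n_features
  classes <- spec$tissue_classes

  bg_idx <- which(vapply(classes, function(cl) cl$geometry$type == "background", logical(1)))
  if (length(bg_idx) > 1L) stopf("at most one background class is allowed")
  explicit <- setdiff(seq_along(classes), bg_idx)

  masks <- vector("list", length(classes))
  for (i in explicit) masks[[i]] <- rasterize_geometry(classes[[i]]$geometry, gs)

  # Disjointness check before interface dilation.
  if (length(explicit) > 1L) {
    for (a in seq_along(explicit)) {
      for (b in seq_len(a - 1L)) {
        ia <- explicit[a]; ib <- explicit[b]
        if (any(masks[[ia]] & masks[[ib]])) {
          stopf("tissue classes '%s' and '%s' overlap",
                classes[[ia]]$name, classes[[ib]]$name)
        }
      }
    }
  }

  label <- array(0L, dim = gs)
  for (i in explicit) label[masks[[i]]] <- i
  if (length(bg_idx) == 1L) {
    masks[[bg_idx]] <- label == 0L
    label[masks[[bg_idx]]] <- bg_idx
  }
  if (any(label == 0L)) {
    stopf("grid not fully covered: add a background class or cover all voxels")
  }

  legend <- stats::setNames(seq_along(classes),
                            vapply(classes, `[[`, character(1), "name"))

  # Interface shell: grown from each non-background class into the background.
  interface_label <- 0L
  interface_of <- integer(0)
  if (spec$interface_width > 0L && length(bg_idx) == 1L && length(explicit)) {
    interface_label <- length(classes) + 1L
    legend <- c(legend, stats::setNames(interface_label, "interface"))
    shell_owner <- array(0L, dim = gs)
    for (i in explicit) {
      shell <- dilate(masks[[i]], spec$interface_width) & masks[[bg_idx]]
      shell_owner[shell & shell_owner == 0L] <- i
    }
    in_shell <- shell_owner > 0L
    label[in_shell] <- interface_label
    interface_of <- shell_owner
  }

  mean_map <- matrix(0, nrow = prod(gs), ncol = n_feat)
  sd_map <- matrix(0, nrow = prod(gs), ncol = n_feat)
  for (i in seq_along(classes)) {
    sel <- label == i
    if (!any(sel)) next
    mean_map[sel, ] <- matrix(classes[[i]]$feature_means, sum(sel), n_feat, byrow = TRUE)
    sd_map[sel, ] <- matrix(classes[[i]]$feature_sds, sum(sel), n_feat, byrow = TRUE)
  }
  if (interface_label > 0L) {
    sel <- label == interface_label
    if (any(sel)) {
      owner <- interface_of[sel]
      bg <- classes[[bg_idx]]
      for (i in unique(owner)) {
        pick <- sel
        pick[pick] <- owner == i
        mid_mean <- (classes[[i]]$feature_means + bg$feature_means) / 2
        mid_sd <- (classes[[i]]$feature_sds + bg$feature_sds) / 2
        mean_map[pick, ] <- matrix(mid_mean, sum(pick), n_feat, byrow = TRUE)
        sd_map[pick, ] <- matrix(mid_sd, sum(pick), n_feat, byrow = TRUE)
      }
    }
  }

  data <- array(0, dim = c(gs, n_feat))
  with_seed(spec$seed, {
    for (f in seq_len(n_feat)) {
      total_sd <- sqrt(sd_map[, f]^2 + spec$noise_sd[f]^2)
      data[, , , f] <- mean_map[, f] + stats::rnorm(prod(gs), 0, total_sd)
    }
  })

  feature_names <- sprintf("feature_%02d", seq_len(n_feat))
  vol <- feature_volume(data, spacing = spec$voxel_spacing,
                        feature_names = feature_names)
  truth <- label_volume(label, legend = legend, spacing = spec$voxel_spacing,
                        affine = vol$affine)
  list(volume = vol, truth = truth)
}

#' Write a phantom to disk as NIfTI volumes
#'
#' One NIfTI file per feature plus an integer ground-truth label volume, a
#' legend JSON, and a feature manifest usable with [load_feature_volumes()].
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- phantom$volume
  paths <- character(0)
  for (f in seq_along(vol$feature_names)) {
    p <- file.path(dir, paste0(vol$feature_names[f], ".nii"))
    write_nifti(vol$data[, , , f, drop = TRUE], p, spacing = vol$spacing,
                affine = vol$affine, datatype = "float32")
    paths <- c(paths, p)
  }
  manifest <- file.path(dir, "features.manifest")
  writeLines(paste(vol$feature_names, basename(paths), sep = "\t"), manifest)
  truth_path <- file.path(dir, "ground_truth.nii")
  write_nifti(phantom$truth$data, truth_path, spacing = vol$spacing,
              affine = vol$affine, datatype = "int32")
  legend_path <- file.path(dir, "ground_truth_legend.json")
  jsonlite::write_json(as.list(phantom$truth$legend), legend_path, auto_unbox = TRUE)
  invisible(c(paths, manifest, truth_path, legend_path))
}

#' Serialize / restore a phantom spec as JSON
#'
#' The round trip is lossless: `read_phantom_spec(write_phantom_spec(s, p))`
#' reproduces `s` exactly.
#'
#' @param spec a `phantom_spec`.
#' @param path JSON file path.
#' @return `write_phantom_spec`: the path, invisibly. `read_phantom_spec`: a
#'   `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  obj <- list(
    grid_shape = spec$grid_shape,
    voxel_spacing = spec$voxel_spacing,
    n_features = spec$n_features,
    interface_width = spec$interface_width,
    noise_sd = spec$noise_sd,
    seed = spec$seed,
    tissue_classes = lapply(spec$tissue_classes, function(cl) {
      g <- cl$geometry
      if (!is.null(g$coords)) g$coords <- apply(as.matrix(g$coords), 1, as.integer, simplify = FALSE)
      list(name = cl$name, geometry = g,
           feature_means = cl$feature_means, feature_sds = cl$feature_sds)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  classes <- lapply(obj$tissue_classes, function(cl) {
    g <- cl$geometry
    if (!is.null(g$coords)) g$coords <- do.call(rbind, lapply(g$coords, as.integer))
    tissue_class(cl$name, g, unlist(cl$feature_means), unlist(cl$feature_sds))
  })
  phantom_spec(
    grid_shape = unlist(obj$grid_shape),
    voxel_spacing = unlist(obj$voxel_spacing),
    n_features = obj$n_features,
    tissue_classes = classes,
    interface_width = obj$interface_width,
    noise_sd = unlist(obj$noise_sd),
    seed = obj$seed
  )
}
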