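# Back-projection and the end-to-end pipeline driver.
#
# Back-projection assigns every masked voxel the label of the network node
# (cluster) it belongs to, producing a segmentation on the original image
# grid at the original spatial resolution. The driver chains phantom/load ->
# voxel table -> (optional k sweep) -> clustering -> profiles -> adjacency ->
# graph -> metrics -> classification -> subnetworks -> hierarchy ->
# back-projection, writing every artifact plus a JSON run record.

#' Back-project node labels onto the image grid
#'
#' @param assignment a `cluster_assignment`.
#' @param node_labels integer vector mapping cluster id -> output label,
#'   either positional (length k) or named by cluster id. Every cluster must
#'   be covered.
#' @param table the `voxel_table` the assignment was computed from (carries
#'   grid, spacing, affine).
#' @param legend optional named integer legend stored on the result.
#' @return a `label_volume`; unmasked voxels are 0.
#' @export
backproject <- function(assignment, node_labels, table, legend = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"), inherits(table, "voxel_table"))
  k <- assignment$k
  if (!is.null(names(node_labels))) {
    lab <- node_labels[as.character(seq_len(k))]
    if (anyNA(lab)) {
      stopf("no label for node(s): %s",
            paste(setdiff(as.character(seq_len(k)), names(node_labels)), collapse = ", "))
    }
  } else {
    if (length(node_labels) != k) {
      stopf("node_labels has length %d but there are %d nodes", length(node_labels), k)
    }
    lab <- node_labels
  }
  voxel_labels <- as.integer(lab)[assignment$labels]
  label_volume(scatter_to_grid(table, voxel_labels), legend = legend,
               spacing = table$spacing, affine = table$affine)
}

# Fixed label scheme for the segmentation volume: major subnetworks get
# 1..S (1 = largest), bridges S+1, satellite groups S+2, unassigned nodes
# S+3; the hierarchy overlay relabels the selected subnetwork's voxels to
# 10 + group.
segmentation_labels <- function(classification) {
  major <- sort(unique(classification$subnetwork_id[
    !is.na(classification$subnetwork_id) & !classification$is_satellite]))
  s <- length(major)
  lab <- integer(nrow(classification))
  for (i in seq_along(major)) {
    lab[!is.na(classification$subnetwork_id) &
          classification$subnetwork_id == major[i] &
          !classification$is_satellite] <- i
  }
  lab[classification$role == "bridge"] <- s + 1L
  lab[classification$is_satellite] <- s + 2L
  lab[lab == 0L] <- s + 3L
  legend <- c(
    stats::setNames(seq_len(s), sprintf("subnetwork_%d", seq_len(s))),
    stats::setNames(s + 1L, "bridge"),
    stats::setNames(s + 2L, "satellite"),
    stats::setNames(s + 3L, "unassigned")
  )
  list(labels = stats::setNames(lab, classification$node), legend = legend,
       n_major = s)
}

#' Assign anatomical identities to subnetworks by ground-truth overlap
#'
#' Identities (e.g. tumor vs healthy) are never guessed from topology alone:
#' each major subnetwork is named after the reference class holding the
#' majority of its back-projected voxels. Reference voxels labeled as
#' interface are excluded from the vote (they belong to neither side by
#' construction).
#'
#' @param segmentation `label_volume` from the pipeline (subnetwork labels).
#' @param truth reference `label_volume` (phantom ground truth or an
#'   anatomical mask) on the same grid, with a legend.
#' @param exclude legend names in `truth` to drop from the vote
#'   (default `"interface"`).
#' @return data.frame: `segment_label`, `segment_name`, `identity`, `purity`
#'   (majority fraction over non-excluded voxels), `n_voxels`.
#' @export
subnetwork_identity <- function(segmentation, truth, exclude = "interface") {
  stopifnot(inherits(segmentation, "label_volume"), inherits(truth, "label_volume"))
  if (!all(dim(segmentation$data) == dim(truth$data))) {
    stopf("segmentation and reference grids differ")
  }
  if (is.null(truth$legend)) stopf("reference label volume needs a legend")
  drop_vals <- truth$legend[names(truth$legend) %in% exclude]
  seg_vals <- sort(setdiff(unique(as.vector(segmentation$data)), 0L))
  rows <- lapply(seg_vals, function(v) {
    sel <- segmentation$data == v & truth$data != 0L
    n_all <- sum(sel)
    sel_vote <- sel & !(truth$data %in% drop_vals)
    if (!sum(sel_vote)) {
      return(data.frame(segment_label = v, identity = NA_character_,
                        purity = NA_real_, n_voxels = n_all))
    }
    tab <- table(truth$data[sel_vote])
    win <- as.integer(names(tab)[which.max(tab)])
    data.frame(
      segment_label = v,
      identity = names(truth$legend)[match(win, truth$legend)],
      purity = max(tab) / sum(tab),
      n_voxels = n_all
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(segmentation$legend)) {
    out$segment_name <- names(segmentation$legend)[match(out$segment_label,
                                                         segmentation$legend)]
    out <- out[, c("segment_label", "segment_name", "identity", "purity", "n_voxels")]
  }
  out
}

#' Assemble a pipeline configuration
#'
#' Exactly one of `phantom_spec` / `manifest` / `paths` provides the input.
#'
#' @param phantom_spec a [phantom_spec()] (synthetic input).
#' @param manifest path to a feature manifest (see
#'   [read_feature_manifest()]).
#' @param paths character vector of NIfTI feature paths.
#' @param mask_path optional NIfTI mask.
#' @param k number of clusters (default 20).
#' @param k_sweep optional integer vector; when given, a cluster-number
#'   sweep report is produced alongside the main run.
#' @param method clustering method.
#' @param seed integer seed driving every random stage.
#' @param edge_threshold number in \[0, 1) or `"auto"`.
#' @param target_density density target for the auto threshold (0.20).
#' @param role_thresholds overrides for [classify_nodes()].
#' @param min_subnetwork_size major-subnetwork cutoff (default 3).
#' @param n_groups hierarchy degree groups (default 4).
#' @param hierarchy_subnetwork subnetwork to stratify: a subnetwork id, or
#'   `"tumor"` to pick the tumor-identified one when ground truth is
#'   available (default 1 = largest).
#' @param output_dir where artifacts are written.
#' @param cor_use `"all"` or `"mean"` statistic vectors for the adjacency.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(phantom_spec = NULL, manifest = NULL, paths = NULL,
                            mask_path = NULL, k = 20L, k_sweep = NULL,
                            method = "kmeans", seed = 42L,
                            edge_threshold = "auto", target_density = 0.20,
                            role_thresholds = list(), min_subnetwork_size = 3L,
                            n_groups = 4L, hierarchy_subnetwork = 1L,
                            output_dir = tempfile("radionet_run_"),
                            cor_use = "all") {
  n_inputs <- sum(!is.null(phantom_spec), !is.null(manifest), !is.null(paths))
  if (n_inputs != 1L) {
    stopf("exactly one of phantom_spec / manifest / paths must be given (got %d)", n_inputs)
  }
  structure(
    list(phantom_spec = phantom_spec, manifest = manifest, paths = paths,
         mask_path = mask_path, k = as.integer(k), k_sweep = k_sweep,
         method = method, seed = as.integer(seed),
         edge_threshold = edge_threshold, target_density = target_density,
         role_thresholds = role_thresholds,
         min_subnetwork_size = as.integer(min_subnetwork_size),
         n_groups = as.integer(n_groups),
         hierarchy_subnetwork = hierarchy_subnetwork,
         output_dir = output_dir, cor_use = cor_use),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file.
#' @param config a `pipeline_config`.
#' @return `read_pipeline_config`: a `pipeline_config`;
#'   `write_pipeline_config`: the path, invisibly.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(obj$phantom_spec_file)) {
    obj$phantom_spec <- read_phantom_spec(obj$phantom_spec_file)
    obj$phantom_spec_file <- NULL
  }
  if (!is.null(obj$k_sweep)) obj$k_sweep <- unlist(obj$k_sweep)
  if (!is.null(obj$paths)) obj$paths <- unlist(obj$paths)
  do.call(pipeline_config, obj)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  if (!is.null(obj$phantom_spec)) {
    spec_path <- sub("\\.json$", "_phantom_spec.json", path)
    if (identical(spec_path, path)) spec_path <- paste0(path, ".phantom_spec.json")
    write_phantom_spec(obj$phantom_spec, spec_path)
    obj$phantom_spec <- NULL
    obj$phantom_spec_file <- spec_path
  }
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full image-to-network pipeline
#'
#' Executes every stage and writes: cluster assignment and segmentation
#' NIfTI volumes, profile / metric / classification / adjacency CSVs, the
#' GraphML + edge-list exports, the optional k-sweep report, the hierarchy
#' overlay volume, and a JSON run record sufficient to reproduce the run.
#' Fully deterministic given the config (including its seed).
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress per-stage progress messages.
#' @return a `pipeline_result` list: `paths` (named output files), `graph`,
#'   `classification`, `segmentation`, `identity`, `record`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[[name]] <<- round(dt, 3)
    if (!quiet) message(sprintf("[radionet] %-16s %.2fs", name, dt))
    res
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  truth <- NULL
  volume <- stage("input", {
    if (!is.null(config$phantom_spec)) {
      ph <- generate_phantom(config$phantom_spec)
      truth <- ph$truth
      ph$volume
    } else if (!is.null(config$manifest)) {
      load_feature_volumes(config$manifest, mask_path = config$mask_path)
    } else {
      load_feature_volumes(config$paths, mask_path = config$mask_path)
    }
  })
  mask <- NULL
  if (!is.null(config$mask_path) && !is.null(config$phantom_spec)) {
    m <- read_nifti(config$mask_path)
    mask <- label_volume(array(as.integer(m$data > 0), dim = dim(m$data)),
                         legend = c(mask = 1L), spacing = m$spacing)
  }
  table <- stage("voxel_table", build_voxel_table(volume, mask = mask))

  sweep_report <- NULL
  if (!is.null(config$k_sweep)) {
    sweep_report <- stage("k_sweep", k_sweep(
      table, config$k_sweep, seed = config$seed, method = config$method,
      edge_threshold = if (is.numeric(config$edge_threshold)) config$edge_threshold else 0.5
    ))
    paths$ksweep <- file.path(out_dir, "ksweep.csv")
    df <- as.data.frame(sweep_report)
    df$overfit_onset <- attr(sweep_report, "overfit_k")
    utils::write.csv(df, paths$ksweep, row.names = FALSE)
  }

  assignment <- stage("clustering", cluster_voxels(
    table, config$k, seed = config$seed, method = config$method))
  profiles <- stage("profiles", cluster_profiles(table, assignment))
  adj <- stage("adjacency", correlation_matrix(profiles, use = config$cor_use))
  rg <- stage("graph", build_graph(adj, edge_threshold = config$edge_threshold,
                                   sizes = profiles$sizes,
                                   target_density = config$target_density))
  metrics <- stage("metrics", node_metrics(rg))
  classification <- stage("classification",
                          classify_nodes(metrics, config$role_thresholds))
  classification <- stage("subnetworks",
                          extract_subnetworks(rg, classification,
                                              min_size = config$min_subnetwork_size))

  seg <- stage("backprojection", {
    sl <- segmentation_labels(classification)
    backproject(assignment, sl$labels, table, legend = sl$legend)
  })

  identity <- NULL
  if (!is.null(truth)) {
    identity <- stage("identity", subnetwork_identity(seg, truth))
  }

  hier_target <- config$hierarchy_subnetwork
  if (identical(hier_target, "tumor")) {
    hier_target <- NA_integer_
    if (!is.null(identity)) {
      hit <- which(!is.na(identity$identity) & identity$identity == "tumor" &
                     grepl("^subnetwork_", identity$segment_name))
      if (length(hit)) {
        hier_target <- as.integer(sub("^subnetwork_", "",
                                      identity$segment_name[hit[1]]))
      }
    }
    if (is.na(hier_target)) {
      warnf("no tumor-identified subnetwork; hierarchy falls back to subnetwork 1")
      hier_target <- 1L
    }
  }
  hierarchy <- NULL
  hier_vol <- NULL
  n_major <- segmentation_labels(classification)$n_major
  if (n_major >= 1 && hier_target <= n_major) {
    hierarchy <- stage("hierarchy", degree_stratify(
      rg, classification, subnetwork_id = hier_target, n_groups = config$n_groups))
    # overlay: voxels of the selected subnetwork -> 10 + group, others keep
    # their segmentation label
    node_overlay <- segmentation_labels(classification)$labels
    node_overlay[hierarchy$node] <- 10L + hierarchy$group
    legend <- c(segmentation_labels(classification)$legend,
                stats::setNames(10L + sort(unique(hierarchy$group)),
                                sprintf("degree_group_%d", sort(unique(hierarchy$group)))))
    hier_vol <- backproject(assignment, node_overlay, table, legend = legend)
  }

  stage("write", {
    paths$assignment <- file.path(out_dir, "cluster_assignment.nii")
    write_nifti(assignment_to_volume(assignment, table)$data, paths$assignment,
                spacing = table$spacing, affine = table$affine, datatype = "int32")
    paths$segmentation <- file.path(out_dir, "segmentation.nii")
    write_nifti(seg$data, paths$segmentation, spacing = table$spacing,
                affine = table$affine, datatype = "int32")
    if (!is.null(hier_vol)) {
      paths$hierarchy_volume <- file.path(out_dir, "hierarchy.nii")
      write_nifti(hier_vol$data, paths$hierarchy_volume, spacing = table$spacing,
                  affine = table$affine, datatype = "int32")
      paths$hierarchy <- file.path(out_dir, "hierarchy_groups.csv")
      utils::write.csv(hierarchy, paths$hierarchy, row.names = FALSE)
    }
    paths$profiles <- file.path(out_dir, "cluster_profiles.csv")
    utils::write.csv(as.data.frame(profiles), paths$profiles, row.names = FALSE)
    paths$adjacency <- file.path(out_dir, "adjacency.csv")
    utils::write.csv(as.data.frame(unclass(adj)), paths$adjacency, row.names = TRUE)
    paths$classification <- file.path(out_dir, "node_classification.csv")
    utils::write.csv(classification, paths$classification, row.names = FALSE)
    paths$graphml <- file.path(out_dir, "network.graphml")
    paths$edges <- file.path(out_dir, "edges.tsv")
    export_graph(rg, graphml_path = paths$graphml, edgelist_path = paths$edges)
    paths$legend <- file.path(out_dir, "segmentation_legend.json")
    jsonlite::write_json(as.list(seg$legend), paths$legend, auto_unbox = TRUE)
    if (!is.null(identity)) {
      paths$identity <- file.path(out_dir, "subnetwork_identity.csv")
      utils::write.csv(identity, paths$identity, row.names = FALSE)
    }
    if (!is.null(truth)) {
      paths$truth <- file.path(out_dir, "ground_truth.nii")
      write_nifti(truth$data, paths$truth, spacing = table$spacing,
                  affine = table$affine, datatype = "int32")
    }
    NULL
  })

  record <- list(
    package_version = as.character(utils::packageVersion("radionet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    k = assignment$k,
    method = config$method,
    edge_threshold = rg$edge_threshold,
    n_nodes = igraph::vcount(rg$graph),
    n_edges = igraph::ecount(rg$graph),
    n_voxels = nrow(table$features),
    n_features = ncol(table$features),
    role_counts = as.list(table(classification$role)),
    n_major_subnetworks = n_major,
    overfit_onset = if (!is.null(sweep_report)) attr(sweep_report, "overfit_k") else NULL,
    timings = timings,
    outputs = lapply(paths, basename),
    total_seconds = round(as.numeric(difftime(Sys.time(), t_start, units = "secs")), 3)
  )
  paths$record <- file.path(out_dir, "run_record.json")
  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  paths$config <- cfg_path
  jsonlite::write_json(record[!vapply(record, is.null, logical(1))], paths$record,
                       auto_unbox = TRUE, pretty = TRUE)

  structure(
    list(paths = paths, graph = rg, metrics = metrics,
         classification = classification, segmentation = seg,
         hierarchy = hierarchy, identity = identity, sweep = sweep_report,
         assignment = assignment, profiles = profiles, table = table,
         truth = truth, record = record),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d nodes, %d edges, %d major subnetworks; outputs in %s\n",
              x$record$n_nodes, x$record$n_edges, x$record$n_major_subnetworks,
              dirname(x$paths$record)))
  invisible(x)
}
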