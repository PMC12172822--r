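# Optional volumetric path: paint node series into a small 4D grid and
# extract them back with spherical ROIs. This exercises the sphere-
# extraction entry point for pipelines that start from already-normalized
# volumes; it does not attempt any volumetric preprocessing.

#' Paint node time series into a 4D volume
#'
#' Builds a small 4D array (x, y, z, frame) in which every node's signal is
#' written into all voxels whose centre lies within the node's sphere
#' radius. Overlapping spheres are painted in node-table order (later nodes
#' overwrite), so use spatially separated nodes when an exact round trip
#' matters.
#'
#' @param series Frames x nodes matrix (columns named by node id).
#' @param node_table Tibble with `node_id`, `x`, `y`, `z`, `radius` (mm).
#' @param voxel_mm Isotropic voxel size (default 3).
#' @param pad_mm Padding added around the bounding box of the nodes.
#' @return 4D array with attributes `voxel_mm` and `origin` (the world
#'   coordinate of voxel `[1, 1, 1]`).
#' @export
series_to_volume <- function(series, node_table, voxel_mm = 3, pad_mm = 9) {
  y <- as_series_matrix(series)
  nt <- node_table[match(colnames(y), node_table$node_id), ]
  if (anyNA(nt$node_id)) abort("Node table is missing series nodes.")
  lo <- c(min(nt$x), min(nt$y), min(nt$z)) - pad_mm
  hi <- c(max(nt$x), max(nt$y), max(nt$z)) + pad_mm
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_mm)) + 1L)
  vol <- array(0, c(dims, nrow(y)))
  centers <- lapply(1:3, function(a) lo[a] + (seq_len(dims[a]) - 1) * voxel_mm)
  for (j in seq_len(ncol(y))) {
    dx <- centers[[1]] - nt$x[j]
    dy <- centers[[2]] - nt$y[j]
    dz <- centers[[3]] - nt$z[j]
    d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    inside <- which(d2 <= nt$radius[j]^2, arr.ind = TRUE)
    if (!nrow(inside)) {
      warn(sprintf("Node %s covers no voxel at %g mm resolution.",
                   nt$node_id[j], voxel_mm))
      next
    }
    for (t in seq_len(nrow(y))) {
      vol[cbind(inside, t)] <- y[t, j]
    }
  }
  structure(vol, voxel_mm = voxel_mm, origin = lo)
}

#' Extract node time series from a 4D volume with spherical ROIs
#'
#' For every node, averages all voxels whose centre lies within the node's
#' radius of its coordinate, per frame — the standard sphere-based node
#' extraction for already-normalized volumes.
#'
#' @param volume 4D array (x, y, z, frame); grid geometry from its
#'   `voxel_mm` / `origin` attributes unless given explicitly.
#' @param node_table Tibble with `node_id`, `x`, `y`, `z`, `radius` (mm).
#' @param voxel_mm,origin Grid geometry overrides.
#' @return Frames x nodes matrix (columns named by node id).
#' @export
extract_node_series <- function(volume, node_table,
                                voxel_mm = attr(volume, "voxel_mm"),
                                origin = attr(volume, "origin")) {
  if (is.null(voxel_mm) || is.null(origin)) {
    abort("Grid geometry (`voxel_mm`, `origin`) is required.")
  }
  dims <- dim(volume)
  if (length(dims) != 4) abort("`volume` must be a 4D array.")
  centers <- lapply(1:3, function(a) {
    origin[a] + (seq_len(dims[a]) - 1) * voxel_mm
  })
  n_frames <- dims[4]
  out <- matrix(NA_real_, n_frames, nrow(node_table))
  colnames(out) <- node_table$node_id
  flat <- matrix(volume, prod(dims[1:3]), n_frames)
  for (j in seq_len(nrow(node_table))) {
    dx <- centers[[1]] - node_table$x[j]
    dy <- centers[[2]] - node_table$y[j]
    dz <- centers[[3]] - node_table$z[j]
    d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    idx <- which(d2 <= node_table$radius[j]^2)
    if (!length(idx)) {
      abort(sprintf("Node %s covers no voxel.", node_table$node_id[j]))
    }
    out[, j] <- colMeans(flat[idx, , drop = FALSE])
  }
  out
}
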