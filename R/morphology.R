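#' Plant height
#'
#' Vertical extent: difference between the maximal and minimal z ordinates.
#'
#' @param cloud metric, cropped plant [PointCloud-class].
#' @return height in meters.
#' @export
plantHeight <- function(cloud) {
  stopifnot(is(cloud, "PointCloud"))
  z <- cloud@points[, 3]
  max(z) - min(z)
}

#' Plant width (planar diameter)
#'
#' Projects all points onto the x-y plane and returns the maximal pairwise
#' planar distance, computed over the convex hull of the projection (which
#' equals the brute-force maximum).
#'
#' @param cloud metric [PointCloud-class].
#' @return width in meters.
#' @export
plantWidth <- function(cloud) {
  stopifnot(is(cloud, "PointCloud"))
  xy <- unique(cloud@points[, 1:2, drop = FALSE])
  n <- nrow(xy)
  if (n == 1L) return(0)
  hull <- if (n > 3L) tryCatch(grDevices::chull(xy[, 1], xy[, 2]),
    error = function(e) seq_len(n)) else seq_len(n)
  h <- xy[hull, , drop = FALSE]
  d2 <- outer(h[, 1], h[, 1], "-")^2 + outer(h[, 2], h[, 2], "-")^2
  sqrt(max(d2))
}

## voxel index encoding: single integer key per (i,j,k) triple
voxelKey <- function(idx, dims) {
  idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
}

voxelComponentsOf <- function(indices, connectivity = 26L) {
  m <- nrow(indices)
  if (m == 0L) return(integer(0))
  dims <- apply(indices, 2, max) + 2L   # pad so shifted keys stay unique
  keys <- voxelKey(indices, dims)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  if (connectivity == 6L)
    offsets <- offsets[rowSums(abs(offsets)) == 1, , drop = FALSE]
  # half-space of offsets is enough for an undirected graph
  lead <- offsets[, 1] * 4 + offsets[, 2] * 2 + offsets[, 3]
  offsets <- offsets[lead > 0, , drop = FALSE]
  edges <- integer(0)
  for (o in seq_len(nrow(offsets))) {
    shifted <- voxelKey(sweep(indices, 2, offsets[o, ], "+"), dims)
    hit <- match(shifted, keys)
    src <- which(!is.na(hit))
    if (length(src)) edges <- c(edges, rbind(src, hit[src]))
  }
  g <- igraph::make_graph(edges, n = m, directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components largest-first for determinism
  sizes <- tabulate(comp)
  as.integer(rank(-sizes, ties.method = "first")[comp])
}

#' Voxelize a point cloud
#'
#' Partitions space into cubic cells of edge `voxelSize` anchored at the
#' cloud's minimum corner; voxel index = floor((p - origin)/voxelSize) per
#' axis. Every point maps to exactly one voxel. Connected components of the
#' occupied set are computed with the requested connectivity.
#'
#' @param cloud metric [PointCloud-class].
#' @param voxelSize edge length in meters (> 0); default 1 cm.
#' @param connectivity 26 (faces + edges + corners, default) or 6 (faces).
#' @return a [VoxelGrid-class].
#' @export
voxelize <- function(cloud, voxelSize = 0.01, connectivity = 26L) {
  stopifnot(is(cloud, "PointCloud"))
  if (!is.finite(voxelSize) || voxelSize <= 0) stop("voxelSize must be > 0")
  connectivity <- as.integer(connectivity)
  p <- cloud@points
  origin <- apply(p, 2, min)
  idx <- floor(sweep(p, 2, origin) / voxelSize)
  # points exactly on the max face belong to the last voxel
  storage.mode(idx) <- "integer"
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  tab <- table(key)
  first <- !duplicated(key)
  uIdx <- idx[first, , drop = FALSE]
  counts <- as.integer(tab[key[first]])
  comp <- voxelComponentsOf(uIdx, connectivity)
  new("VoxelGrid", voxelSize = voxelSize, origin = as.numeric(origin),
    indices = uIdx, counts = counts, component = comp,
    connectivity = connectivity)
}

#' Remove small voxel components (noise filter)
#'
#' Connected sets of occupied voxels smaller than `minCells` are treated as
#' reconstruction noise and discarded; surviving components are untouched.
#' Idempotent.
#'
#' @param grid a [VoxelGrid-class].
#' @param minCells minimum surviving component size (default 5 cells).
#' @return filtered [VoxelGrid-class] (may be empty, with a warning).
#' @export
filterVoxelNoise <- function(grid, minCells = 5L) {
  stopifnot(is(grid, "VoxelGrid"))
  if (nrow(grid@indices) == 0L) return(grid)
  sizes <- tabulate(grid@component)
  keep <- sizes[grid@component] >= minCells
  if (!any(keep)) {
    warning("all voxel components below ", minCells, " cells; grid is empty")
    return(new("VoxelGrid", voxelSize = grid@voxelSize, origin = grid@origin,
      indices = grid@indices[0, , drop = FALSE], counts = integer(0),
      component = integer(0), connectivity = grid@connectivity))
  }
  new("VoxelGrid", voxelSize = grid@voxelSize, origin = grid@origin,
    indices = grid@indices[keep, , drop = FALSE],
    counts = grid@counts[keep],
    component = voxelComponentsOf(grid@indices[keep, , drop = FALSE],
      grid@connectivity),
    connectivity = grid@connectivity)
}

#' Plant volume from voxel occupancy
#'
#' Occupied-voxel count times cell volume. Apply [filterVoxelNoise()] first
#' so isolated reconstruction-noise blobs do not inflate the estimate.
#'
#' @param grid a (noise-filtered) [VoxelGrid-class].
#' @return volume in cubic meters (0 with a warning for an empty grid).
#' @export
plantVolume <- function(grid) {
  stopifnot(is(grid, "VoxelGrid"))
  n <- nrow(grid@indices)
  if (n == 0L) {
    warning("empty voxel grid: volume is 0")
    return(0)
  }
  n * grid@voxelSize^3
}

#' Whole-plant morphology report
#'
#' Computes height, width and noise-filtered voxel volume on the full plant
#' cloud (all labeled points), and optionally the first internode length
#' from a [NodeSet-class].
#'
#' @param cloud metric plant [PointCloud-class].
#' @param nodes optional [NodeSet-class]; adds the first internode.
#' @param stem optional stem [PointCloud-class] (needed with `nodes`).
#' @param voxelSize voxel edge for the volume (default 1 cm).
#' @param minCells voxel noise-filter threshold (default 5).
#' @param meta named list of session metadata (plant id, group, GDD, ...).
#' @return a [MorphologyReport-class].
#' @export
morphologyReport <- function(cloud, nodes = NULL, stem = NULL,
                             voxelSize = 0.01, minCells = 5L, meta = list()) {
  grid <- filterVoxelNoise(voxelize(cloud, voxelSize), minCells)
  fi <- NA_real_
  if (!is.null(nodes) && nNodes(nodes) > 0) {
    if (is.null(stem)) stop("stem cloud required to measure the first internode")
    fi <- internodeLengths(nodes, stem)@firstInternode
  }
  new("MorphologyReport", height = plantHeight(cloud),
    width = plantWidth(cloud), volume = plantVolume(grid),
    firstInternode = fi, meta = meta)
}

#' Morphology report as a one-row data frame (cm / m^3)
#'
#' @param report a [MorphologyReport-class].
#' @return data.frame with plant_id, group, gdd, height_cm, width_cm,
#'   volume_m3, first_internode_cm.
#' @export
asMorphologyRow <- function(report) {
  stopifnot(is(report, "MorphologyReport"))
  m <- report@meta
  data.frame(
    plant_id = if (is.null(m$plant_id)) NA_character_ else m$plant_id,
    group = if (is.null(m$group)) NA_character_ else m$group,
    gdd = if (is.null(m$gdd)) NA_real_ else m$gdd,
    height_cm = 100 * report@height,
    width_cm = 100 * report@width,
    volume_m3 = report@volume,
    first_internode_cm = 100 * report@firstInternode,
    stringsAsFactors = FALSE)
}
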