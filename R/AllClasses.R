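#' @useDynLib tensorPheno, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' PointCloud: a single-plant 3-D point cloud
#'
#' Holds an ordered set of 3-D points, optional per-point RGB colors, and a
#' frame flag recording whether coordinates are still in the arbitrary units
#' of the photogrammetric reconstruction (`"raw"`) or have been scaled to
#' meters (`"metric"`). All downstream analysis (segmentation, morphology)
#' requires a metric cloud; see [scaleCloud()].
#'
#' The gravity axis is assumed to be +z: plant height is measured along z and
#' soil removal is a z-threshold. Clouds reconstructed in another orientation
#' must be rotated before use.
#'
#' @slot points numeric matrix, N x 3 (x, y, z). N >= 1, all finite.
#' @slot colors integer matrix N x 3 (RGB, 0-255) or NULL.
#' @slot frame `"raw"` or `"metric"`.
#' @export
setClass("PointCloud",
  representation(points = "matrix", colors = "ANY", frame = "character"),
  prototype(colors = NULL, frame = "raw"))

setValidity("PointCloud", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L) return("points must be a numeric N x 3 matrix")
  if (nrow(p) < 1L) return("point cloud must contain at least one point")
  if (!all(is.finite(p))) return("all coordinates must be finite")
  if (!object@frame %in% c("raw", "metric")) return("frame must be 'raw' or 'metric'")
  if (!is.null(object@colors)) {
    if (!is.matrix(object@colors) || nrow(object@colors) != nrow(p) ||
        ncol(object@colors) != 3L)
      return("colors must be NULL or an N x 3 matrix")
  }
  TRUE
})

#' TensorField: per-point first/second-order tensor structure
#'
#' For every point i, the first-order tensor t_i = sum_j (x_i - x_j) over its
#' neighborhood, the (unnormalized) second-order tensor
#' T_i = sum_j (x_j - x_i)(x_j - x_i)^T stored as its six unique entries, the
#' eigenvalues sorted descending, the orthonormal eigenvectors, and the
#' stick/plate/sphere saliencies (lambda1-lambda2, lambda2-lambda3, lambda3).
#' Points with fewer than `minNeighbors` neighbors are flagged degenerate and
#' carry NA rows.
#'
#' @slot firstOrder numeric N x 3.
#' @slot secondOrder numeric N x 6 (xx, xy, xz, yy, yz, zz).
#' @slot eigenvalues numeric N x 3, descending, non-negative.
#' @slot eigenvectors numeric N x 9 (v1, v2, v3 concatenated).
#' @slot saliencies numeric N x 3 (stick, plate, sphere).
#' @slot meanDist numeric N: mean neighbor distance (for magnitude scaling).
#' @slot neighborCount integer N.
#' @slot degenerate logical N.
#' @export
setClass("TensorField",
  representation(firstOrder = "matrix", secondOrder = "matrix",
    eigenvalues = "matrix", eigenvectors = "matrix", saliencies = "matrix",
    meanDist = "numeric", neighborCount = "integer", degenerate = "logical"))

setValidity("TensorField", function(object) {
  n <- nrow(object@firstOrder)
  dims <- c(nrow(object@secondOrder), nrow(object@eigenvalues),
            nrow(object@eigenvectors), nrow(object@saliencies),
            length(object@meanDist), length(object@neighborCount),
            length(object@degenerate))
  if (any(dims != n)) return("inconsistent per-point dimensions")
  ok <- !object@degenerate
  ev <- object@eigenvalues[ok, , drop = FALSE]
  if (nrow(ev) && (any(ev < -1e-8) ||
      any(ev[, 1] < ev[, 2] - 1e-8) || any(ev[, 2] < ev[, 3] - 1e-8)))
    return("eigenvalues must be non-negative and sorted descending")
  TRUE
})

#' OrganLabels: per-point leaf/stem classification
#'
#' @slot labels character N in {"stem", "leaf", "unassigned"}.
#' @slot stage `"second_order"` or `"refined"`.
#' @slot scores numeric N x 4: planar_ratio (lambda2/lambda1), linear_ratio
#'   ((lambda1-lambda2)/lambda1), flatness (lambda3/lambda1), and the
#'   normalized first-order magnitude.
#' @slot degenerate logical N (too few neighbors; always "unassigned").
#' @export
setClass("OrganLabels",
  representation(labels = "character", stage = "character",
    scores = "matrix", degenerate = "logical"))

setValidity("OrganLabels", function(object) {
  if (!all(object@labels %in% c("stem", "leaf", "unassigned")))
    return("labels must be stem/leaf/unassigned")
  if (!object@stage %in% c("second_order", "refined"))
    return("stage must be 'second_order' or 'refined'")
  if (nrow(object@scores) != length(object@labels) ||
      length(object@degenerate) != length(object@labels))
    return("inconsistent per-point dimensions")
  TRUE
})

#' NodeSet: detected stem nodes (petiole junctions)
#'
#' @slot nodes numeric m x 3 centroids in meters, strictly ascending z.
#' @slot supportCounts integer m: points in each high-lambda2 region.
#' @slot lambda2Threshold the lambda2/lambda1 ratio threshold used.
#' @export
setClass("NodeSet",
  representation(nodes = "matrix", supportCounts = "integer",
    lambda2Threshold = "numeric"))

setValidity("NodeSet", function(object) {
  m <- nrow(object@nodes)
  if (m != length(object@supportCounts)) return("support count mismatch")
  if (m > 0 && ncol(object@nodes) != 3L) return("nodes must be m x 3")
  if (m > 1 && any(diff(object@nodes[, 3]) <= 0))
    return("node centroids must be strictly increasing in z")
  TRUE
})

#' VoxelGrid: occupancy grid over a point cloud
#'
#' @slot voxelSize edge length in meters.
#' @slot origin numeric 3: minimum corner of the cloud.
#' @slot indices integer m x 3: occupied voxel indices (0-based).
#' @slot counts integer m: points per occupied voxel.
#' @slot component integer m: connected-component id per voxel.
#' @slot connectivity 6 or 26.
#' @export
setClass("VoxelGrid",
  representation(voxelSize = "numeric", origin = "numeric",
    indices = "matrix", counts = "integer", component = "integer",
    connectivity = "integer"))

setValidity("VoxelGrid", function(object) {
  if (object@voxelSize <= 0) return("voxelSize must be > 0")
  m <- nrow(object@indices)
  if (length(object@counts) != m || length(object@component) != m)
    return("inconsistent voxel dimensions")
  if (m > 0 && any(object@counts < 1L)) return("occupied voxels must hold >= 1 point")
  if (!object@connectivity %in% c(6L, 26L)) return("connectivity must be 6 or 26")
  TRUE
})

#' InternodeReport: internode lengths along the stem
#'
#' @slot firstInternode meters, stem base to first node.
#' @slot internodeLengths meters, consecutive node pairs (first included as
#'   element 1, so length == node count).
#' @slot basePoint numeric 3.
#' @export
setClass("InternodeReport",
  representation(firstInternode = "numeric", internodeLengths = "numeric",
    basePoint = "numeric"))

setValidity("InternodeReport", function(object) {
  if (any(object@internodeLengths <= 0)) return("internode lengths must be > 0")
  if (length(object@basePoint) != 3L) return("basePoint must be length 3")
  TRUE
})

#' MorphologyReport: whole-plant parameters
#'
#' Heights/widths/internodes in meters internally; `show` prints cm
#' (volume in cubic meters) to match field reporting conventions.
#'
#' @slot height meters.
#' @slot width meters.
#' @slot volume cubic meters.
#' @slot firstInternode meters (NA if no node was detected).
#' @slot meta named list (plant id, group, GDD, ...).
#' @export
setClass("MorphologyReport",
  representation(height = "numeric", width = "numeric", volume = "numeric",
    firstInternode = "numeric", meta = "list"),
  prototype(meta = list()))

setValidity("MorphologyReport", function(object) {
  vals <- c(object@height, object@width, object@volume)
  if (any(!is.na(vals) & vals < 0)) return("morphology values must be >= 0")
  TRUE
})
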