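#' Node-detection parameters
#'
#' @param tauNode lambda2/lambda1 ratio above which a stem point is
#'   junction-like (default 0.2). Node regions have a broader point spread
#'   than plain stem because petioles meet the stem there.
#' @param gapZ vertical gap (m) starting a new candidate region (default
#'   2 cm).
#' @param minSupport minimum points per node region (default 10).
#' @param k neighbors for the stem-restricted tensor field (default 30,
#'   reduced automatically for small stem clouds).
#' @param slabHeight thickness (m) of the basal slab defining the stem base
#'   point (default 1 cm).
#' @param tubeRadius radius (m) of the tube around the estimated stem axis
#'   within which node-candidate points must lie (default 2 cm); keeps the
#'   detection on the stem proper rather than along petiole arms.
#' @return a `NodeParams` list.
#' @export
nodeParams <- function(tauNode = 0.2, gapZ = 0.02, minSupport = 10L,
                       k = 30L, slabHeight = 0.01, tubeRadius = 0.02) {
  stopifnot(tauNode > 0, gapZ > 0, minSupport >= 1, k >= 3, slabHeight > 0,
    tubeRadius > 0)
  structure(list(tauNode = tauNode, gapZ = gapZ,
    minSupport = as.integer(minSupport), k = as.integer(k),
    slabHeight = slabHeight, tubeRadius = tubeRadius),
    class = "NodeParams")
}

#' Connected components of points carrying a given label
#'
#' Points are voxelized at `voxel` and components are taken over the
#' occupied voxels (26-connectivity), so two points are connected when a
#' chain of occupied voxels links them.
#'
#' @param cloud metric [PointCloud-class].
#' @param labels optional [OrganLabels-class]; with `label`, restricts to
#'   the points carrying that label.
#' @param label label to select when `labels` is given.
#' @param voxel linking voxel size in meters (default 1.5 cm).
#' @return integer vector: component id (largest = 1) per selected point,
#'   with attribute `index` giving the selected point indices.
#' @export
organComponents <- function(cloud, labels = NULL, label = "leaf",
                            voxel = 0.015) {
  stopifnot(is(cloud, "PointCloud"))
  idx <- if (is.null(labels)) seq_len(nPoints(cloud))
    else which(labels@labels == label)
  if (!length(idx)) return(structure(integer(0), index = integer(0)))
  sub <- cloud@points[idx, , drop = FALSE]
  origin <- apply(sub, 2, min)
  vIdx <- floor(sweep(sub, 2, origin) / voxel)
  storage.mode(vIdx) <- "integer"
  key <- paste(vIdx[, 1], vIdx[, 2], vIdx[, 3])
  first <- !duplicated(key)
  comp <- voxelComponentsOf(vIdx[first, , drop = FALSE], 26L)
  structure(comp[match(key, key[first])], index = idx)
}

#' Extract the stem-related points
#'
#' Keeps the largest connected component of the non-leaf points and reports
#' minor fragments (typically residual leaf-boundary misclassifications).
#' Unassigned points that are spatially connected to the main stem axis are
#' included by default: stem-petiole junctions have a broad 3-D point
#' spread that lands them between the pure planar and pure linear ratio
#' bands, yet they carry exactly the elevated-lambda2 signal node detection
#' relies on. Set `includeUnassigned = FALSE` for strictly stem-labeled
#' points.
#'
#' @param labels refined [OrganLabels-class].
#' @param cloud the matching [PointCloud-class].
#' @param voxel linking voxel for the connectivity (default 2.5 cm: wide
#'   enough to bridge small reconstruction voids on a thin stem).
#' @param includeUnassigned also keep unassigned points connected to the
#'   main stem component (default TRUE).
#' @param tubeRadius radius (m) of the tube swept along the component's
#'   tracked axis; any point of the cloud inside the tube is reclaimed as
#'   stem-related regardless of its spectral label (default 2 cm, NULL to
#'   disable). Junction collars are locally quasi-planar (stem plus one
#'   emerging petiole) and can be misread as leaf; laminae themselves sit
#'   a full petiole length away from the axis and stay out of the tube.
#' @return stem [PointCloud-class] with attributes `index` (original point
#'   indices) and `fragments` (number of discarded minor components).
#' @export
extractStem <- function(labels, cloud, voxel = 0.025,
                        includeUnassigned = TRUE, tubeRadius = 0.02) {
  stopifnot(is(labels, "OrganLabels"), is(cloud, "PointCloud"))
  if (!any(labels@labels == "stem"))
    stop("no stem points: segmentation failed")
  cand <- if (includeUnassigned) which(labels@labels != "leaf")
    else which(labels@labels == "stem")
  sub <- subsetCloud(cloud, cand)
  comp <- organComponents(sub, voxel = voxel)
  # main component = the one holding most stem-labeled points
  stemIn <- labels@labels[cand] == "stem"
  main <- which.max(tapply(stemIn, comp, sum))
  idx <- cand[comp == as.integer(names(main))]
  if (!any(labels@labels[idx] == "stem"))
    stop("no stem points: segmentation failed")
  if (!is.null(tubeRadius)) {
    # track the axis over all non-leaf points so it is anchored at the
    # plant base even when a junction break truncated the main component
    axis <- stemPolyline(sub, trackRadius = tubeRadius)
    p <- cloud@points
    # sweep from the cloud base up to the component top
    zlo <- min(p[, 3]); zhi <- max(p[idx, 3])
    axisXY <- if (nrow(axis) < 2L)
      matrix(axis[1, 1:2], nrow(p), 2, byrow = TRUE)
    else cbind(stats::approx(axis[, 3], axis[, 1], p[, 3], rule = 2)$y,
      stats::approx(axis[, 3], axis[, 2], p[, 3], rule = 2)$y)
    radial <- sqrt(rowSums((p[, 1:2] - axisXY)^2))
    inTube <- which(radial <= tubeRadius & p[, 3] >= zlo & p[, 3] <= zhi)
    idx <- sort(union(idx, inTube))
  }
  out <- subsetCloud(cloud, idx)
  attr(out, "index") <- idx
  attr(out, "fragments") <- max(comp) - 1L
  out
}

#' Detect nodes along the stem
#'
#' Recomputes the tensor field restricted to the stem subset and selects
#' the points whose lambda2/lambda1 ratio exceeds `tauNode`: junction areas
#' have a broader point spread (stem plus emerging petioles) and hence an
#' elevated second eigenvalue compared to plain stem points. Candidates are
#' kept only within `tubeRadius` of the estimated stem axis (per-slab xy
#' centroids of the stem cloud), so petiole arms do not smear the regions.
#' Candidates are grouped into regions by 1-D gap clustering along z (a
#' vertical gap larger than `gapZ` starts a new region) and each region
#' with at least `minSupport` points yields one node: the centroid of its
#' points, ordered by ascending z. An empty [NodeSet-class] is a valid
#' result (bare stem).
#'
#' @param stem stem [PointCloud-class] from [extractStem()].
#' @param params a [nodeParams()].
#' @return a [NodeSet-class].
#' @export
detectNodes <- function(stem, params = nodeParams()) {
  stopifnot(is(stem, "PointCloud"))
  n <- nPoints(stem)
  k <- min(params$k, n - 1L)
  empty <- new("NodeSet", nodes = matrix(numeric(0), 0, 3),
    supportCounts = integer(0), lambda2Threshold = params$tauNode)
  if (k < 3L) return(empty)
  field <- tensorField(stem, spec = neighborhoodSpec(k = k))
  ev <- field@eigenvalues
  ratio <- ifelse(!field@degenerate & ev[, 1] > 0, ev[, 2] / ev[, 1], NA)
  axis <- stemPolyline(stem, params$slabHeight)
  axisXY <- if (nrow(axis) < 2L)
    matrix(axis[1, 1:2], n, 2, byrow = TRUE)
  else
    cbind(stats::approx(axis[, 3], axis[, 1], stem@points[, 3], rule = 2)$y,
      stats::approx(axis[, 3], axis[, 2], stem@points[, 3], rule = 2)$y)
  radial <- sqrt(rowSums((stem@points[, 1:2] - axisXY)^2))
  sel <- which(is.finite(ratio) & ratio >= params$tauNode &
    radial <= params$tubeRadius)
  if (!length(sel)) return(empty)
  z <- stem@points[sel, 3]
  ord <- order(z)
  sel <- sel[ord]; z <- z[ord]
  region <- cumsum(c(1, diff(z) > params$gapZ))
  cents <- do.call(rbind, lapply(split(sel, region), function(ix) {
    if (length(ix) < params$minSupport) return(NULL)
    c(colMeans(stem@points[ix, , drop = FALSE]), length(ix))
  }))
  if (is.null(cents)) return(empty)
  ordz <- order(cents[, 3])
  new("NodeSet", nodes = cents[ordz, 1:3, drop = FALSE],
    supportCounts = as.integer(cents[ordz, 4]),
    lambda2Threshold = params$tauNode)
}

stemBasePoint <- function(stem, slabHeight = 0.01) {
  p <- stem@points
  zmin <- min(p[, 3])
  slab <- p[p[, 3] <= zmin + slabHeight, , drop = FALSE]
  # xy centroid of the basal slab; z from a low quantile so Gaussian
  # surface noise neither biases the base upward (slab-centroid z would)
  # nor downward (min z would)
  c(mean(slab[, 1]), mean(slab[, 2]),
    as.numeric(stats::quantile(slab[, 3], 0.02)))
}

#' Internode lengths from a node set
#'
#' The first internode runs from the stem base (xy centroid of the lowest
#' 1-cm stem slab) to the lowest node; subsequent internodes connect
#' consecutive node centroids. Distances are Euclidean by default; the
#' `"polyline"` method follows the stem through ordered 1-cm slab centroids
#' for curved stems.
#'
#' @param nodes a non-empty [NodeSet-class].
#' @param stem the stem [PointCloud-class] the nodes came from.
#' @param method `"euclidean"` (default) or `"polyline"`.
#' @param slabHeight basal-slab thickness in meters (default 1 cm).
#' @return an [InternodeReport-class].
#' @export
internodeLengths <- function(nodes, stem,
                             method = c("euclidean", "polyline"),
                             slabHeight = 0.01) {
  stopifnot(is(nodes, "NodeSet"), is(stem, "PointCloud"))
  method <- match.arg(method)
  if (nNodes(nodes) == 0L) stop("no nodes detected")
  base <- stemBasePoint(stem, slabHeight)
  anchors <- unname(rbind(base, nodes@nodes))
  if (method == "euclidean") {
    lens <- as.numeric(sqrt(rowSums(diff(anchors)^2)))
  } else {
    path <- stemPolyline(stem, slabHeight)
    lens <- vapply(seq_len(nrow(anchors) - 1L), function(i)
      polylineDistance(path, anchors[i, 3], anchors[i + 1L, 3]), 0)
  }
  new("InternodeReport", firstInternode = lens[1],
    internodeLengths = as.numeric(lens), basePoint = as.numeric(base))
}

# Tracked stem axis: slab-by-slab xy centroid, restricted to points near
# the previous slab's axis so petiole points in junction slabs do not drag
# the axis sideways. The basal slab (no petioles) anchors the track.
stemPolyline <- function(stem, slab = 0.01, trackRadius = 0.02) {
  p <- stem@points
  z <- p[, 3]
  bins <- floor((z - min(z)) / slab)
  groups <- split(seq_along(z), bins)
  cents <- matrix(NA_real_, length(groups), 3)
  prevXY <- NULL
  for (g in seq_along(groups)) {
    ix <- groups[[g]]
    sub <- p[ix, , drop = FALSE]
    if (!is.null(prevXY)) {
      d <- sqrt((sub[, 1] - prevXY[1])^2 + (sub[, 2] - prevXY[2])^2)
      if (any(d <= trackRadius)) {
        sub <- sub[d <= trackRadius, , drop = FALSE]
      } else {
        # nothing near the track in this slab (local break or a slab of
        # petiole points): carry the axis forward instead of jumping
        cents[g, ] <- c(prevXY, mean(sub[, 3]))
        next
      }
    }
    cents[g, ] <- colMeans(sub)
    prevXY <- cents[g, 1:2]
  }
  cents[order(cents[, 3]), , drop = FALSE]
}

polylineDistance <- function(path, z0, z1) {
  lo <- min(z0, z1); hi <- max(z0, z1)
  if (nrow(path) < 2L) return(abs(z1 - z0))
  # interpolate the axis at the exact endpoint heights, clamp outside
  zs <- path[, 3]
  endXY <- function(z) c(
    stats::approx(zs, path[, 1], z, rule = 2)$y,
    stats::approx(zs, path[, 2], z, rule = 2)$y, z)
  inner <- path[zs > lo & zs < hi, , drop = FALSE]
  seg <- rbind(endXY(lo), inner, endXY(hi))
  sum(sqrt(rowSums(diff(seg)^2)))
}

#' Full phenotyping pipeline for one plant cloud
#'
#' Segments the cloud, extracts the stem, detects nodes, and assembles the
#' morphology report (height, width, noise-filtered voxel volume, first
#' internode).
#'
#' @param cloud metric, cropped plant [PointCloud-class].
#' @param params a [segParams()].
#' @param spec a [neighborhoodSpec()].
#' @param nodePar a [nodeParams()].
#' @param voxelSize voxel edge for volume (default 1 cm).
#' @param meta named metadata list.
#' @return list with `report` ([MorphologyReport-class]), `labels`,
#'   `stem`, `nodes`, `internodes` (NULL if no nodes).
#' @export
phenotypePlant <- function(cloud, params = segParams(),
                           spec = neighborhoodSpec(k = 30),
                           nodePar = nodeParams(), voxelSize = 0.01,
                           meta = list()) {
  seg <- segmentPlant(cloud, params, spec)
  stem <- extractStem(seg$labels, cloud)
  nodes <- detectNodes(stem, nodePar)
  internodes <- if (nNodes(nodes) > 0) internodeLengths(nodes, stem) else NULL
  report <- morphologyReport(cloud, nodes = if (nNodes(nodes)) nodes,
    stem = stem, voxelSize = voxelSize, meta = meta)
  list(report = report, labels = seg$labels, stem = stem, nodes = nodes,
    internodes = internodes)
}

#' Write node centroids and internode lengths as JSON-ready list
#'
#' @param nodes a [NodeSet-class].
#' @param internodes an [InternodeReport-class] or NULL.
#' @return list with centroids (cm), supports, and lengths (cm).
#' @export
nodeReport <- function(nodes, internodes = NULL) {
  stopifnot(is(nodes, "NodeSet"))
  out <- list(
    n_nodes = nNodes(nodes),
    centroids_cm = round(100 * nodes@nodes, 3),
    support_counts = nodes@supportCounts,
    lambda2_threshold = nodes@lambda2Threshold)
  if (!is.null(internodes)) {
    out$first_internode_cm <- 100 * internodes@firstInternode
    out$internode_lengths_cm <- 100 * internodes@internodeLengths
  }
  out
}
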