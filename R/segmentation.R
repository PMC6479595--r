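#' Segmentation parameters
#'
#' All thresholds are eigenvalue ratios or normalized magnitudes, hence
#' dimensionless and invariant to global scale.
#'
#' A point is labeled leaf when lambda2/lambda1 >= `tauPlanar` and
#' lambda3/lambda1 <= `tauFlat` (even point spread on a plane, negligible
#' off-plane spread), stem when lambda2/lambda1 <= `tauLinear` (elongated
#' axial form), and unassigned in the band between. In refinement, a stem or
#' unassigned point whose normalized first-order magnitude exceeds `tauMag`
#' and whose neighborhood is at least `leafFrac` leaf-labeled is relabeled
#' leaf: leaf-boundary points have strongly asymmetric neighborhoods (large
#' first-order magnitude) while stem points, being symmetric elongated
#' structures, stay small even at their edges.
#'
#' @param tauPlanar leaf planarity threshold on lambda2/lambda1 (default 0.5).
#' @param tauFlat leaf flatness cap on lambda3/lambda1 (default 0.1, from
#'   the observation that on surface-like distributions lambda3 rarely
#'   exceeds 10% of lambda1).
#' @param tauLinear stem threshold on lambda2/lambda1 (default 0.25). Must
#'   be < `tauPlanar`.
#' @param tauMag refinement threshold on |t| / (neighborCount x mean
#'   neighbor distance) (default 0.35; interior symmetric points sit near
#'   0.15-0.2, true boundary points near 0.6).
#' @param leafFrac minimum fraction of leaf-labeled neighbors for a
#'   refinement flip (default 0.3); prevents flipping isolated stem points.
#' @return a `SegParams` list.
#' @export
segParams <- function(tauPlanar = 0.5, tauFlat = 0.1, tauLinear = 0.25,
                      tauMag = 0.35, leafFrac = 0.3) {
  if (tauLinear >= tauPlanar)
    stop("overlapping thresholds: tauLinear must be < tauPlanar")
  stopifnot(tauFlat > 0, tauMag > 0, leafFrac >= 0, leafFrac <= 1)
  structure(list(tauPlanar = tauPlanar, tauFlat = tauFlat,
    tauLinear = tauLinear, tauMag = tauMag, leafFrac = leafFrac),
    class = "SegParams")
}

labelScoresFromField <- function(field) {
  ev <- field@eigenvalues
  l1 <- ev[, 1]
  safe <- ifelse(is.finite(l1) & l1 > 0, l1, NA_real_)
  mag <- sqrt(rowSums(field@firstOrder^2))
  denom <- field@neighborCount * field@meanDist
  cbind(planar_ratio = ev[, 2] / safe,
    linear_ratio = (l1 - ev[, 2]) / safe,
    flatness = ev[, 3] / safe,
    first_order_mag = ifelse(denom > 0, mag / denom, NA_real_))
}

#' Second-order (eigenvalue-ratio) classification
#'
#' Labels every non-degenerate point leaf, stem or unassigned from the
#' eigenvalue ratios of its second-order tensor; see [segParams()] for the
#' decision rule. Degenerate points (too few neighbors, or lambda1 = 0)
#' stay unassigned.
#'
#' @param field a [TensorField-class].
#' @param params a [segParams()].
#' @return an [OrganLabels-class] with `stage = "second_order"`.
#' @export
classifySecondOrder <- function(field, params = segParams()) {
  stopifnot(is(field, "TensorField"), inherits(params, "SegParams"))
  scores <- labelScoresFromField(field)
  planar <- scores[, "planar_ratio"]
  flat <- scores[, "flatness"]
  labels <- rep("unassigned", nrow(scores))
  ok <- !field@degenerate & is.finite(planar)
  labels[ok & planar >= params$tauPlanar & flat <= params$tauFlat] <- "leaf"
  labels[ok & planar <= params$tauLinear] <- "stem"
  new("OrganLabels", labels = labels, stage = "second_order",
    scores = scores, degenerate = field@degenerate | !is.finite(planar))
}

#' First-order boundary refinement
#'
#' Repairs leaf-boundary misclassifications: stem or unassigned points with
#' a large normalized first-order magnitude that touch a leaf neighborhood
#' are relabeled leaf. Stem labels with small magnitude are retained (the
#' symmetric elongated form of stems keeps their first-order magnitude
#' small even at the stem edge).
#'
#' Adjacency is measured against the spectrally confident leaf points (the
#' points whose eigenvalue ratios satisfy the leaf rule), not against the
#' evolving label field, so leafness cannot cascade point-to-point along a
#' petiole into the stem, and a second application reproduces the same
#' flips exactly (idempotence).
#'
#' @param labels an [OrganLabels-class] (stage `"second_order"` or
#'   `"refined"`; idempotent on the latter).
#' @param field the [TensorField-class] the labels came from.
#' @param neighbors the [findNeighbors()] list used for the field.
#' @param params a [segParams()].
#' @return an [OrganLabels-class] with `stage = "refined"`.
#' @export
refineFirstOrder <- function(labels, field, neighbors, params = segParams()) {
  stopifnot(is(labels, "OrganLabels"), is(field, "TensorField"))
  lab <- labels@labels
  sc <- labels@scores
  mag <- sc[, "first_order_mag"]
  confidentLeaf <- !labels@degenerate &
    is.finite(sc[, "planar_ratio"]) &
    sc[, "planar_ratio"] >= params$tauPlanar &
    sc[, "flatness"] <= params$tauFlat
  idx <- which(!labels@degenerate & lab != "leaf" &
    is.finite(mag) & mag > params$tauMag)
  if (length(idx)) {
    frac <- vapply(idx, function(i) {
      nb <- neighbors[[i]]
      if (!length(nb)) return(0)
      mean(confidentLeaf[nb])
    }, 0)
    lab[idx[frac >= params$leafFrac]] <- "leaf"
  }
  new("OrganLabels", labels = lab, stage = "refined",
    scores = labels@scores, degenerate = labels@degenerate)
}

#' Segment a plant cloud into leaf and stem points
#'
#' Full pipeline: neighborhoods, tensor field, second-order classification,
#' first-order refinement.
#'
#' @param cloud metric, cropped, plant-only [PointCloud-class].
#' @param params a [segParams()].
#' @param spec a [neighborhoodSpec()].
#' @param refine apply first-order refinement (default TRUE).
#' @return list with `labels` ([OrganLabels-class]), `field`
#'   ([TensorField-class]), `neighbors`, and `unassignedFraction`.
#' @export
segmentPlant <- function(cloud, params = segParams(),
                         spec = neighborhoodSpec(k = 30), refine = TRUE) {
  stopifnot(is(cloud, "PointCloud"))
  nbrs <- findNeighbors(cloud, spec)
  field <- tensorField(cloud, nbrs)
  labels <- classifySecondOrder(field, params)
  if (refine) labels <- refineFirstOrder(labels, field, nbrs, params)
  list(labels = labels, field = field, neighbors = nbrs,
    unassignedFraction = mean(labels@labels == "unassigned"))
}

#' Point-wise label accuracy against ground truth
#'
#' Fraction of non-degenerate points whose label equals the reference;
#' unassigned points count as errors.
#'
#' @param labels an [OrganLabels-class].
#' @param truth character vector of reference labels ("stem"/"leaf").
#' @return scalar in `[0, 1]`.
#' @export
labelAccuracy <- function(labels, truth) {
  stopifnot(is(labels, "OrganLabels"), length(truth) == length(labels@labels))
  keep <- !labels@degenerate
  mean(labels@labels[keep] == truth[keep])
}

#' Write a labeled PLY (stem red, leaf green, unassigned gray)
#'
#' @param cloud the segmented [PointCloud-class].
#' @param labels matching [OrganLabels-class].
#' @param path output PLY path.
#' @param binary write binary PLY.
#' @return `path`, invisibly.
#' @export
writeLabeledPly <- function(cloud, labels, path, binary = FALSE) {
  stopifnot(is(cloud, "PointCloud"), is(labels, "OrganLabels"))
  colmap <- rbind(stem = c(200L, 30L, 30L), leaf = c(30L, 170L, 30L),
    unassigned = c(150L, 150L, 150L))
  writeCloud(pointCloud(cloud@points, colors = colmap[labels@labels, ],
    frame = cloud@frame), path, format = "ply", binary = binary)
}
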