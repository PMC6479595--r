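#' @rdname PointCloud-class
#' @param object,x a `PointCloud`
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname PointCloud-class
#' @export
setGeneric("cloudColors", function(x) standardGeneric("cloudColors"))

#' @rdname PointCloud-class
#' @export
setGeneric("cloudFrame", function(x) standardGeneric("cloudFrame"))

#' @rdname PointCloud-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname OrganLabels-class
#' @param x an `OrganLabels`
#' @export
setGeneric("organLabels", function(x) standardGeneric("organLabels"))

#' @rdname OrganLabels-class
#' @export
setGeneric("labelStage", function(x) standardGeneric("labelStage"))

#' @rdname OrganLabels-class
#' @export
setGeneric("labelScores", function(x) standardGeneric("labelScores"))

#' @rdname TensorField-class
#' @param x a `TensorField`
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname TensorField-class
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname TensorField-class
#' @export
setGeneric("saliencies", function(x) standardGeneric("saliencies"))

#' @rdname TensorField-class
#' @export
setGeneric("firstOrder", function(x) standardGeneric("firstOrder"))

#' @rdname NodeSet-class
#' @param x a `NodeSet`
#' @export
setGeneric("nodeCentroids", function(x) standardGeneric("nodeCentroids"))

#' @rdname NodeSet-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname VoxelGrid-class
#' @param x a `VoxelGrid`
#' @export
setGeneric("nOccupied", function(x) standardGeneric("nOccupied"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelComponents", function(x) standardGeneric("voxelComponents"))

setMethod("cloudPoints", "PointCloud", function(x) x@points)
setMethod("cloudColors", "PointCloud", function(x) x@colors)
setMethod("cloudFrame", "PointCloud", function(x) x@frame)
setMethod("nPoints", "PointCloud", function(x) nrow(x@points))

setMethod("organLabels", "OrganLabels", function(x) x@labels)
setMethod("labelStage", "OrganLabels", function(x) x@stage)
setMethod("labelScores", "OrganLabels", function(x) x@scores)

setMethod("eigenvalues", "TensorField", function(x) x@eigenvalues)
setMethod("eigenvectors", "TensorField", function(x) x@eigenvectors)
setMethod("saliencies", "TensorField", function(x) x@saliencies)
setMethod("firstOrder", "TensorField", function(x) x@firstOrder)

setMethod("nodeCentroids", "NodeSet", function(x) x@nodes)
setMethod("nNodes", "NodeSet", function(x) nrow(x@nodes))

setMethod("nOccupied", "VoxelGrid", function(x) nrow(x@indices))
setMethod("voxelComponents", "VoxelGrid", function(x) x@component)

setMethod("show", "PointCloud", function(object) {
  rng <- apply(object@points, 2, range)
  cat(sprintf("PointCloud: %d points [%s]%s\n", nrow(object@points),
      object@frame, if (is.null(object@colors)) "" else ", RGB"))
  cat(sprintf("  extent x [%.4g, %.4g]  y [%.4g, %.4g]  z [%.4g, %.4g]\n",
      rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
})

setMethod("show", "TensorField", function(object) {
  cat(sprintf("TensorField: %d points (%d degenerate)\n",
      nrow(object@firstOrder), sum(object@degenerate)))
})

setMethod("show", "OrganLabels", function(object) {
  tab <- table(factor(object@labels, c("stem", "leaf", "unassigned")))
  cat(sprintf("OrganLabels [%s]: stem %d, leaf %d, unassigned %d (%.1f%%)\n",
      object@stage, tab["stem"], tab["leaf"], tab["unassigned"],
      100 * tab["unassigned"] / length(object@labels)))
})

setMethod("show", "NodeSet", function(object) {
  cat(sprintf("NodeSet: %d nodes (lambda2/lambda1 >= %.3g)\n",
      nrow(object@nodes), object@lambda2Threshold))
  if (nrow(object@nodes))
    cat(sprintf("  z (cm): %s\n",
        paste(sprintf("%.1f", 100 * object@nodes[, 3]), collapse = ", ")))
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %d occupied voxels of %.3g m, %d component(s) [%d-conn]\n",
      nrow(object@indices), object@voxelSize,
      if (length(object@component)) max(object@component, 0L) else 0L,
      object@connectivity))
})

setMethod("show", "InternodeReport", function(object) {
  cat(sprintf("InternodeReport: first internode %.2f cm; %d internode(s)\n",
      100 * object@firstInternode, length(object@internodeLengths)))
})

setMethod("show", "MorphologyReport", function(object) {
  cat(sprintf(paste0("MorphologyReport: height %.1f cm, width %.1f cm, ",
      "volume %.3g m^3, first internode %s\n"),
      100 * object@height, 100 * object@width, object@volume,
      if (is.na(object@firstInternode)) "NA"
      else sprintf("%.1f cm", 100 * object@firstInternode)))
})
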