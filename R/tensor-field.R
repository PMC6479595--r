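#' Neighborhood specification
#'
#' Exactly one of `k` (k-nearest-neighbor mode) or `r` (fixed-radius mode)
#' must be given. kNN is density-adaptive and is the default for multi-view
#' stereo clouds, whose sampling density varies with surface visibility;
#' radius mode suits clouds of uniform density.
#'
#' @param k integer >= 3: number of neighbors (kNN mode).
#' @param r radius in meters > 0 (radius mode).
#' @param minNeighbors points with fewer neighbors are flagged degenerate
#'   and stay unclassified (default 8).
#' @return a `NeighborhoodSpec` list.
#' @export
neighborhoodSpec <- function(k = NULL, r = NULL, minNeighbors = 8L) {
  if (is.null(k) == is.null(r))
    stop("exactly one of k (knn) or r (radius) must be set")
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 3L) stop("k must be >= 3")
  }
  if (!is.null(r) && (!is.finite(r) || r <= 0)) stop("r must be > 0")
  minNeighbors <- as.integer(minNeighbors)
  if (minNeighbors < 3L) stop("minNeighbors must be >= 3")
  structure(list(mode = if (is.null(k)) "radius" else "knn",
    k = k, r = r, minNeighbors = minNeighbors), class = "NeighborhoodSpec")
}

#' Find per-point neighborhoods
#'
#' @param cloud metric [PointCloud-class].
#' @param spec a [neighborhoodSpec()].
#' @return list of 1-based integer vectors (self excluded), one per point,
#'   with attributes `spec` and `degenerate` (logical: fewer than
#'   `minNeighbors` neighbors).
#' @export
findNeighbors <- function(cloud, spec = neighborhoodSpec(k = 30)) {
  stopifnot(is(cloud, "PointCloud"), inherits(spec, "NeighborhoodSpec"))
  if (cloud@frame != "metric")
    stop("findNeighbors requires a metric cloud")
  n <- nPoints(cloud)
  if (spec$mode == "knn") {
    if (n < spec$k + 1L)
      stop("cloud has ", n, " points; knn mode needs at least k+1 = ",
        spec$k + 1L)
    idx <- cpp_knn(cloud@points, spec$k)
    nbrs <- lapply(seq_len(n), function(i) idx[i, ])
  } else {
    nbrs <- cpp_radius_neighbors(cloud@points, spec$r)
  }
  attr(nbrs, "spec") <- spec
  attr(nbrs, "degenerate") <- lengths(nbrs) < spec$minNeighbors
  nbrs
}

#' Compute the per-point tensor field
#'
#' For each point x_i with neighborhood sigma: the first-order tensor
#' t_i = sum_{j in sigma} (x_i - x_j) (a vector whose magnitude grows with
#' the asymmetry of the neighborhood), and the second-order tensor
#' T_i = sum_{j in sigma} (x_j - x_i)(x_j - x_i)^T, a symmetric
#' positive-semidefinite matrix kept unnormalized: every classification
#' criterion downstream is a ratio of eigenvalues, so normalization is
#' immaterial. Eigenvalues are sorted descending; saliencies are
#' stick = lambda1 - lambda2, plate = lambda2 - lambda3, sphere = lambda3.
#'
#' @param cloud metric [PointCloud-class].
#' @param neighbors output of [findNeighbors()]; computed with `spec` if NULL.
#' @param spec used when `neighbors` is NULL.
#' @return a [TensorField-class].
#' @export
tensorField <- function(cloud, neighbors = NULL,
                        spec = neighborhoodSpec(k = 30)) {
  stopifnot(is(cloud, "PointCloud"))
  if (is.null(neighbors)) neighbors <- findNeighbors(cloud, spec)
  minN <- attr(neighbors, "spec")$minNeighbors
  if (is.null(minN)) minN <- 3L
  res <- cpp_tensor_field(cloud@points, neighbors, minN)
  ev <- res$eigenvalues
  sal <- cbind(ev[, 1] - ev[, 2], ev[, 2] - ev[, 3], ev[, 3])
  new("TensorField", firstOrder = res$firstOrder,
    secondOrder = res$secondOrder, eigenvalues = ev,
    eigenvectors = res$eigenvectors, saliencies = sal,
    meanDist = as.numeric(res$meanDist),
    neighborCount = as.integer(res$neighborCount),
    degenerate = as.logical(res$degenerate))
}

#' First-order tensor of one neighborhood
#'
#' t = sum over neighbors of (x_i - x_j).
#'
#' @param xi numeric 3: the center point.
#' @param neighbors numeric m x 3 matrix of neighbor coordinates.
#' @return numeric 3.
#' @export
firstOrderTensor <- function(xi, neighbors) {
  neighbors <- rbind(neighbors)
  colSums(matrix(rep(xi, each = nrow(neighbors)), ncol = 3) - neighbors)
}

#' Second-order tensor of one neighborhood
#'
#' T = sum over neighbors of (x_j - x_i)(x_j - x_i)^T, unnormalized.
#'
#' @inheritParams firstOrderTensor
#' @return symmetric 3 x 3 matrix.
#' @export
secondOrderTensor <- function(xi, neighbors) {
  neighbors <- rbind(neighbors)
  d <- neighbors - matrix(rep(xi, each = nrow(neighbors)), ncol = 3)
  crossprod(d)
}

#' Spectral decomposition of a second-order tensor
#'
#' Defensively symmetrizes, sorts eigenvalues descending, clamps tiny
#' negative eigenvalues to zero, and applies a deterministic sign
#' convention (first nonzero eigenvector component positive).
#'
#' @param T symmetric positive-semidefinite 3 x 3 matrix.
#' @return list with `values` (descending) and `vectors` (columns v1,v2,v3).
#' @export
spectralDecompose <- function(T) {
  if (!is.matrix(T) || any(dim(T) != 3L) || any(!is.finite(T)))
    stop("T must be a finite 3 x 3 matrix")
  Ts <- (T + t(T)) / 2
  e <- eigen(Ts, symmetric = TRUE)   # already descending
  vals <- e$values
  tol <- 1e-10 * max(1, abs(vals[1]))
  vals[vals < 0 & vals > -tol] <- 0
  V <- e$vectors
  for (j in 1:3) {
    nz <- which(abs(V[, j]) > 1e-12)
    if (length(nz) && V[nz[1], j] < 0) V[, j] <- -V[, j]
  }
  list(values = vals, vectors = V)
}

#' Saliency decomposition
#'
#' Splits a decomposed tensor into stick (linear), plate (planar) and
#' sphere (isotropic) components:
#' T = (l1-l2) v1 v1' + (l2-l3)(v1 v1' + v2 v2') + l3 I. The scalar
#' saliencies (l1-l2, l2-l3, l3) weight each component.
#'
#' @param values eigenvalues sorted descending.
#' @param vectors 3 x 3 orthonormal eigenvector matrix (columns).
#' @return list with `stick`, `plate`, `sphere` scalars and the three
#'   component tensors (`stickTensor`, `plateTensor`, `sphereTensor`).
#' @export
saliencyDecompose <- function(values, vectors) {
  if (is.unsorted(rev(values))) stop("eigenvalues must be sorted descending")
  v1 <- vectors[, 1]; v2 <- vectors[, 2]; v3 <- vectors[, 3]
  P1 <- tcrossprod(v1)
  P12 <- P1 + tcrossprod(v2)
  P123 <- P12 + tcrossprod(v3)
  list(stick = values[1] - values[2], plate = values[2] - values[3],
    sphere = values[3],
    stickTensor = (values[1] - values[2]) * P1,
    plateTensor = (values[2] - values[3]) * P12,
    sphereTensor = values[3] * P123)
}

#' Dump per-point tensor features to CSV
#'
#' Columns: index, lambda1..3, first-order magnitude, stick, plate, sphere.
#'
#' @param field a [TensorField-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureDump <- function(field, path) {
  stopifnot(is(field, "TensorField"))
  ev <- field@eigenvalues
  d <- data.frame(index = seq_len(nrow(ev)),
    lambda1 = ev[, 1], lambda2 = ev[, 2], lambda3 = ev[, 3],
    t_mag = sqrt(rowSums(field@firstOrder^2)),
    stick = field@saliencies[, 1], plate = field@saliencies[, 2],
    sphere = field@saliencies[, 3])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
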