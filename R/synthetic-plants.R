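## Synthetic sunflower-like plants with exact ground truth. The generator
## emulates what a multi-view-stereo reconstruction of a potted single
## plant looks like after cropping: a roughly vertical stem (slightly
## bowed), whorls of petioles carrying planar elliptical laminae, Gaussian
## noise along the local surface normal, and small reconstruction voids.

withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic plant
#'
#' Defaults describe a mid-season sunflower-like plant: 62 cm tall, 5 mm
#' stem radius, three nodes each bearing two opposite petioles (whorl
#' azimuth rotating 90 degrees per node), broad elliptical laminae a
#' quarter of the plant height long, 2 mm Gaussian surface noise, and a
#' sampling density of 1e4 points/m^2 (a voxel-thinned multi-view-stereo
#' working resolution chosen so that the default k = 30 neighborhoods span
#' ~3 cm: large against the 2 mm noise, small against the laminae).
#'
#' @param height stem height in meters.
#' @param stemRadius stem radius (m).
#' @param stemCurvature maximal lateral bow of the stem axis (m).
#' @param nodeHeights strictly increasing node z positions (m), all below
#'   `height`; may be empty (bare stem).
#' @param petiolesPerNode petioles per node (default 2).
#' @param petioleAzimuthOffset azimuth between successive petioles of one
#'   node, radians. The default golden angle (137.5 degrees) avoids the
#'   degenerate case of exactly opposite petioles, whose union with the
#'   stem is a planar cross rather than a 3-D junction; set to `pi` to
#'   construct that case deliberately.
#' @param petioleLength,petioleRadius petiole geometry (m).
#' @param petioleElevation petiole elevation above horizontal (radians).
#' @param leafMajor,leafMinor lamina semi-axes (m).
#' @param density surface sampling density (points/m^2).
#' @param noiseSigma Gaussian surface-normal noise sd (m).
#' @param voidFraction fraction of points carved out as reconstruction
#'   voids, in `[0, 1)`.
#' @param seed integer seed; fixed seed gives identical clouds.
#' @return a `PlantSpec` list.
#' @export
plantSpec <- function(height = 0.62, stemRadius = 0.005,
                      stemCurvature = 0.01,
                      nodeHeights = c(0.18, 0.30, 0.42),
                      petiolesPerNode = 2L,
                      petioleAzimuthOffset = 137.5 * pi / 180,
                      petioleLength = 0.07,
                      petioleRadius = 0.004,
                      petioleElevation = 10 * pi / 180,
                      leafMajor = 0.25 * height,
                      leafMinor = leafMajor * 2 / 3,
                      density = 1e4, noiseSigma = 0.002,
                      voidFraction = 0.02, seed = 1L) {
  if (height <= 0) stop("height must be > 0")
  if (length(nodeHeights)) {
    if (any(diff(nodeHeights) <= 0)) stop("nodeHeights must be strictly increasing")
    if (any(nodeHeights <= 0) || any(nodeHeights >= height))
      stop("nodeHeights must lie strictly inside (0, height)")
  }
  if (density <= 0) stop("density must be > 0")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (voidFraction < 0 || voidFraction >= 1) stop("voidFraction must be in [0,1)")
  if (petioleLength <= 2 * stemRadius)
    stop("impossible geometry: petiole shorter than stem clearance")
  reach <- if (length(nodeHeights))
    max(nodeHeights) + (petioleLength + 2 * leafMajor) * sin(petioleElevation)
  else 0
  if (reach >= height)
    stop("impossible geometry: leaves would overtop the stem ",
      "(reach ", signif(reach, 3), " m >= height ", height, " m)")
  structure(list(height = height, stemRadius = stemRadius,
    stemCurvature = stemCurvature, nodeHeights = nodeHeights,
    petiolesPerNode = as.integer(petiolesPerNode),
    petioleAzimuthOffset = petioleAzimuthOffset,
    petioleLength = petioleLength, petioleRadius = petioleRadius,
    petioleElevation = petioleElevation, leafMajor = leafMajor,
    leafMinor = leafMinor, density = density, noiseSigma = noiseSigma,
    voidFraction = voidFraction, seed = seed), class = "PlantSpec")
}

stemAxisOffset <- function(z, spec, bendDir) {
  s <- spec$stemCurvature * (z / spec$height)^2
  cbind(s * bendDir[1], s * bendDir[2], 0)
}

#' Generate a labeled synthetic plant cloud
#'
#' Surface-samples the stem (bowed cylinder), petioles (thin cylinders) and
#' laminae (planar ellipses attached at the petiole tips), adds Gaussian
#' noise along the local surface normal, and carves small spherical voids.
#' Deterministic for a fixed `spec$seed`. The stem carries point rings at
#' its exact base and top so the noiseless cloud's vertical extent equals
#' `spec$height` by construction (stem noise is radial, i.e. horizontal).
#'
#' @param spec a [plantSpec()].
#' @return list with `cloud` (metric [PointCloud-class]) and `truth`: a
#'   list with per-point `labels` ("stem"/"leaf"; petioles count as stem),
#'   `nodePositions` (axis points at the node heights), `firstInternode`,
#'   `internodes`, `height`, `width`, `volumeRef` + `volumeVoxel`, `bbox`.
#' @export
generatePlant <- function(spec = plantSpec()) {
  stopifnot(inherits(spec, "PlantSpec"))
  withSeed(spec$seed, {
    bendAz <- stats::runif(1, 0, 2 * pi)
    bendDir <- c(cos(bendAz), sin(bendAz))
    baseAz <- stats::runif(1, 0, 2 * pi)
    pts <- list(); nrm <- list(); lab <- list(); protect <- list()
    organ <- list()

    # stem shell + exact end rings
    nStem <- max(20L, round(spec$density * 2 * pi * spec$stemRadius * spec$height))
    zs <- stats::runif(nStem, 0, spec$height)
    ring <- seq(0, 2 * pi, length.out = 9L)[-9L]
    zs <- c(zs, rep(0, 8L), rep(spec$height, 8L))
    th <- c(stats::runif(nStem, 0, 2 * pi), ring, ring)
    isRing <- c(rep(FALSE, nStem), rep(TRUE, 16L))
    u <- cbind(cos(th), sin(th), 0)
    pts[[1]] <- stemAxisOffset(zs, spec, bendDir) +
      cbind(0, 0, zs) + spec$stemRadius * u
    nrm[[1]] <- u
    lab[[1]] <- rep("stem", length(zs))
    protect[[1]] <- isRing
    organ[[1]] <- rep("stem", length(zs))

    nodePos <- NULL
    k <- 2L
    for (m in seq_along(spec$nodeHeights)) {
      zm <- spec$nodeHeights[m]
      attach0 <- c(stemAxisOffset(zm, spec, bendDir)[1, 1:2], zm)
      nodePos <- rbind(nodePos, attach0)
      for (j in seq_len(spec$petiolesPerNode)) {
        az <- baseAz + (m - 1) * pi / 2 +
          (j - 1) * spec$petioleAzimuthOffset
        el <- spec$petioleElevation
        d <- c(cos(az) * cos(el), sin(az) * cos(el), sin(el))
        e2 <- c(-sin(az), cos(az), 0)               # horizontal, |e2|=1, e2 _|_ d
        e3 <- c(d[2] * e2[3] - d[3] * e2[2],        # d x e2
                d[3] * e2[1] - d[1] * e2[3],
                d[1] * e2[2] - d[2] * e2[1])
        # petiole cylinder
        nPet <- max(5L, round(spec$density * 2 * pi * spec$petioleRadius *
          spec$petioleLength))
        s <- stats::runif(nPet, 0, spec$petioleLength)
        ph <- stats::runif(nPet, 0, 2 * pi)
        rad <- outer(cos(ph), e2) + outer(sin(ph), e3)
        pts[[k]] <- matrix(attach0, nPet, 3, byrow = TRUE) + outer(s, d) +
          spec$petioleRadius * rad
        nrm[[k]] <- rad
        lab[[k]] <- rep("stem", nPet)
        protect[[k]] <- rep(FALSE, nPet)
        organ[[k]] <- rep(sprintf("petiole:%d.%d", m, j), nPet)
        k <- k + 1L

        # lamina: planar ellipse tangent to the petiole tip
        tip <- attach0 + spec$petioleLength * d
        centre <- tip + spec$leafMajor * d
        nLeaf <- max(10L, round(spec$density * pi * spec$leafMajor *
          spec$leafMinor))
        rr <- sqrt(stats::runif(nLeaf))
        phL <- stats::runif(nLeaf, 0, 2 * pi)
        pts[[k]] <- matrix(centre, nLeaf, 3, byrow = TRUE) +
          outer(spec$leafMajor * rr * cos(phL), d) +
          outer(spec$leafMinor * rr * sin(phL), e2)
        nrm[[k]] <- matrix(e3, nLeaf, 3, byrow = TRUE)
        lab[[k]] <- rep("leaf", nLeaf)
        protect[[k]] <- rep(FALSE, nLeaf)
        organ[[k]] <- rep(sprintf("leaf:%d.%d", m, j), nLeaf)
        k <- k + 1L
      }
    }

    p <- do.call(rbind, pts)
    normal <- do.call(rbind, nrm)
    labels <- unlist(lab)
    organs <- unlist(organ)
    protected <- unlist(protect)
    if (spec$noiseSigma > 0)
      p <- p + normal * stats::rnorm(nrow(p), 0, spec$noiseSigma)

    # reconstruction voids: spherical bites, never at the protected stem ends
    if (spec$voidFraction > 0) {
      target <- floor(spec$voidFraction * nrow(p))
      removed <- rep(FALSE, nrow(p))
      guard <- 0L
      while (sum(removed) < target && guard < 200L) {
        guard <- guard + 1L
        cand <- which(!removed & !protected)
        if (!length(cand)) break
        ctr <- p[sample(cand, 1L), ]
        d2 <- rowSums(sweep(p, 2, ctr)^2)
        removed <- removed | (d2 < 0.01^2 & !protected)
      }
      keep <- !removed
      p <- p[keep, , drop = FALSE]
      labels <- labels[keep]
      organs <- organs[keep]
    }

    cloud <- pointCloud(p, frame = "metric")
    noiseFree <- spec$noiseSigma == 0 && spec$voidFraction == 0
    axisPts <- rbind(c(0, 0, 0),
      if (length(spec$nodeHeights)) nodePos else NULL)
    segs <- if (nrow(axisPts) > 1)
      as.numeric(sqrt(rowSums(diff(axisPts)^2))) else numeric(0)
    grid <- voxelize(cloud, 0.01)
    truth <- list(labels = labels, organs = organs,
      nodePositions = if (length(spec$nodeHeights)) nodePos else
        matrix(numeric(0), 0, 3),
      firstInternode = if (length(segs)) segs[1] else NA_real_,
      internodes = segs,
      height = spec$height,
      width = plantWidth(cloud),
      volumeRef = plantVolume(grid),
      volumeVoxel = 0.01,
      bbox = apply(p, 2, range),
      noiseFree = noiseFree)
    list(cloud = cloud, truth = truth)
  })
}

#' Generate a full scene: plant + pot + soil clutter
#'
#' The plant is identical to `generatePlant(spec)`; a pot wall (cylinder)
#' and soil disc are appended below the soil line (z < 0). The returned
#' truth records the plant point indices and a `cropSpec` that recovers
#' exactly those points.
#'
#' @param spec a [plantSpec()].
#' @param potRadius,potDepth,soilZ clutter geometry (m); clutter occupies
#'   z in `[-potDepth, soilZ]` with `soilZ < 0`.
#' @return list with `cloud`, `truth` (plant truth plus `plantIndex` and
#'   `cropSpec`).
#' @export
generateScene <- function(spec = plantSpec(), potRadius = 0.12,
                          potDepth = 0.17, soilZ = -0.02) {
  stopifnot(soilZ < 0, potDepth > -soilZ)
  plant <- generatePlant(spec)
  clutter <- withSeed(spec$seed * 2L + 1L, {
    nWall <- max(50L, round(spec$density * 2 * pi * potRadius *
      (potDepth + soilZ)))
    zw <- stats::runif(nWall, -potDepth, soilZ)
    tw <- stats::runif(nWall, 0, 2 * pi)
    wall <- cbind(potRadius * cos(tw), potRadius * sin(tw), zw)
    nSoil <- max(50L, round(spec$density * pi * potRadius^2))
    rs <- potRadius * sqrt(stats::runif(nSoil))
    ts <- stats::runif(nSoil, 0, 2 * pi)
    soil <- cbind(rs * cos(ts), rs * sin(ts), soilZ)
    out <- rbind(wall, soil)
    if (spec$noiseSigma > 0) {
      wn <- cbind(cos(tw), sin(tw), 0)
      sn <- matrix(c(0, 0, 1), nSoil, 3, byrow = TRUE)
      out <- out + rbind(wn, sn) * stats::rnorm(nrow(out), 0, spec$noiseSigma)
    }
    out
  })
  pPlant <- cloudPoints(plant$cloud)
  all <- pointCloud(rbind(pPlant, clutter), frame = "metric")
  eps <- 1e-9
  bb <- plant$truth$bbox
  truth <- plant$truth
  truth$plantIndex <- seq_len(nrow(pPlant))
  truth$cropSpec <- cropSpec(
    xlim = c(bb[1, 1] - eps, bb[2, 1] + eps),
    ylim = c(bb[1, 2] - eps, bb[2, 2] + eps),
    zlim = c(bb[1, 3] - eps, bb[2, 3] + eps),
    soilZ = soilZ / 2)
  list(cloud = all, truth = truth)
}

#' Specs for the default synthetic validation suite
#'
#' `n` plants with first-internode lengths evenly spanning 10-30 cm, three
#' nodes 12 cm apart, two opposite petioles per node, and 2 mm surface
#' noise — the conditions used by the package's accuracy and RMSE
#' validation.
#'
#' @param n number of plants (default 20).
#' @param seeds integer seeds, length `n` (default `1:n`).
#' @param noiseSigma surface noise sd (default 2 mm).
#' @return list of [plantSpec()]s.
#' @export
plantSuiteSpecs <- function(n = 20L, seeds = seq_len(n), noiseSigma = 0.002) {
  stopifnot(length(seeds) == n)
  fi <- seq(0.10, 0.30, length.out = n)
  lapply(seq_len(n), function(i) {
    nodes <- fi[i] + c(0, 0.12, 0.24)
    plantSpec(height = nodes[3] + 0.20, nodeHeights = nodes,
      noiseSigma = noiseSigma, seed = seeds[i])
  })
}

## printed session means the cohort trajectories interpolate through
## (height & internode cm, volume m^3, width cm; control/infected)
cohortCalibration <- function() {
  data.frame(
    gdd = c(550, 750, 940, 1120),
    height_c = c(15, 48, 81, 112), height_i = c(15, 41, 62, 82),
    internode_c = c(5, 23, 27, 31), internode_i = c(5, 13, 14, 15),
    volume_c = c(0.01, 0.05, 0.20, 0.45),
    volume_i = c(0.01, 0.045, 0.12, 0.20),
    width_c = c(20, 40, 55, 66), width_i = c(20, 40, 61, 66))
}

cohortSpecAt <- function(heightCm, internodeCm, density, seed) {
  h <- heightCm / 100; fi <- internodeCm / 100
  gap <- max(0.02, (0.75 * h - fi) / 2)
  nodes <- pmin(fi + c(0, gap, 2 * gap), 0.9 * h)
  if (any(diff(nodes) <= 0)) nodes <- fi * c(1, 1.3, 1.6)
  a <- max(0.015, 0.10 * h)
  plantSpec(height = h, stemRadius = 0.003 + 0.004 * h,
    stemCurvature = 0.02 * h, nodeHeights = nodes,
    petioleLength = max(0.025, 0.08 * h), petioleElevation = 25 * pi / 180,
    leafMajor = a, leafMinor = 2 / 3 * a, density = density,
    noiseSigma = 0.002, voidFraction = 0.02, seed = seed)
}

#' Generate a control/infected cohort across imaging sessions
#'
#' Growth trajectories linearly interpolate (in GDD) through per-session
#' calibration means for height and first-internode length of control and
#' infected groups; between-plant variation is a configurable coefficient
#' of variation. This is a calibration device for generating test cohorts,
#' not a growth model.
#'
#' @param nPerGroup plants per group (>= 2, default 5).
#' @param sessions GDD values of the imaging sessions.
#' @param cv between-plant coefficient of variation (default 0.05).
#' @param density sampling density for the cohort clouds (default 1.5e4,
#'   lighter than single-plant studies).
#' @param seed integer master seed.
#' @param keepClouds set FALSE to skip cloud realization (specs + truth only).
#' @return data.frame with one row per plant x session (group, plant,
#'   gdd, seed, target/truth height and internode in cm) and, when
#'   `keepClouds`, a list-column `cloud` of [PointCloud-class] objects.
#' @export
generateCohort <- function(nPerGroup = 5L, sessions = c(550, 750, 940, 1120),
                           cv = 0.05, density = 1.5e4, seed = 1L,
                           keepClouds = TRUE) {
  stopifnot(nPerGroup >= 2L, length(sessions) >= 1L)
  cal <- cohortCalibration()
  interp <- function(col) stats::approx(cal$gdd, cal[[col]], xout = sessions,
    rule = 2)$y
  targets <- expand.grid(group = c("control", "infected"),
    session = seq_along(sessions), plant = seq_len(nPerGroup),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  targets$gdd <- sessions[targets$session]
  hC <- interp("height_c"); hI <- interp("height_i")
  fC <- interp("internode_c"); fI <- interp("internode_i")
  # one multiplicative size factor per plant, shared across sessions
  factors <- withSeed(seed, {
    f <- stats::rnorm(2L * nPerGroup, 1, cv)
    pmax(f, 0.5)
  })
  names(factors) <- paste(rep(c("control", "infected"), each = nPerGroup),
    seq_len(nPerGroup), sep = "_")
  rows <- lapply(seq_len(nrow(targets)), function(r) {
    g <- targets$group[r]; s <- targets$session[r]; pl <- targets$plant[r]
    f <- factors[paste(g, pl, sep = "_")]
    hTarget <- f * (if (g == "control") hC[s] else hI[s])
    fiTarget <- f * (if (g == "control") fC[s] else fI[s])
    plantSeed <- (seed * 10000L + (match(g, c("control", "infected")) - 1L) *
      1000L + s * 100L + pl) %% .Machine$integer.max
    spec <- cohortSpecAt(hTarget, fiTarget, density, plantSeed)
    list(group = g, plant = pl, gdd = targets$gdd[r], seed = plantSeed,
      height_cm = 100 * spec$height,
      first_internode_cm = 100 * spec$nodeHeights[1], spec = spec)
  })
  out <- data.frame(
    group = vapply(rows, `[[`, "", "group"),
    plant = vapply(rows, `[[`, 0L, "plant"),
    gdd = vapply(rows, `[[`, 0, "gdd"),
    seed = vapply(rows, `[[`, 0, "seed"),
    height_cm = vapply(rows, `[[`, 0, "height_cm"),
    first_internode_cm = vapply(rows, `[[`, 0, "first_internode_cm"),
    stringsAsFactors = FALSE)
  out$spec <- lapply(rows, `[[`, "spec")
  if (keepClouds)
    out$cloud <- lapply(out$spec, function(s) generatePlant(s)$cloud)
  out
}

#' Three-parameter log-logistic response
#'
#' y = a / (1 + (x/x0)^b): upper asymptote `a`, inflection at `x0` (where
#' y = a/2), shape `b` (negative for an increasing sigmoid).
#'
#' @param x thermal time (GDD).
#' @param a,x0,b parameters.
#' @return numeric vector.
#' @export
logLogistic <- function(x, a, x0, b) a / (1 + (x / x0)^b)

#' Generate a synthetic attachment-dynamics series
#'
#' @param params named or positional numeric: (a, x0, b).
#' @param gdd strictly increasing GDD evaluation points.
#' @param noiseSd additive Gaussian noise sd (attachments per tube).
#' @param seed integer seed or NULL.
#' @return data.frame with `gdd`, `attachments` (truncated at 0).
#' @export
generateAttachments <- function(params, gdd, noiseSd = 0, seed = NULL) {
  stopifnot(length(gdd) >= 1L, length(params) == 3L)
  if (any(diff(gdd) <= 0)) stop("gdd must be strictly increasing")
  y <- logLogistic(gdd, params[[1]], params[[2]], params[[3]])
  if (noiseSd > 0)
    y <- withSeed(seed, y + stats::rnorm(length(gdd), 0, noiseSd))
  data.frame(gdd = gdd, attachments = pmax(y, 0))
}
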