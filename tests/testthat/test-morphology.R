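test_that("plant height is the z extent", {
  p <- pointCloud(cbind(runif(50), runif(50), runif(50, 0, 1.12)),
    frame = "metric")
  expect_equal(plantHeight(p), diff(range(cloudPoints(p)[, 3])))
  expect_equal(plantHeight(pointCloud(matrix(c(1, 2, 3), 1))), 0)
})

test_that("plant width equals the brute-force planar diameter", {
  twoPts <- pointCloud(rbind(c(0, 0, 0), c(3, 4, 7)), frame = "metric")
  expect_equal(plantWidth(twoPts), 5)
  vline <- pointCloud(cbind(0.3, -0.1, seq(0, 1, 0.1)), frame = "metric")
  expect_equal(plantWidth(vline), 0)
  set.seed(61)
  p <- matrix(runif(1500), ncol = 3)
  expect_equal(plantWidth(pointCloud(p, frame = "metric")),
    bruteWidth(p[, 1:2]), tolerance = 1e-12)
})

# cell-center lattice anchored at the origin so offsets stay mid-cell
# (a lattice whose min corner coincides with a cell boundary would sit on
# the floor-division knife edge)
cubeLattice <- function() {
  ax <- seq(0.005, 0.095, 0.01)
  rbind(c(0, 0, 0), as.matrix(expand.grid(x = ax, y = ax, z = ax)))
}

test_that("voxelization maps points by floor division", {
  # a full 10x10x10 cm cube at 1 cm resolution (anchor shares cell 1)
  grid <- voxelize(pointCloud(cubeLattice(), frame = "metric"), 0.01)
  expect_equal(nOccupied(grid), 1000L)
  expect_equal(sum(grid@counts), 1001L)
  expect_equal(nOccupied(voxelize(pointCloud(matrix(1:3, 1),
    frame = "metric"), 0.01)), 1L)
  set.seed(62)
  p <- matrix(runif(600, 0, 0.3), ncol = 3)
  grid <- voxelize(pointCloud(p, frame = "metric"), 0.017)
  keys <- paste(grid@indices[, 1], grid@indices[, 2], grid@indices[, 3])
  expect_setequal(keys, bruteVoxelKeys(p, 0.017))
  expect_error(voxelize(pointCloud(p, frame = "metric"), 0), "> 0")
})

# clusters of collinear voxel runs with controlled component sizes,
# separated by > 2 voxels so they never merge; a tiny increasing jitter
# keeps every point strictly inside its cell
componentsCloud <- function(sizes, size = 0.01) {
  pts <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    cbind(size * (seq_len(n) - 0.5) + seq_len(n) * 1e-7,
      0.005 + 0.1 * i, 0.005)
  }))
  pointCloud(pts, frame = "metric")
}

test_that("the five-cell noise filter drops small components only", {
  grid <- voxelize(componentsCloud(c(3, 4, 5, 6)), 0.01)
  expect_equal(sort(tabulate(voxelComponents(grid))), c(3L, 4L, 5L, 6L))
  filt <- filterVoxelNoise(grid, minCells = 5L)
  sizes <- sort(tabulate(voxelComponents(filt)))
  expect_equal(sizes, c(5L, 6L))
  expect_equal(min(sizes), 5L)
  # idempotent
  expect_equal(filterVoxelNoise(filt, 5L)@indices, filt@indices)
  # a single large component is untouched
  big <- voxelize(componentsCloud(100), 0.01)
  expect_equal(nOccupied(filterVoxelNoise(big)), 100L)
  # everything below threshold leaves an empty grid with a warning
  ones <- voxelize(componentsCloud(c(1, 1, 1)), 0.01)
  expect_warning(empty <- filterVoxelNoise(ones), "empty")
  expect_equal(nOccupied(empty), 0L)
})

test_that("volume is occupied count times cell volume", {
  grid <- voxelize(pointCloud(cubeLattice(), frame = "metric"), 0.01)
  expect_equal(plantVolume(grid), 1e-3)
  ones <- voxelize(componentsCloud(c(1, 1, 1)), 0.01)
  suppressWarnings(empty <- filterVoxelNoise(ones))
  expect_warning(v <- plantVolume(empty), "empty")
  expect_equal(v, 0)
})

test_that("an injected sub-threshold noise blob does not change volume", {
  g <- generatePlant(plantSpec(seed = 63))
  grid0 <- filterVoxelNoise(voxelize(g$cloud, 0.01))
  v0 <- plantVolume(grid0)
  # 4 points in 4 voxels, 30 cm away from the plant
  blob <- rbind(c(-0.3, -0.3, 0.1), c(-0.29, -0.3, 0.1),
    c(-0.28, -0.3, 0.1), c(-0.27, -0.3, 0.1))
  noisy <- pointCloud(rbind(cloudPoints(g$cloud), blob), frame = "metric")
  grid1 <- filterVoxelNoise(voxelize(noisy, 0.01))
  expect_equal(plantVolume(grid1), v0)
})

test_that("volume grows monotonically with added points before filtering", {
  set.seed(64)
  anchor <- c(0, 0, 0)   # shared min corner keeps the grid fixed
  p <- rbind(anchor, matrix(runif(300, 0.01, 0.2), ncol = 3))
  v1 <- plantVolume(voxelize(pointCloud(p[1:51, ], frame = "metric"),
    0.02))
  v2 <- plantVolume(voxelize(pointCloud(p[1:91, ], frame = "metric"),
    0.02))
  expect_gte(v2, v1)
})

test_that("morphology is invariant to translation and z-rotation", {
  g <- generatePlant(plantSpec(seed = 65))
  h0 <- plantHeight(g$cloud); w0 <- plantWidth(g$cloud)
  v0 <- plantVolume(filterVoxelNoise(voxelize(g$cloud, 0.01)))
  moved <- pointCloud(sweep(cloudPoints(g$cloud), 2, c(4, 5, -2), "+"),
    frame = "metric")
  expect_equal(plantHeight(moved), h0, tolerance = 1e-12)
  expect_equal(plantWidth(moved), w0, tolerance = 1e-12)
  expect_equal(plantVolume(filterVoxelNoise(voxelize(moved, 0.01))), v0,
    tolerance = 1e-12)
  rot <- pointCloud(cloudPoints(g$cloud) %*% t(rotZ(0.8)),
    frame = "metric")
  expect_equal(plantHeight(rot), h0, tolerance = 1e-9)
  # voxel volume under rotation moves by at most a few boundary cells
  vr <- plantVolume(filterVoxelNoise(voxelize(rot, 0.01)))
  expect_lt(abs(vr - v0) / v0, 0.1)
})
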