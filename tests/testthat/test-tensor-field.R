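test_that("single-neighborhood tensors match the defining sums", {
  xi <- c(1, 2, 3)
  # symmetric pair cancels the first-order tensor
  expect_equal(firstOrderTensor(xi, rbind(xi + c(0.5, 0, 0),
    xi - c(0.5, 0, 0))), c(0, 0, 0))
  # sign convention: t = x_i - x_j
  expect_equal(firstOrderTensor(xi, rbind(xi + c(1, 0, 0))), c(-1, 0, 0))
  # asymmetric set against term-by-term summation
  set.seed(4)
  nb <- matrix(rnorm(15), ncol = 3) + rep(xi, each = 5)
  expect_equal(firstOrderTensor(xi, nb), bruteFirstOrder(xi, nb))

  expect_equal(secondOrderTensor(c(0, 0, 0),
    rbind(c(1, 0, 0), c(-1, 0, 0))), diag(c(2, 0, 0)))
  expect_equal(secondOrderTensor(c(0, 0, 0),
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))),
    diag(c(2, 2, 0)))
  nb8 <- matrix(rnorm(24), ncol = 3)
  expect_equal(secondOrderTensor(c(0, 0, 0), nb8),
    bruteSecondOrder(c(0, 0, 0), nb8))
})

test_that("knn neighborhoods equal the exhaustive-sort oracle", {
  # collinear points: nearest neighbors are the adjacent line positions
  line <- pointCloud(cbind(0:5, 0, 0), frame = "metric")
  nb <- findNeighbors(line, neighborhoodSpec(k = 3))
  expect_identical(sort(nb[[1]]), c(2L, 3L, 4L))
  expect_identical(sort(nb[[3]]), c(1L, 2L, 4L))
  expect_identical(sort(nb[[6]]), c(3L, 4L, 5L))
  # 200 random points, k = 10
  set.seed(5)
  p <- matrix(runif(600), ncol = 3)
  cloud <- pointCloud(p, frame = "metric")
  nb <- findNeighbors(cloud, neighborhoodSpec(k = 10))
  oracle <- bruteKnn(p, 10)
  for (i in seq_len(200)) expect_setequal(nb[[i]], oracle[i, ])
  # cloud smaller than k+1 errors
  expect_error(findNeighbors(line, neighborhoodSpec(k = 6)), "k\\+1")
})

test_that("radius mode flags isolated points degenerate", {
  p <- pointCloud(cbind(seq(0, 1, by = 0.1), 0, 0), frame = "metric")
  nb <- findNeighbors(p, neighborhoodSpec(r = 0.01))
  expect_true(all(attr(nb, "degenerate")))
  expect_true(all(lengths(nb) == 0))
  nb2 <- findNeighbors(p, neighborhoodSpec(r = 0.35, minNeighbors = 3))
  expect_false(any(attr(nb2, "degenerate")))
  # radius list agrees with manual distance threshold
  expect_setequal(nb2[[1]], which(abs(seq(0, 1, 0.1) - 0) <= 0.35)[-1])
})

test_that("spectral decomposition reconstructs and respects isometry", {
  s <- spectralDecompose(diag(c(2, 2, 0)))
  expect_equal(s$values, c(2, 2, 0))
  set.seed(6)
  for (rep in 1:10) {
    A <- matrix(rnorm(9), 3, 3)
    T <- A %*% t(A)
    s <- spectralDecompose(T)
    expect_true(all(diff(s$values) <= 1e-12))
    expect_true(all(s$values >= 0))
    recon <- s$vectors %*% diag(s$values) %*% t(s$vectors)
    expect_lt(max(abs(recon - T)), 1e-8 * max(1, norm(T, "F")))
    expect_equal(crossprod(s$vectors), diag(3), tolerance = 1e-8)
    # rotation leaves eigenvalues unchanged
    R <- randomRotation()
    s2 <- spectralDecompose(R %*% T %*% t(R))
    expect_equal(s2$values, s$values, tolerance = 1e-8)
  }
  expect_error(spectralDecompose(matrix(c(1, NA, rep(0, 7)), 3, 3)),
    "finite")
})

test_that("saliency decomposition splits stick/plate/sphere and sums to T", {
  s <- saliencyDecompose(c(5, 0, 0), diag(3))
  expect_equal(c(s$stick, s$plate, s$sphere), c(5, 0, 0))
  s <- saliencyDecompose(c(3, 3, 0), diag(3))
  expect_equal(c(s$stick, s$plate, s$sphere), c(0, 3, 0))
  set.seed(7)
  A <- matrix(rnorm(9), 3, 3); T <- A %*% t(A)
  e <- spectralDecompose(T)
  s <- saliencyDecompose(e$values, e$vectors)
  expect_equal(s$stickTensor + s$plateTensor + s$sphereTensor, T,
    tolerance = 1e-8)
  expect_error(saliencyDecompose(c(1, 2, 3), diag(3)), "descending")
})

test_that("tensor field matches per-point brute-force accumulation", {
  set.seed(8)
  p <- matrix(runif(150, 0, 0.2), ncol = 3)
  cloud <- pointCloud(p, frame = "metric")
  nb <- findNeighbors(cloud, neighborhoodSpec(k = 8, minNeighbors = 3))
  field <- tensorField(cloud, nb)
  for (i in c(1, 17, 50)) {
    nbp <- p[nb[[i]], , drop = FALSE]
    expect_equal(firstOrder(field)[i, ], bruteFirstOrder(p[i, ], nbp),
      tolerance = 1e-12)
    T <- bruteSecondOrder(p[i, ], nbp)
    expect_equal(field@secondOrder[i, ],
      c(T[1, 1], T[1, 2], T[1, 3], T[2, 2], T[2, 3], T[3, 3]),
      tolerance = 1e-12)
    expect_equal(eigenvalues(field)[i, ], spectralDecompose(T)$values,
      tolerance = 1e-10)
  }
  # saliencies are eigenvalue differences
  ev <- eigenvalues(field)
  expect_equal(saliencies(field),
    cbind(ev[, 1] - ev[, 2], ev[, 2] - ev[, 3], ev[, 3]),
    ignore_attr = TRUE)
})

test_that("tensor field is translation invariant and rotation equivariant", {
  set.seed(9)
  p <- matrix(runif(450, 0, 0.3), ncol = 3)
  cloud <- pointCloud(p, frame = "metric")
  spec <- neighborhoodSpec(k = 12)
  f0 <- tensorField(cloud, spec = spec)
  shifted <- pointCloud(sweep(p, 2, c(5, -3, 11), "+"), frame = "metric")
  f1 <- tensorField(shifted, spec = spec)
  expect_equal(f1@secondOrder, f0@secondOrder, tolerance = 1e-9)
  expect_equal(sqrt(rowSums(firstOrder(f1)^2)),
    sqrt(rowSums(firstOrder(f0)^2)), tolerance = 1e-9)
  R <- randomRotation()
  rotated <- pointCloud(p %*% t(R), frame = "metric")
  f2 <- tensorField(rotated, spec = spec)
  expect_equal(eigenvalues(f2), eigenvalues(f0), tolerance = 1e-8)
  # eigenvectors rotate (up to the sign convention)
  i <- 25
  v0 <- matrix(eigenvectors(f0)[i, ], 3, 3)
  v2 <- matrix(eigenvectors(f2)[i, ], 3, 3)
  expect_equal(abs(colSums((R %*% v0) * v2)), c(1, 1, 1), tolerance = 1e-6)
})

test_that("degenerate collinear and coplanar neighborhoods have null eigenvalues", {
  zline <- pointCloud(cbind(0, 0, seq(0, 1, length.out = 50)),
    frame = "metric")
  f <- tensorField(zline, spec = neighborhoodSpec(k = 6, minNeighbors = 3))
  ev <- eigenvalues(f)
  expect_true(all(ev[, 2] <= 1e-10 * ev[, 1] + 1e-15))
  expect_true(all(ev[, 3] <= 1e-10 * ev[, 1] + 1e-15))
  set.seed(10)
  plane <- pointCloud(cbind(runif(300), runif(300), 0.7), frame = "metric")
  fp <- tensorField(plane, spec = neighborhoodSpec(k = 10))
  evp <- eigenvalues(fp)
  expect_true(all(evp[, 3] <= 1e-10 * evp[, 1] + 1e-15))
})

test_that("planar patches have dominant plate saliency and small lambda3", {
  set.seed(11)
  # density chosen so 30-point neighborhoods span ~3 cm, well above the
  # 2 mm noise scale (the regime the classifier thresholds assume)
  d <- discCloud(1250, R = 0.2, sigma = 0.002)
  f <- tensorField(d$cloud, spec = neighborhoodSpec(k = 30))
  rn <- sqrt(30 / (pi * 1250 / (pi * 0.2^2)))
  interior <- d$rr < 0.2 - 1.5 * rn
  ev <- eigenvalues(f)
  expect_gt(mean(ev[interior, 3] <= 0.1 * ev[interior, 1]), 0.95)
  # plate dominance: a wider neighborhood suppresses the sampling spread
  # of the two in-plane eigenvalues
  f2 <- tensorField(d$cloud, spec = neighborhoodSpec(k = 100))
  sal <- saliencies(f2)
  expect_gt(mean(sal[interior, 2] > sal[interior, 1] &
    sal[interior, 2] > sal[interior, 3]), 0.95)
})

test_that("feature dump writes one row per point", {
  set.seed(12)
  cloud <- pointCloud(matrix(runif(90), ncol = 3), frame = "metric")
  f <- tensorField(cloud, spec = neighborhoodSpec(k = 5, minNeighbors = 3))
  path <- tempfile(fileext = ".csv")
  writeFeatureDump(f, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 30)
  expect_named(d, c("index", "lambda1", "lambda2", "lambda3", "t_mag",
    "stick", "plate", "sphere"))
})
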