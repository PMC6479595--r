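test_that("generation is deterministic under a fixed seed", {
  a <- generatePlant(plantSpec(seed = 71))
  b <- generatePlant(plantSpec(seed = 71))
  expect_identical(cloudPoints(a$cloud), cloudPoints(b$cloud))
  expect_identical(a$truth$labels, b$truth$labels)
  c <- generatePlant(plantSpec(seed = 72))
  expect_false(isTRUE(all.equal(cloudPoints(a$cloud), cloudPoints(c$cloud))))
  s1 <- generateScene(plantSpec(seed = 71))
  s2 <- generateScene(plantSpec(seed = 71))
  expect_identical(cloudPoints(s1$cloud), cloudPoints(s2$cloud))
})

test_that("a zero-node spec yields a pure stem cloud", {
  g <- generatePlant(plantSpec(nodeHeights = numeric(0), seed = 73))
  expect_true(all(g$truth$labels == "stem"))
  expect_equal(nrow(g$truth$nodePositions), 0L)
})

test_that("noise-free plant height equals the spec height by construction", {
  sp <- plantSpec(noiseSigma = 0, voidFraction = 0, seed = 74)
  g <- generatePlant(sp)
  expect_equal(plantHeight(g$cloud), sp$height, tolerance = 1e-9)
})

test_that("ground-truth internodes mirror the node spacing", {
  sp <- plantSpec(stemCurvature = 0, nodeHeights = c(0.15, 0.27, 0.40),
    seed = 75)
  g <- generatePlant(sp)
  expect_equal(g$truth$firstInternode, 0.15)
  expect_equal(g$truth$internodes, c(0.15, 0.12, 0.13))
})

test_that("scene equals plant plus clutter, with recorded plant indices", {
  sp <- plantSpec(seed = 76)
  plant <- generatePlant(sp)
  sc <- generateScene(sp)
  np <- nPoints(plant$cloud)
  expect_identical(cloudPoints(sc$cloud)[seq_len(np), ],
    cloudPoints(plant$cloud))
  expect_identical(sc$truth$plantIndex, seq_len(np))
  expect_gt(nPoints(sc$cloud), np)
  clutterZ <- cloudPoints(sc$cloud)[-seq_len(np), 3]
  expect_true(all(clutterZ < 0))
})

test_that("impossible geometries are rejected", {
  expect_error(plantSpec(nodeHeights = c(0.3, 0.2)), "increasing")
  expect_error(plantSpec(nodeHeights = 0.7, height = 0.6), "inside")
  expect_error(plantSpec(petioleLength = 0.001), "impossible geometry")
  expect_error(plantSpec(height = 0.3, nodeHeights = 0.28), "overtop")
  expect_error(plantSpec(voidFraction = 1), "voidFraction")
})

test_that("leaf fraction grows with lamina area", {
  small <- generatePlant(plantSpec(leafMajor = 0.08, leafMinor = 0.05,
    seed = 77))
  large <- generatePlant(plantSpec(leafMajor = 0.16, leafMinor = 0.10,
    seed = 77))
  expect_gt(mean(large$truth$labels == "leaf"),
    mean(small$truth$labels == "leaf"))
})

test_that("cohorts have the right layout, reproducibility and calibration", {
  co <- generateCohort(nPerGroup = 2L, sessions = c(750, 1120), cv = 0.03,
    density = 5000, seed = 81)
  expect_equal(nrow(co), 2L * 2L * 2L)
  expect_setequal(unique(co$group), c("control", "infected"))
  co2 <- generateCohort(nPerGroup = 2L, sessions = c(750, 1120), cv = 0.03,
    density = 5000, seed = 81)
  expect_identical(co$height_cm, co2$height_cm)
  expect_identical(cloudPoints(co$cloud[[1]]), cloudPoints(co2$cloud[[1]]))
  # zero CV puts every plant exactly on the group trajectory
  co0 <- generateCohort(nPerGroup = 2L, sessions = c(750, 1120), cv = 0,
    density = 5000, seed = 82, keepClouds = FALSE)
  ctrl <- co0[co0$group == "control" & co0$gdd == 1120, ]
  expect_equal(length(unique(ctrl$height_cm)), 1L)
  expect_equal(ctrl$height_cm[1], 112, tolerance = 1e-9)
  inf <- co0[co0$group == "infected" & co0$gdd == 1120, ]
  expect_equal(inf$height_cm[1], 82, tolerance = 1e-9)
  # final-session truth means stay within the configured CV of the targets
  co3 <- generateCohort(nPerGroup = 5L, sessions = 1120, cv = 0.05,
    density = 5000, seed = 83, keepClouds = FALSE)
  m <- tapply(co3$height_cm, co3$group, mean)
  expect_lt(abs(m["control"] - 112) / 112, 0.05)
  expect_lt(abs(m["infected"] - 82) / 82, 0.05)
})

test_that("attachment series follow the log-logistic form", {
  gdd <- seq(500, 1200, by = 50)
  atInfl <- generateAttachments(c(6.62, 1000.18, -6.37),
    c(500, 1000.18, 1500))
  expect_equal(atInfl$attachments[2], 6.62 / 2, tolerance = 1e-9)
  far <- generateAttachments(c(6.62, 1000.18, -6.37), c(1e5, 2e5))
  expect_equal(far$attachments, c(6.62, 6.62), tolerance = 1e-3)
  n1 <- generateAttachments(c(6.62, 1000.18, -6.37), gdd, noiseSd = 0.3,
    seed = 84)
  n2 <- generateAttachments(c(6.62, 1000.18, -6.37), gdd, noiseSd = 0.3,
    seed = 84)
  expect_identical(n1, n2)
  expect_true(all(n1$attachments >= 0))
  big <- generateAttachments(c(0.1, 800, -4), gdd, noiseSd = 2, seed = 85)
  expect_true(all(big$attachments >= 0))   # truncation at zero
})

test_that("the default validation suite spans 10-30 cm first internodes", {
  specs <- plantSuiteSpecs()
  fi <- vapply(specs, function(s) s$nodeHeights[1], 0)
  expect_equal(range(fi), c(0.10, 0.30))
  expect_length(specs, 20L)
  expect_true(all(vapply(specs, function(s) s$noiseSigma, 0) == 0.002))
})
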