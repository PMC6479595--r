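test_that("GDD accumulation matches hand-computed daily means", {
  h48 <- seq(as.POSIXct("2020-04-01 00:00", tz = "UTC"), by = "hour",
    length.out = 48)
  g <- gddFromTemperature(h48, rep(25, 48), tBase = 5)
  expect_equal(nrow(g), 2L)
  expect_equal(g$cumGdd, c(20, 40))
  # everything below base contributes nothing
  cold <- gddFromTemperature(h48, rep(2, 48), tBase = 5)
  expect_equal(cold$cumGdd, c(0, 0))
  # mixed series against a manual oracle
  set.seed(91)
  h <- seq(as.POSIXct("2020-04-01 00:00", tz = "UTC"), by = "hour",
    length.out = 24 * 7)
  temps <- runif(length(h), -2, 30)
  g <- gddFromTemperature(h, temps, tBase = 5)
  manual <- cumsum(pmax(0, vapply(split(temps,
    rep(1:7, each = 24)), mean, 0) - 5))
  expect_equal(g$cumGdd, unname(manual))
  expect_true(all(diff(g$cumGdd) >= 0))
  expect_false(any(g$incomplete))
  # additivity over date ranges
  g1 <- gddFromTemperature(h[1:72], temps[1:72], 5)
  g2 <- gddFromTemperature(h[73:168], temps[73:168], 5)
  expect_equal(g$cumGdd[7], g1$cumGdd[3] + g2$cumGdd[4])
  expect_error(gddFromTemperature(numeric(0), numeric(0)), "empty")
})

test_that("partial days are flagged incomplete", {
  h <- seq(as.POSIXct("2020-04-01 00:00", tz = "UTC"), by = "hour",
    length.out = 30)
  g <- gddFromTemperature(h, rep(20, 30))
  expect_identical(g$incomplete, c(FALSE, TRUE))
})

test_that("log-logistic fitting recovers generating parameters exactly", {
  gdd <- seq(500, 1200, by = 50)
  set.seed(92)
  for (rep in 1:10) {
    a <- runif(1, 2, 12)
    x0 <- runif(1, 700, 1000)
    b <- runif(1, -10, -3)
    y <- generateAttachments(c(a, x0, b), gdd)
    fit <- fitLogLogistic(y)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$coefficients - c(a, x0, b)) / abs(c(a, x0, b))),
      1e-3)
    expect_gt(fit$r.squared, 0.999999)
    expect_lt(fit$rmse, 1e-4)
  }
})

test_that("degenerate and undersized series are handled", {
  gdd <- seq(500, 1200, by = 100)
  const <- data.frame(gdd = gdd, attachments = rep(3, length(gdd)))
  fit <- fitLogLogistic(const)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_equal(unname(fit$coefficients["a"]), 3)
  expect_error(fitLogLogistic(data.frame(gdd = c(1, 2, 3),
    attachments = c(1, 2, 3))), "at least 4")
})

test_that("group comparison agrees with the textbook ANOVA F ratio", {
  set.seed(93)
  v <- c(rnorm(5, 10), rnorm(5, 12))
  g <- rep(c("control", "infected"), each = 5)
  cmp <- compareGroups(v, g)
  expect_equal(cmp$fStatistic, bruteAnovaF(v, g), tolerance = 1e-10)
  expect_equal(cmp$p.value,
    pf(bruteAnovaF(v, g), 1, 8, lower.tail = FALSE), tolerance = 1e-10)
  # two-group Tukey agrees with the equal-variance t-test
  expect_equal(cmp$tukey[, "p adj"], cmp$tTest.p, tolerance = 1e-6,
    ignore_attr = TRUE)
})

test_that("clear separations are significant, identical groups are not", {
  same <- compareGroups(rep(c(5, 5, 5), 2), rep(c("a", "b"), each = 3))
  expect_false(same$significant)
  expect_equal(same$p.value, 1)
  set.seed(94)
  v <- c(rep(0, 5), rep(10, 5) + rnorm(5, 0, 1e-6))
  cmp <- compareGroups(v, rep(c("a", "b"), each = 5))
  expect_true(cmp$significant)
  expect_lt(cmp$p.value, 1e-6)
  expect_error(compareGroups(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("ANOVA p agrees with a permutation test within Monte-Carlo error", {
  set.seed(95)
  v <- c(rnorm(6, 0, 1), rnorm(6, 1.2, 1))
  g <- rep(c("a", "b"), each = 6)
  cmp <- compareGroups(v, g)
  obs <- abs(diff(tapply(v, g, mean)))
  perm <- replicate(4000, {
    gp <- sample(g)
    abs(diff(tapply(v, gp, mean)))
  })
  pPerm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(pPerm - cmp$p.value), 3 * sqrt(pPerm * (1 - pPerm) / 4000) +
    0.02)
})

test_that("accuracy regression matches closed-form OLS", {
  est <- c(10, 15, 20, 25, 30)
  r <- suppressWarnings(accuracyRegression(est, est))  # perfect fit
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r.squared, 1)
  expect_equal(r$rmse, 0)
  # constant offset is absorbed by the intercept ("perfect fit" warning
  # from summary.lm is expected here)
  r2 <- suppressWarnings(accuracyRegression(est + 2, est))
  expect_equal(r2$slope, 1)
  expect_equal(r2$rmse, 0, tolerance = 1e-12)
  set.seed(96)
  actual <- runif(30, 10, 30)
  estimated <- 1.02 * actual - 0.4 + rnorm(30, 0, 0.7)
  r3 <- accuracyRegression(estimated, actual)
  o <- bruteOls(actual, estimated)
  expect_equal(r3$slope, o$slope, tolerance = 1e-10)
  expect_equal(r3$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(r3$r.squared, o$r.squared, tolerance = 1e-10)
  expect_equal(r3$rmse, o$rmse, tolerance = 1e-10)
  expect_equal(r3$percentError, o$rmse / mean(actual) * 100,
    tolerance = 1e-10)
  expect_error(accuracyRegression(1:3, rep(2, 3)), "zero variance")
})

test_that("percent differences follow the stated reference convention", {
  expect_equal(percentDifference(112, 82, "infected")$display, 36L)
  expect_equal(percentDifference(0.2, 0.12, "control")$display, 40L)
  expect_equal(percentDifference(7, 7, "control")$display, 0L)
  # depends only on |control - infected| for a fixed reference value
  expect_equal(percentDifference(20, 15, "control")$percent,
    percentDifference(20, 25, "control")$percent)
  # homogeneous of degree zero
  expect_equal(percentDifference(23, 13, "infected")$percent,
    percentDifference(2300, 1300, "infected")$percent)
  expect_error(percentDifference(1, 0, "infected"), "reference")
})
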