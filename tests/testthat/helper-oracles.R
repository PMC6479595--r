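# Independent brute-force oracles and small fixture builders.

bruteKnn <- function(pts, k) {
  n <- nrow(pts)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt(colSums((t(pts) - pts[i, ])^2))
    d[i] <- Inf
    order(d)[seq_len(k)]
  }, integer(k)))
}

bruteFirstOrder <- function(xi, nb) {
  out <- c(0, 0, 0)
  for (j in seq_len(nrow(nb))) out <- out + (xi - nb[j, ])
  out
}

bruteSecondOrder <- function(xi, nb) {
  out <- matrix(0, 3, 3)
  for (j in seq_len(nrow(nb))) {
    d <- nb[j, ] - xi
    out <- out + d %*% t(d)
  }
  out
}

bruteWidth <- function(xy) {
  n <- nrow(xy)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    best <- max(best, sum((xy[i, ] - xy[j, ])^2))
  sqrt(best)
}

bruteVoxelKeys <- function(pts, size) {
  origin <- apply(pts, 2, min)
  idx <- floor(sweep(pts, 2, origin) / size)
  unique(paste(idx[, 1], idx[, 2], idx[, 3]))
}

# textbook one-way ANOVA F statistic
bruteAnovaF <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  k <- nlevels(groups); n <- length(values)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# closed-form simple OLS
bruteOls <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - (a + b * x)
  list(slope = b, intercept = a,
    r.squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean(res^2)))
}

rotZ <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0, -sin(theta), cos(theta), 0, 0, 0, 1),
    3, 3)
}

randomRotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

# uniformly sampled horizontal disc at height z0
discCloud <- function(n, R = 0.12, z0 = 0.2, sigma = 0) {
  rr <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  p <- cbind(rr * cos(th), rr * sin(th), z0 + rnorm(n, 0, sigma))
  list(cloud = pointCloud(p, frame = "metric"), rr = rr)
}

# points jittered around a vertical line (ideal-line stem sample)
lineCloud <- function(n, len = 0.6, jitter = 1e-4) {
  z <- sort(runif(n, 0, len))
  pointCloud(cbind(rnorm(n, 0, jitter), rnorm(n, 0, jitter), z),
    frame = "metric")
}
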