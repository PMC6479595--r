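#' Growing degree days from an hourly temperature series
#'
#' Daily mean temperature above a base temperature, accumulated from the
#' first day of the series (the planting date). Days with fewer than 24
#' hourly records are flagged incomplete but still contribute their mean.
#'
#' @param timestamps POSIXct (or coercible) hourly timestamps, ordered.
#' @param temps soil temperatures in degrees C, same length.
#' @param tBase base temperature in degrees C (default 5).
#' @return data.frame with `date`, `meanTemp`, `gdd` (daily increment,
#'   `max(0, mean - tBase)`), `cumGdd`, `nHours`, `incomplete`.
#' @export
gddFromTemperature <- function(timestamps, temps, tBase = 5) {
  if (!length(timestamps)) stop("empty temperature series")
  if (length(timestamps) != length(temps))
    stop("timestamps and temps must have the same length")
  ts <- as.POSIXct(timestamps, tz = "UTC")
  if (is.unsorted(ts)) stop("timestamps must be ordered")
  day <- as.Date(ts)
  meanTemp <- tapply(temps, day, mean)
  nHours <- tapply(temps, day, length)
  inc <- pmax(0, meanTemp - tBase)
  data.frame(date = as.Date(names(meanTemp)),
    meanTemp = as.numeric(meanTemp),
    gdd = as.numeric(inc), cumGdd = cumsum(as.numeric(inc)),
    nHours = as.integer(nHours),
    incomplete = as.integer(nHours) < 24L,
    row.names = NULL)
}

#' Fit the three-parameter log-logistic attachment model
#'
#' Least-squares fit of y = a / (1 + (x/x0)^b) to attachments-per-tube
#' against thermal time, with multi-start Levenberg-Marquardt
#' initialization. Reports estimates, asymptotic standard errors, R^2,
#' RMSE, and the F-test p-value of the model against a constant mean.
#'
#' @param series data.frame with columns `gdd` and `attachments` (e.g. from
#'   [generateAttachments()]), or two vectors via `gdd`/`attachments`.
#' @param gdd,attachments alternative vector interface.
#' @return object of class `LogisticFit`: list with `coefficients` (a, x0,
#'   b), `se`, `r.squared`, `rmse`, `p.value`, `fitted`, `residuals`,
#'   `converged`, `degenerate`.
#' @export
fitLogLogistic <- function(series = NULL, gdd = series$gdd,
                           attachments = series$attachments) {
  x <- as.numeric(gdd); y <- as.numeric(attachments)
  n <- length(x)
  if (n < 4L) stop("need at least 4 points to fit 3 parameters")
  if (any(diff(x) <= 0)) stop("gdd must be strictly increasing")
  if (any(y < 0)) stop("attachments must be >= 0")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    fit <- list(coefficients = c(a = mean(y), x0 = NA_real_, b = NA_real_),
      se = c(a = NA_real_, x0 = NA_real_, b = NA_real_),
      r.squared = NA_real_, rmse = 0, p.value = NA_real_,
      fitted = rep(mean(y), n), residuals = rep(0, n),
      converged = FALSE, degenerate = TRUE)
    class(fit) <- "LogisticFit"
    return(fit)
  }
  d <- data.frame(x = x, y = y)
  starts <- list()
  aGuess <- max(y) * c(1.05, 1.5)
  x0Guess <- c(stats::median(x), stats::quantile(x, 0.25),
    stats::quantile(x, 0.75))
  for (a0 in aGuess) for (x00 in x0Guess) for (b0 in c(-2, -6, -12, 2))
    starts[[length(starts) + 1L]] <- c(a = a0, x0 = as.numeric(x00), b = b0)
  best <- NULL
  for (st in starts) {
    f <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ a / (1 + (x / x0)^b), data = d, start = as.list(st),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
  }
  if (is.null(best))
    stop("log-logistic fit failed to converge from any start; ",
      "check that the series is sigmoidal in GDD")
  f <- best$fit
  co <- stats::coef(f)
  se <- tryCatch(summary(f)$coefficients[, "Std. Error"],
    error = function(e) rep(NA_real_, 3))
  rss <- best$rss
  p <- 3L
  fStat <- ((sst - rss) / (p - 1)) / (rss / (n - p))
  pVal <- stats::pf(fStat, p - 1, n - p, lower.tail = FALSE)
  fit <- list(coefficients = c(a = co[["a"]], x0 = co[["x0"]], b = co[["b"]]),
    se = stats::setNames(as.numeric(se), c("a", "x0", "b")),
    r.squared = 1 - rss / sst, rmse = sqrt(rss / n), p.value = pVal,
    fitted = as.numeric(stats::fitted(f)),
    residuals = as.numeric(stats::residuals(f)),
    converged = TRUE, degenerate = FALSE)
  class(fit) <- "LogisticFit"
  fit
}

#' @export
print.LogisticFit <- function(x, ...) {
  if (x$degenerate) {
    cat("Log-logistic fit: degenerate (constant response)\n")
    return(invisible(x))
  }
  cat("Log-logistic fit  y = a / (1 + (x/x0)^b)\n")
  est <- rbind(Estimate = x$coefficients, SE = x$se)
  print(round(est, 4))
  cat(sprintf("R2 = %.4f, RMSE = %.4f, p %s\n", x$r.squared, x$rmse,
    if (is.na(x$p.value)) "= NA" else if (x$p.value < 1e-4) "< 0.0001"
    else sprintf("= %.4f", x$p.value)))
  invisible(x)
}

#' One-way ANOVA with Tukey-HSD comparison of groups
#'
#' For the two-group designs used in infection studies, the Tukey-HSD
#' comparison is the studentized-range equivalent of the two-sample t-test;
#' both p-values are reported.
#'
#' @param values numeric response (e.g. height per plant).
#' @param groups group labels, same length; >= 2 groups with n >= 2 each.
#' @param alpha significance level (default 0.05).
#' @return object of class `GroupComparison`: list with `means`, `se`, `n`,
#'   `fStatistic`, `p.value`, `tukey` (pairwise table), `tTest.p` (two
#'   groups only), `significant`, `alpha`.
#' @export
compareGroups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  if (length(values) != length(groups)) stop("length mismatch")
  means <- tapply(values, groups, mean)
  sds <- tapply(values, groups, stats::sd)
  ns <- tapply(values, groups, length)
  if (all(sds == 0)) {
    # zero variance everywhere: identical groups give p = 1, else separation
    ident <- length(unique(means)) == 1L
    out <- list(means = means, se = sds / sqrt(ns), n = ns,
      fStatistic = if (ident) 0 else Inf,
      p.value = if (ident) 1 else 0,
      tukey = NULL, tTest.p = if (ident) 1 else 0,
      significant = !ident, alpha = alpha)
    class(out) <- "GroupComparison"
    return(out)
  }
  d <- data.frame(v = values, g = groups)
  fit <- stats::aov(v ~ g, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tp <- if (nlevels(groups) == 2L)
    stats::t.test(values ~ groups, var.equal = TRUE)$p.value else NA_real_
  out <- list(means = means, se = sds / sqrt(ns), n = ns,
    fStatistic = an[["F value"]][1], p.value = an[["Pr(>F)"]][1],
    tukey = tk, tTest.p = tp,
    significant = any(tk[, "p adj"] <= alpha), alpha = alpha)
  class(out) <- "GroupComparison"
  out
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("Group comparison (one-way ANOVA + Tukey-HSD)\n")
  tab <- data.frame(mean = as.numeric(x$means), se = as.numeric(x$se),
    n = as.numeric(x$n), row.names = names(x$means))
  print(round(tab, 4))
  cat(sprintf("F = %.4g, p = %.4g, significant at alpha=%.2g: %s\n",
    x$fStatistic, x$p.value, x$alpha, x$significant))
  invisible(x)
}

#' Accuracy regression of estimated vs. actual measurements
#'
#' Ordinary least squares of estimated on actual (both in cm), with the
#' RMSE of the residuals and the percent error defined as
#' RMSE / mean(actual) x 100.
#'
#' @param estimated numeric, model-estimated values (cm).
#' @param actual numeric, manually measured values (cm), same length >= 3.
#' @return object of class `RegressionReport`: list with `slope`,
#'   `intercept`, `r.squared`, `rmse`, `percentError`, `n`.
#' @export
accuracyRegression <- function(estimated, actual) {
  if (length(estimated) != length(actual)) stop("length mismatch")
  if (length(actual) < 3L) stop("need at least 3 pairs")
  if (stats::var(actual) == 0) stop("actual values have zero variance")
  fit <- stats::lm(estimated ~ actual)
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  out <- list(slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r.squared = summary(fit)$r.squared,
    rmse = rmse,
    percentError = rmse / mean(actual) * 100,
    n = length(actual))
  class(out) <- "RegressionReport"
  out
}

#' @export
print.RegressionReport <- function(x, ...) {
  cat(sprintf("y = %.2fx %+.2f (R^2 = %.2f, RMSE = %.2f), %.1f%% error, n = %d\n",
    x$slope, x$intercept, x$r.squared, x$rmse, x$percentError, x$n))
  invisible(x)
}

#' Percent difference between control and infected means
#'
#' |control - infected| / reference x 100, where the reference group is an
#' explicit argument (reporting conventions vary between parameters). The
#' `display` element truncates toward zero, matching how such percentages
#' are conventionally printed.
#'
#' @param control,infected group means (same units).
#' @param reference `"infected"` or `"control"`: the denominator.
#' @return list with `percent` (exact) and `display` (truncated integer).
#' @export
percentDifference <- function(control, infected,
                              reference = c("infected", "control")) {
  reference <- match.arg(reference)
  ref <- if (reference == "infected") infected else control
  if (!is.finite(ref) || ref <= 0) stop("reference value must be > 0")
  pct <- abs(control - infected) / ref * 100
  list(percent = pct, display = as.integer(floor(pct)))
}
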