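#' Construct a cohort scatter
#'
#' @param data data.frame with columns `participant`, `label` ("NC"/"PD"),
#'   `age`, `shape`, `scale`, `maxShift`, optionally `fano` (defaults to
#'   the scale, i.e. the Fano factor of the signature), `minShift`,
#'   `yearsSinceDiagnosis`.
#' @return a [CohortScatter-class].
#' @export
cohortScatter <- function(data) {
  if (is.null(data$fano)) data$fano <- data$scale
  new("CohortScatter", data = as.data.frame(data))
}

#' Power-law fit on the original scale
#'
#' Fits y = a * x^b by nonlinear least squares in the original coordinates,
#' initialised from the log-log linear regression.  Goodness of fit (SSE,
#' R2, adjusted R2 with 2 parameters, RMSE with n - 2 degrees of freedom)
#' is reported on the original y scale; 95% confidence bounds come from the
#' Jacobian-based asymptotic covariance with t(n - 2) quantiles.  The
#' log-log regression itself is available with `method = "loglog"`.
#'
#' @param x,y positive vectors, at least 3 points.
#' @param method `"nls"` (default) or `"loglog"`.
#' @return a [PowerFit-class].
#' @examples
#' x <- c(1, 2, 4, 8); fitPowerLaw(x, 2 * x^-1)  # recovers a = 2, b = -1
#' @export
fitPowerLaw <- function(x, y, method = c("nls", "loglog")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 (x, y) pairs of equal length")
  if (any(x <= 0 | y <= 0)) stop("power fit needs strictly positive data")
  n <- length(x)
  ll <- lm(log(y) ~ log(x))
  start <- list(a = unname(exp(coef(ll)[1])), b = unname(coef(ll)[2]))
  if (method == "loglog") {
    a <- start$a; b <- start$b
    vcv <- suppressWarnings(vcov(ll))  # on (log a, b)
    seA <- a * sqrt(vcv[1, 1])  # delta method
    seB <- sqrt(vcv[2, 2])
  } else {
    fit <- minpack.lm::nlsLM(y ~ a * x^b, start = start,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
    vcv <- suppressWarnings(vcov(fit))
    seA <- sqrt(vcv[1, 1]); seB <- sqrt(vcv[2, 2])
  }
  res <- y - a * x^b
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_  # constant response
  tq <- qt(0.975, n - 2)
  new("PowerFit", coefficient = a, exponent = b,
      ciCoefficient = a + c(-1, 1) * tq * seA,
      ciExponent = b + c(-1, 1) * tq * seB,
      sse = sse, r2 = r2, adjR2 = 1 - (1 - r2) * (n - 1) / (n - 2),
      rmse = sqrt(sse / (n - 2)), n = as.integer(n))
}

#' Ordinary least-squares line fit
#'
#' @param x,y numeric vectors, at least 3 pairs; x must not be constant.
#' @return a [LinearFit-class] with t-based 95% confidence bounds and
#'   goodness of fit (adjusted R2 with 2 parameters).
#' @export
linearFit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 (x, y) pairs of equal length")
  if (sd(x) == 0) stop("singular design: x is constant")
  n <- length(x)
  fit <- lm(y ~ x)
  sse <- sum(resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_  # constant response
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  tq <- qt(0.975, n - 2)
  new("LinearFit",
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      ciSlope = unname(coef(fit)[2] + c(-1, 1) * tq * se[2]),
      ciIntercept = unname(coef(fit)[1] + c(-1, 1) * tq * se[1]),
      sse = sse, r2 = r2, adjR2 = 1 - (1 - r2) * (n - 1) / (n - 2),
      rmse = sqrt(sse / (n - 2)), n = as.integer(n))
}

#' k-medians clustering with the city-block metric
#'
#' Lloyd iterations alternating L1 nearest-centroid assignment and
#' component-wise median centroid update (the median minimises the L1
#' cost, so the total cost is non-increasing and the iteration converges).
#' The best of `restarts` random initialisations by total L1 cost is
#' returned; given `seed` the result is deterministic.
#'
#' @param points numeric matrix (n x d) or data.frame.
#' @param k number of clusters (default 2).
#' @param restarts random restarts (default 50).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return a [ClusterResult-class].
#' @export
kmeansCityblock <- function(points, k = 2L, restarts = 50L, seed = 1L) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < k) stop("need at least k points")
  if (nrow(unique(pts)) < k)
    stop("degenerate input: fewer than k distinct points")
  l1 <- function(cen) {
    # n x k matrix of city-block distances
    sapply(seq_len(nrow(cen)), function(j)
      rowSums(abs(sweep(pts, 2, cen[j, ], "-"))))
  }
  runOnce <- function() {
    cen <- pts[sample.int(n, k), , drop = FALSE]
    trace <- numeric(0)
    asg <- integer(n)
    for (it in 1:200) {
      d <- l1(cen)
      asgNew <- max.col(-d, ties.method = "first")
      # re-seed empty clusters from the farthest point
      for (j in seq_len(k)[tabulate(asgNew, k) == 0L]) {
        far <- which.max(d[cbind(seq_len(n), asgNew)])
        asgNew[far] <- j
      }
      trace <- c(trace, sum(d[cbind(seq_len(n), asgNew)]))
      if (identical(asgNew, asg)) break
      asg <- asgNew
      cen <- t(sapply(seq_len(k), function(j)
        apply(pts[asg == j, , drop = FALSE], 2, median)))
    }
    d <- l1(cen)
    list(asg = asg, cen = cen, trace = trace,
         cost = sum(d[cbind(seq_len(n), asg)]))
  }
  best <- withSeed(seed, {
    runs <- lapply(seq_len(restarts), function(r) runOnce())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "cost"))]]
  })
  colnames(best$cen) <- colnames(pts)
  new("ClusterResult", assignments = as.integer(best$asg),
      centroids = best$cen, cost = best$cost, costTrace = best$trace)
}

#' City-block distances to a centroid
#'
#' @param points n x d matrix or data.frame.
#' @param centroid length-d centroid.
#' @param metric `"cityblock"` (default, consistent with the clustering
#'   metric) or `"euclidean"`.
#' @return numeric vector of distances.
#' @export
centroidDistances <- function(points, centroid,
                              metric = c("cityblock", "euclidean")) {
  metric <- match.arg(metric)
  pts <- as.matrix(points)
  dev <- sweep(pts, 2, as.numeric(centroid), "-")
  if (metric == "cityblock") rowSums(abs(dev)) else sqrt(rowSums(dev^2))
}

#' Identify the normal-control cluster and misclassifications
#'
#' The "NC" cluster is the one holding the majority of veridically
#' labelled NC participants (clusters are named post hoc against labels).
#'
#' @param result a [ClusterResult-class] with k = 2.
#' @param labels character vector of veridical "NC"/"PD" labels.
#' @return list: `ncCluster` (cluster index), `ncCentroid`,
#'   `misclassified` (logical per point), `nMisclassified`,
#'   `ncInPdCluster` and `pdInNcCluster` counts.
#' @export
clusterAgreement <- function(result, labels) {
  stopifnot(is(result, "ClusterResult"), nrow(result@centroids) == 2L)
  asg <- result@assignments
  ncCluster <- which.max(vapply(1:2, function(j)
    sum(labels == "NC" & asg == j), numeric(1)))
  predicted <- ifelse(asg == ncCluster, "NC", "PD")
  mis <- predicted != labels
  list(ncCluster = ncCluster,
       ncCentroid = result@centroids[ncCluster, ],
       misclassified = mis, nMisclassified = sum(mis),
       ncInPdCluster = sum(labels == "NC" & mis),
       pdInNcCluster = sum(labels == "PD" & mis))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when both samples have at most 10 observations
#' and no ties occur; normal approximation with tie correction otherwise.
#'
#' @param x,y non-empty numeric samples.
#' @return list with `statistic` (W) and `p.value` (two-sided).
#' @export
ranksumTest <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) <= 10L && length(y) <= 10L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     correct = !exact))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

.fitStats <- function(f) list(
  estimate1 = if (is(f, "PowerFit")) f@coefficient else f@slope,
  estimate2 = if (is(f, "PowerFit")) f@exponent else f@intercept,
  ci1 = if (is(f, "PowerFit")) f@ciCoefficient else f@ciSlope,
  ci2 = if (is(f, "PowerFit")) f@ciExponent else f@ciIntercept,
  sse = f@sse, r2 = f@r2, adjR2 = f@adjR2, rmse = f@rmse, n = f@n)

#' Cohort-level report
#'
#' Runs the full cohort battery on a labelled scatter: group medians and
#' ranges of Fano factor and maximal shift; power-law fits of scale on
#' shape (full cohort and per group); k = 2 city-block k-medians clustering
#' with misclassification against the veridical labels; OLS of the PD Fano
#' factors on their L1 distances to the NC-cluster centroid; OLS of age on
#' shape per group; and rank-sum tests between groups.  Analyses whose
#' group has fewer than 3 members are skipped with a warning.
#'
#' @param scatter a [CohortScatter-class].
#' @param restarts,seed clustering controls (see [kmeansCityblock()]).
#' @return a list of class `cohortReport`; see [writeCohortReport()] for
#'   serialization.
#' @export
cohortReport <- function(scatter, restarts = 50L, seed = 1L) {
  stopifnot(is(scatter, "CohortScatter"))
  d <- scatter@data
  groups <- split(d, d$label)
  rep <- list(n = lapply(groups, nrow), seed = seed)
  rep$medians <- lapply(groups, function(g) list(
    fano = median(g$fano), fanoRange = range(g$fano),
    maxShift = median(g$maxShift), maxShiftRange = range(g$maxShift)))
  rep$medians$cohort <- list(fano = median(d$fano),
                             maxShift = median(d$maxShift))
  rep$powerFit <- list(cohort = .fitStats(fitPowerLaw(d$shape, d$scale)))
  for (g in names(groups)) {
    if (nrow(groups[[g]]) < 3L) {
      warning("group ", g, " has < 3 members; per-group fits skipped")
      next
    }
    rep$powerFit[[g]] <-
      .fitStats(fitPowerLaw(groups[[g]]$shape, groups[[g]]$scale))
    rep$ageShapeFit[[g]] <-
      .fitStats(linearFit(groups[[g]]$shape, groups[[g]]$age))
  }
  pts <- as.matrix(d[, c("shape", "scale")])
  cl <- kmeansCityblock(pts, k = 2L, restarts = restarts, seed = seed)
  agree <- clusterAgreement(cl, d$label)
  rep$cluster <- list(
    assignments = cl@assignments, centroids = cl@centroids,
    cost = cl@cost, ncCluster = agree$ncCluster,
    ncCentroid = agree$ncCentroid,
    nMisclassified = agree$nMisclassified,
    ncInPdCluster = agree$ncInPdCluster,
    pdInNcCluster = agree$pdInNcCluster,
    misclassifiedIds = d$participant[agree$misclassified])
  pd <- d[d$label == "PD", , drop = FALSE]
  if (nrow(pd) >= 3L) {
    dist <- centroidDistances(pd[, c("shape", "scale")], agree$ncCentroid)
    rep$fanoDistance <- c(.fitStats(linearFit(dist, pd$fano)),
                          list(distances = setNames(dist,
                                                    pd$participant)))
  }
  if (all(vapply(groups, nrow, integer(1)) > 0L) && length(groups) == 2L) {
    rep$ranksum <- list(
      fano = ranksumTest(groups$NC$fano, groups$PD$fano),
      maxShift = ranksumTest(groups$NC$maxShift, groups$PD$maxShift))
  }
  class(rep) <- "cohortReport"
  rep
}

#' Serialize a cohort report
#'
#' Writes the report as JSON plus delimited tables for the fit blocks.
#'
#' @param report result of [cohortReport()].
#' @param dir output directory.
#' @return (invisibly) the JSON path.
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "cohort_report.json")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  fits <- c(lapply(report$powerFit, `[`,
                   c("estimate1", "estimate2", "sse", "r2", "adjR2",
                     "rmse", "n")),
            if (!is.null(report$fanoDistance))
              list(fanoDistance = report$fanoDistance[
                c("estimate1", "estimate2", "sse", "r2", "adjR2", "rmse",
                  "n")]))
  tab <- do.call(rbind, lapply(names(fits), function(nm)
    data.frame(fit = nm, as.data.frame(fits[[nm]]))))
  names(tab) <- c("fit", "estimate1", "estimate2", "sse", "r2", "adjR2",
                  "rmse", "n")
  write.table(tab, file.path(dir, "fits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
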