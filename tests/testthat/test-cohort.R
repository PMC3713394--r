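test_that("power-law fit recovers exact models", {
  x <- c(1, 2, 4, 8, 16)
  f <- fitPowerLaw(x, 2 * x^(-1))
  expect_equal(f@coefficient, 2, tolerance = 1e-8)
  expect_equal(f@exponent, -1, tolerance = 1e-8)
  expect_equal(f@sse, 0, tolerance = 1e-12)
  set.seed(2)
  x2 <- runif(12, 0.5, 5)
  f2 <- fitPowerLaw(x2, 6.36 * x2^(-1.91))
  expect_equal(f2@coefficient, 6.36, tolerance = 1e-8)
  expect_equal(f2@exponent, -1.91, tolerance = 1e-8)
  expect_error(fitPowerLaw(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(fitPowerLaw(1:2, 1:2), ">= 3")
  # the log-log variant is the initializer, exact on noiseless data too
  f3 <- fitPowerLaw(x, 2 * x^(-1), method = "loglog")
  expect_equal(f3@exponent, -1, tolerance = 1e-10)
})

test_that("linear fit equals the closed-form normal equations", {
  x <- c(0, 1, 2, 4)
  f <- linearFit(x, 2 * x + 1)
  expect_equal(f@slope, 2, tolerance = 1e-12)
  expect_equal(f@intercept, 1, tolerance = 1e-12)
  expect_equal(f@sse, 0, tolerance = 1e-12)
  set.seed(3)
  xr <- rnorm(20); yr <- 3 * xr - 2 + rnorm(20)
  fr <- linearFit(xr, yr)
  beta <- solve(crossprod(cbind(1, xr)), crossprod(cbind(1, xr), yr))
  expect_equal(fr@intercept, beta[1], tolerance = 1e-10)
  expect_equal(fr@slope, beta[2], tolerance = 1e-10)
  expect_error(linearFit(rep(2, 5), 1:5), "singular")
})

test_that("city-block k-medians separates blobs and minimises L1 cost", {
  set.seed(5)
  blob1 <- cbind(rnorm(5, 0, 0.1), rnorm(5, 0, 0.1))
  blob2 <- cbind(rnorm(5, 10, 0.1), rnorm(5, 10, 0.1))
  pts <- rbind(blob1, blob2)
  res <- kmeansCityblock(pts, k = 2, restarts = 10, seed = 1)
  expect_identical(length(unique(res@assignments[1:5])), 1L)
  expect_identical(length(unique(res@assignments[6:10])), 1L)
  expect_false(res@assignments[1] == res@assignments[6])

  # per-iteration cost trace is non-increasing (validity also enforces it)
  expect_true(all(diff(res@costTrace) <= 1e-8))

  # randomized oracle: no random assignment with median centroids beats it
  set.seed(6)
  rndCost <- replicate(1000, {
    asg <- sample(1:2, nrow(pts), replace = TRUE)
    if (length(unique(asg)) < 2) Inf else {
      cen <- t(sapply(1:2, function(j)
        apply(pts[asg == j, , drop = FALSE], 2, median)))
      sum(vapply(seq_len(nrow(pts)), function(i)
        sum(abs(pts[i, ] - cen[asg[i], ])), numeric(1)))
    }
  })
  expect_lte(res@cost, min(rndCost) + 1e-9)

  # determinism given the seed
  res2 <- kmeansCityblock(pts, k = 2, restarts = 10, seed = 1)
  expect_identical(res@assignments, res2@assignments)
  expect_error(kmeansCityblock(matrix(1, 4, 2), k = 2), "degenerate")
})

test_that("centroid distances use the clustering metric", {
  expect_equal(centroidDistances(rbind(c(2.96, 0.78)), c(2.96, 0.78)), 0)
  expect_equal(centroidDistances(rbind(c(1, 1)), c(4, 5)), 7)
  expect_equal(centroidDistances(rbind(c(1, 1)), c(4, 5),
                                 metric = "euclidean"), 5)
})

test_that("rank-sum test matches full enumeration on small samples", {
  x <- c(1.3, 2.2, 0.7); y <- c(3.1, 2.9, 4.0)
  expect_equal(ranksumTest(x, y)$p.value, oracleRanksumP(x, y))
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(sample(3:5, 1)); b <- rnorm(sample(3:5, 1), 0.5)
    expect_equal(ranksumTest(a, b)$p.value, oracleRanksumP(a, b),
                 tolerance = 1e-12)
  }
  same <- c(1, 2, 3, 4)
  expect_equal(ranksumTest(same, same)$p.value, 1)
  expect_error(ranksumTest(numeric(0), 1:3), "non-empty")
})

test_that("cohort report medians match a sort-based oracle", {
  set.seed(8)
  d <- data.frame(
    participant = sprintf("p%02d", 1:12),
    label = rep(c("NC", "PD"), each = 6),
    age = c(50:55, 60:65),
    shape = c(runif(6, 2, 4), runif(6, 0.6, 1.5)),
    scale = c(runif(6, 0.4, 1.2), runif(6, 3, 14)),
    maxShift = c(runif(6, 5, 15), runif(6, 20, 80)))
  rep <- cohortReport(cohortScatter(d), restarts = 20, seed = 3)
  sortMedian <- function(v) {
    s <- sort(v); n <- length(s)
    if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  expect_identical(rep$medians$NC$fano,
                   sortMedian(d$scale[d$label == "NC"]))
  expect_identical(rep$medians$PD$maxShift,
                   sortMedian(d$maxShift[d$label == "PD"]))
  expect_identical(rep$medians$cohort$maxShift, sortMedian(d$maxShift))
  expect_identical(rep$medians$NC$fanoRange,
                   range(d$scale[d$label == "NC"]))
  # generated group contrast is reflected in the report ordering
  expect_gt(rep$medians$PD$fano, rep$medians$NC$fano)
  expect_lt(rep$ranksum$fano$p.value, 0.05)

  # report serializes
  dir <- withr::local_tempdir()
  writeCohortReport(rep, dir)
  expect_true(file.exists(file.path(dir, "cohort_report.json")))
  expect_true(file.exists(file.path(dir, "fits.tsv")))

  # a too-small group skips the per-group analyses with a warning
  small <- d[c(1:2, 7:12), ]
  expect_warning(rep2 <- cohortReport(cohortScatter(small), restarts = 5,
                                      seed = 3), "skipped")
  expect_null(rep2$powerFit$NC)
})

test_that("cluster agreement names the NC cluster post hoc", {
  pts <- rbind(cbind(rnorm(5, 0, 0.1), rnorm(5, 0, 0.1)),
               cbind(rnorm(5, 8, 0.1), rnorm(5, 8, 0.1)))
  res <- kmeansCityblock(pts, seed = 2)
  lab <- rep(c("NC", "PD"), each = 5)
  ag <- clusterAgreement(res, lab)
  expect_identical(ag$nMisclassified, 0L)
  expect_equal(unname(ag$ncCentroid),
               unname(apply(pts[1:5, ], 2, median)), tolerance = 1e-9)
})
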