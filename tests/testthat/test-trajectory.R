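mkSigs <- function(shapes, scales, days = NULL) {
  sigs <- Map(function(a, b) gammaEstimate(a, b, n = 100L), shapes, scales)
  attr(sigs, "entryIndex") <- seq_along(shapes)
  attr(sigs, "day") <- if (is.null(days)) rep(1L, length(shapes))
                       else as.integer(days)
  attr(sigs, "session") <- rep(1L, length(shapes))
  sigs
}

test_that("trajectories preserve acquisition order across days", {
  sigs <- mkSigs(1:5, 5:1, days = c(1, 1, 1, 2, 2))
  traj <- buildTrajectory(sigs, "p1")
  expect_identical(nrow(trajectoryPoints(traj)), 5L)
  expect_identical(trajectoryPoints(traj)$day, c(1L, 1L, 1L, 2L, 2L))
  expect_length(shiftValues(shiftMagnitudes(traj)), 4)  # 4 segments
  expect_error(buildTrajectory(mkSigs(1, 1)), "insufficient")
})

test_that("shifts are Euclidean distances with the rest cutoff", {
  traj <- buildTrajectory(mkSigs(c(1, 4), c(1, 5)), "p1")
  expect_equal(shiftValues(shiftMagnitudes(traj)), 5)

  trajSame <- buildTrajectory(mkSigs(c(2, 2, 3), c(7, 7, 7)), "p1")
  prof <- shiftMagnitudes(trajSame)
  expect_equal(prof@shifts[1], 0)
  expect_identical(prof@subCutoff, c(TRUE, FALSE))

  set.seed(4)
  a <- runif(10, 0.5, 4); b <- runif(10, 0.5, 10)
  prof10 <- shiftMagnitudes(buildTrajectory(mkSigs(a, b), "p1"))
  brute <- vapply(1:9, function(i)
    sqrt((a[i + 1] - a[i])^2 + (b[i + 1] - b[i])^2), numeric(1))
  expect_equal(shiftValues(prof10), brute)
})

test_that("speed profile ignores day segmentation but not point order", {
  set.seed(6)
  a <- runif(8, 0.5, 4); b <- runif(8, 0.5, 10)
  s1 <- shiftValues(shiftMagnitudes(
    buildTrajectory(mkSigs(a, b, days = rep(1, 8)), "p")))
  s2 <- shiftValues(shiftMagnitudes(
    buildTrajectory(mkSigs(a, b, days = c(1, 1, 2, 2, 2, 3, 3, 3)), "p")))
  expect_identical(s1, s2)
  sRev <- shiftValues(shiftMagnitudes(
    buildTrajectory(mkSigs(rev(a), rev(b)), "p")))
  expect_equal(sRev, rev(s1))
})

test_that("peaks are the supra-threshold moving shifts", {
  prof <- new("SpeedProfile", shifts = c(0.5, 1.2, 0.001, 27.7),
              subCutoff = c(FALSE, FALSE, TRUE, FALSE), cutoff = 0.002)
  expect_equal(extractPeaks(prof), c(1.2, 27.7))
  expect_warning(
    none <- extractPeaks(new("SpeedProfile", shifts = c(0.2, 0.9),
                             subCutoff = c(FALSE, FALSE),
                             cutoff = 0.002)),
    "more data")
  expect_length(none, 0)
  # threshold-0 identity when nothing is flagged
  noFlags <- new("SpeedProfile", shifts = c(0.5, 1.2, 27.7),
                 subCutoff = rep(FALSE, 3), cutoff = 0.002)
  expect_equal(extractPeaks(noFlags, threshold = 0), noFlags@shifts)
})

test_that("person signature fits the peak distribution", {
  set.seed(8)
  peaks <- rgamma(5000, shape = 0.7476, scale = 13.4048)
  prof <- new("SpeedProfile", shifts = peaks,
              subCutoff = rep(FALSE, 5000), cutoff = 0.002)
  sig <- personSignature("orchidoid", peaks, prof)
  expect_s4_class(sig, "PersonSignature")
  expect_equal(fanoFactor(sig), 13.4048, tolerance = 0.05)
  expect_identical(sig@maxShift, max(peaks))
  expect_identical(sig@nPeaks, 5000L)

  # scale-1 peaks have Fano about 1 whatever the shape
  for (a in c(0.6, 2, 5)) {
    pk <- rgamma(3000, shape = a, scale = 1)
    pr <- new("SpeedProfile", shifts = pk,
              subCutoff = rep(FALSE, 3000), cutoff = 0.002)
    expect_equal(fanoFactor(personSignature("p", pk, pr)), 1,
                 tolerance = 0.08)
  }

  expect_warning(out <- personSignature("few", peaks[1:5], prof),
                 "excluded")
  expect_null(out)
})

test_that("the Fano factor of a Gamma fit matches Monte-Carlo dispersion", {
  expect_identical(fanoFactor(gammaEstimate(0.7476, 13.4048)), 13.4048)
  expect_identical(fanoFactor(gammaEstimate(5, 1)), 1)
  set.seed(10)
  x <- rgamma(1e6, shape = 2, scale = 3)
  expect_equal(var(x) / mean(x), 3, tolerance = 0.01)
  expect_equal(fanoFactor(fitGammaMLE(x)), 3, tolerance = 0.01)
})
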