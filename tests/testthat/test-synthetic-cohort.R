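test_that("a drift-free persona is stationary at its baseline", {
  p <- persona("stat", a0 = 3.5, b0 = 0.64, driftSd = 0, jumpProb = 0,
               contaminationProb = 0, days = 2L, sessionsPerDay = 2L,
               readingsPerSession = 500L, seed = 42L)
  sim <- simulatePersonaStream(p)
  vals <- magnitudes(magnitudeSeries(sim$sessions))
  mu <- 3.5 * 0.64
  se <- sqrt(3.5 * 0.64^2 / length(vals))
  expect_lt(abs(mean(vals) - mu), 3 * se)
  expect_true(all(sim$ledger$shape == 3.5 & sim$ledger$scale == 0.64))
})

test_that("persona streams are reproducible and validated", {
  p <- pdPersona("pd1", seed = 9L, days = 2L, sessionsPerDay = 2L)
  s1 <- simulatePersonaStream(p)
  s2 <- simulatePersonaStream(p)
  expect_identical(s1$ledger, s2$ledger)
  expect_identical(s1$sessions[[3]]@readings, s2$sessions[[3]]@readings)
  expect_error(persona("bad", a0 = -1), "positive")
  expect_error(persona("bad", readingsPerSession = 50), ">= 100")
  expect_error(persona("bad", jumpProb = 1.5), "probabilities")
})

test_that("jump events occur at about the configured rate", {
  p <- persona("j", a0 = 1.5, b0 = 2, driftSd = 0.02, jumpProb = 0.05,
               contaminationProb = 0, days = 5L, sessionsPerDay = 4L,
               readingsPerSession = 1000L, seed = 5L)  # 200 blocks
  led <- simulatePersonaStream(p)$ledger
  expect_identical(nrow(led), 200L)
  nJump <- sum(led$jump)
  # Binomial(200, 0.05): central 99.9% range
  expect_gte(nJump, qbinom(0.0005, 200, 0.05))
  expect_lte(nJump, qbinom(0.9995, 200, 0.05))
})

test_that("simulated cohorts land on disk deterministically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- function() list(
    ncPersona("n1", seed = 3L, days = 1L, sessionsPerDay = 1L,
              readingsPerSession = 100L),
    pdPersona("p1", seed = 4L, days = 1L, sessionsPerDay = 1L,
              readingsPerSession = 100L))
  simulateCohort(spec(), d1)
  simulateCohort(spec(), d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(sort(f1))),
                   unname(tools::md5sum(sort(f2))))
  # one session of 100 readings -> exactly one entry downstream
  ser <- magnitudeSeries(readSession(file.path(d1, "n1", "1", "1.csv")))
  expect_length(chunkEntries(ser), 1)
})

test_that("the default cohort has 6 NC-like and 9 PD-like personas", {
  spec <- defaultCohortSpec(seed = 2L, days = 1L, sessionsPerDay = 1L)
  labels <- vapply(spec, function(p) p@label, character(1))
  expect_identical(sum(labels == "NC"), 6L)
  expect_identical(sum(labels == "PD"), 9L)
  expect_identical(anyDuplicated(vapply(spec, function(p) p@seed,
                                        integer(1))), 0L)
  dir <- withr::local_tempdir()
  simulateCohort(spec, dir)
  expect_length(list.dirs(dir, recursive = FALSE), 15)
})

test_that("downstream MLE recovers stationary ground truth within 5%", {
  for (a0 in c(0.75, 1.5, 3.5)) {
    p <- persona(paste0("r", a0), a0 = a0, b0 = 2.5, driftSd = 0,
                 jumpProb = 0, contaminationProb = 0, days = 1L,
                 sessionsPerDay = 1L, readingsPerSession = 10000L,
                 seed = round(100 * a0))
    vals <- magnitudes(magnitudeSeries(simulatePersonaStream(p)$sessions))
    f <- fitGammaMLE(vals)
    expect_lt(abs(shapeParam(f) - a0) / a0, 0.05)
    expect_lt(abs(scaleParam(f) - 2.5) / 2.5, 0.05)
  }
})

test_that("entry-level CIs cover stationary truth 90-99% of the time", {
  p <- persona("cov", a0 = 2, b0 = 1.5, driftSd = 0, jumpProb = 0,
               contaminationProb = 0, days = 1L, sessionsPerDay = 2L,
               readingsPerSession = 10000L, seed = 21L)  # 200 entries
  ser <- magnitudeSeries(simulatePersonaStream(p)$sessions)
  fits <- lapply(chunkEntries(ser), function(e) fitGammaMLE(e@samples))
  expect_gte(length(fits), 200)
  covA <- mean(vapply(fits, function(f)
    f@ciShape[1] <= 2 && 2 <= f@ciShape[2], logical(1)))
  covB <- mean(vapply(fits, function(f)
    f@ciScale[1] <= 1.5 && 1.5 <= f@ciScale[2], logical(1)))
  expect_gte(covA, 0.90); expect_lte(covA, 0.99)
  expect_gte(covB, 0.90); expect_lte(covB, 0.99)
})

test_that("rescaling the stream rescales only the recovered scale", {
  p <- persona("eq", a0 = 1.2, b0 = 3, driftSd = 0.05, jumpProb = 0,
               contaminationProb = 0, days = 1L, sessionsPerDay = 1L,
               readingsPerSession = 2000L, seed = 31L)
  ser <- magnitudeSeries(simulatePersonaStream(p)$sessions)
  fits <- lapply(chunkEntries(ser), function(e) fitGammaMLE(e@samples))
  serC <- seriesFromValues(ser@values * 50)
  fitsC <- lapply(chunkEntries(serC), function(e) fitGammaMLE(e@samples))
  for (i in seq_along(fits)) {
    expect_equal(shapeParam(fitsC[[i]]), shapeParam(fits[[i]]),
                 tolerance = 1e-6)
    expect_equal(scaleParam(fitsC[[i]]), 50 * scaleParam(fits[[i]]),
                 tolerance = 1e-6)
  }
})
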