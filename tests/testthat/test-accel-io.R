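test_that("vector magnitude is the Euclidean norm and rejects bad input", {
  expect_equal(vectorMagnitude(c(3, 4, 0)), 5)
  expect_equal(vectorMagnitude(c(0, 0, 0)), 0)
  expect_equal(vectorMagnitude(c(1, 2, 2)), 3)
  expect_error(vectorMagnitude(c(1, NA, 2)), "finite")
  expect_error(vectorMagnitude(c(1, 2)), "3-vector")
})

test_that("vector magnitude is rotation invariant", {
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(3)
    R <- randomRotation()
    expect_equal(vectorMagnitude(as.numeric(R %*% v)), vectorMagnitude(v),
                 tolerance = 1e-9)
  }
})

test_that("session files read, drop corrupt rows, and round-trip", {
  dir <- withr::local_tempdir()
  df <- makeSessionDF(100)
  f <- writeSessionFile(df, file.path(dir, "alice", "1", "1.csv"))
  s <- readSession(f)
  expect_s4_class(s, "Session")
  expect_identical(nrow(s@readings), 100L)
  expect_identical(participantId(s), "alice")
  expect_identical(s@dayIndex, 1L)

  # one corrupt row of 100 is dropped and counted
  lines <- readLines(f)
  lines[51] <- sub("^([^,]*),[^,]*", "\\1,not_a_number", lines[51])
  f2 <- file.path(dir, "alice", "1", "2.csv")
  writeLines(lines, f2)
  expect_warning(s2 <- readSession(f2), "1 corrupt row")
  expect_identical(nrow(s2@readings), 99L)
  expect_identical(s2@nDropped, 1L)

  # empty file and missing columns are format errors
  f3 <- file.path(dir, "empty.csv"); file.create(f3)
  expect_error(readSession(f3), "empty")
  f4 <- writeSessionFile(df[, -2], file.path(dir, "alice", "1", "4.csv"))
  expect_error(readSession(f4), "x_maxdev")

  # tab dialect is auto-detected; write/read round-trips numerically
  f5 <- writeSessionFile(df, file.path(dir, "alice", "2", "1.csv"),
                         sep = "\t")
  s5 <- readSession(f5)
  expect_equal(s5@readings$x_maxdev, df$x_maxdev, tolerance = 1e-9)
  f6 <- file.path(dir, "alice", "2", "2.csv")
  writeSession(s5, f6)
  s6 <- readSession(f6, participantId = "alice", dayIndex = 2,
                    sessionIndex = 2)
  expect_equal(s6@readings, s5@readings, tolerance = 1e-9)
})

test_that("magnitude series concatenates in (day, session) order", {
  mk <- function(day, session, xs)
    new("Session", participantId = "p", dayIndex = as.integer(day),
        sessionIndex = as.integer(session),
        readings = data.frame(t = seq_along(xs) - 1, x_maxdev = xs,
                              y_maxdev = 0, z_maxdev = 0))
  s11 <- mk(1, 1, rep(1, 100)); s12 <- mk(1, 2, rep(2, 100))
  s21 <- mk(2, 1, rep(3, 50))
  ser <- magnitudeSeries(list(s11, s12, s21))
  expect_identical(length(ser), 250L)
  expect_equal(unique(ser@values[1:100]), 1)

  # sessions supplied out of order are re-ordered; provenance proves it
  shuffled <- magnitudeSeries(list(s21, s12, s11))
  expect_equal(shuffled@values, ser@values)
  expect_identical(shuffled@day, c(rep(1L, 200), rep(2L, 50)))
  expect_identical(shuffled@session[1:200], rep(c(1L, 2L), each = 100))

  s11b <- mk(1, 1, 5); s11b@participantId <- "other"
  expect_error(magnitudeSeries(list(s11, s11b)), "mix participant ids")

  one <- mk(1, 1, c(5))
  one@readings[1, c("x_maxdev", "y_maxdev", "z_maxdev")] <- c(3, 4, 0)
  expect_equal(magnitudes(magnitudeSeries(list(one))), 5)
})

test_that("magnitude series serializes with provenance sidecar", {
  dir <- withr::local_tempdir()
  ser <- seriesFromValues(c(1.25, 2.5, 3.75))
  p <- file.path(dir, "series.csv")
  writeMagnitudeSeries(ser, p)
  back <- utils::read.table(p, header = TRUE, sep = ",")
  expect_equal(back$magnitude, ser@values, tolerance = 1e-9)
  side <- jsonlite::read_json(paste0(p, ".json"), simplifyVector = TRUE)
  expect_identical(side$participant, "p1")
  expect_identical(length(side$day), 3L)
})
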