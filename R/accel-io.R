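#' Euclidean magnitude of a 3-component deviation vector
#'
#' @param v numeric vector of exactly 3 finite components (X, Y, Z of the
#'   maximal deviation from the mean acceleration).
#' @return non-negative scalar, sqrt(x^2 + y^2 + z^2).
#' @examples
#' vectorMagnitude(c(3, 4, 0))  # 5
#' @export
vectorMagnitude <- function(v) {
  if (length(v) != 3L || !is.numeric(v) || !all(is.finite(v)))
    stop("v must be a numeric 3-vector with finite components")
  sqrt(sum(v^2))
}

.sessionCols <- c("t", "x_mean", "y_mean", "z_mean",
                  "x_maxdev", "y_maxdev", "z_maxdev")

#' Read one session file of accelerometer summaries
#'
#' Reads a delimited text file (comma or tab, auto-detected) with a header
#' row naming at least `t`, `x_maxdev`, `y_maxdev`, `z_maxdev`; the mean
#' acceleration columns `x_mean`, `y_mean`, `z_mean` are optional.  Rows
#' with missing or non-numeric max-deviation components are dropped and
#' counted in the `nDropped` slot with a warning.
#'
#' @param path path to the session file.
#' @param participantId,dayIndex,sessionIndex identity of the session; when
#'   NULL they are taken from the conventional path layout
#'   `<participant>/<day>/<session>.csv`.
#' @return a [Session-class].
#' @export
readSession <- function(path, participantId = NULL, dayIndex = NULL,
                        sessionIndex = NULL) {
  if (!file.exists(path)) stop("cannot read session file: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header))
    stop("empty session file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep,
                   colClasses = NA, stringsAsFactors = FALSE)
  need <- c("t", "x_maxdev", "y_maxdev", "z_maxdev")
  missingCols <- setdiff(need, names(df))
  if (length(missingCols))
    stop("session file ", path, " lacks column(s): ",
         paste(missingCols, collapse = ", "))
  for (cn in intersect(.sessionCols, names(df)))
    df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  ok <- complete.cases(df[, need]) &
    is.finite(df$x_maxdev) & is.finite(df$y_maxdev) & is.finite(df$z_maxdev)
  nDropped <- sum(!ok)
  if (nDropped > 0L)
    warning(nDropped, " corrupt row(s) dropped from ", path)
  df <- df[ok, intersect(.sessionCols, names(df)), drop = FALSE]
  if (nrow(df) == 0L) stop("session file ", path, " has no valid rows")
  parts <- rev(strsplit(normalizePath(path, mustWork = FALSE),
                        .Platform$file.sep)[[1]])
  if (is.null(sessionIndex))
    sessionIndex <- as.integer(sub("\\..*$", "", parts[1]))
  if (is.null(dayIndex)) dayIndex <- as.integer(parts[2])
  if (is.null(participantId)) participantId <- parts[3]
  rownames(df) <- NULL
  new("Session", participantId = participantId,
      dayIndex = as.integer(dayIndex),
      sessionIndex = as.integer(sessionIndex),
      readings = df, nDropped = as.integer(nDropped))
}

#' Write a session to a delimited file
#'
#' Inverse of [readSession()]; numeric content round-trips to full
#' precision.
#'
#' @param session a [Session-class].
#' @param path output file path (directories are created).
#' @param sep field separator, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
writeSession <- function(session, path, sep = ",") {
  stopifnot(is(session, "Session"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- session@readings
  out <- data.frame(lapply(df, function(col) format(col, digits = 15,
                                                   trim = TRUE,
                                                   scientific = FALSE)),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce ordered sessions to a magnitude series
#'
#' Concatenates the Euclidean magnitudes of the per-reading max-deviation
#' vectors in lexicographic (day, session, row) order, carrying provenance
#' tags.  The acquisition index -- not wall-clock time -- is the clock of
#' all downstream statistics; timestamps only order readings within a
#' session.
#'
#' @param sessions list of [Session-class] objects for one participant, in
#'   any order (they are sorted by day then session).
#' @return a [MagnitudeSeries-class].
#' @export
magnitudeSeries <- function(sessions) {
  if (is(sessions, "Session")) sessions <- list(sessions)
  if (!length(sessions)) stop("no sessions supplied")
  ids <- unique(vapply(sessions, participantId, character(1)))
  if (length(ids) != 1L)
    stop("sessions mix participant ids: ", paste(ids, collapse = ", "))
  ord <- order(vapply(sessions, function(s) s@dayIndex, integer(1)),
               vapply(sessions, function(s) s@sessionIndex, integer(1)))
  sessions <- sessions[ord]
  vals <- lapply(sessions, function(s) {
    m <- as.matrix(s@readings[, c("x_maxdev", "y_maxdev", "z_maxdev")])
    sqrt(rowSums(m^2))
  })
  n <- vapply(vals, length, integer(1))
  new("MagnitudeSeries", participantId = ids,
      values = unlist(vals, use.names = FALSE),
      day = rep(vapply(sessions, function(s) s@dayIndex, integer(1)), n),
      session = rep(vapply(sessions, function(s) s@sessionIndex,
                           integer(1)), n))
}

#' Serialize a magnitude series
#'
#' Writes a two-column delimited file (index, magnitude) and a JSON sidecar
#' with the per-value (day, session) provenance.
#'
#' @param series a [MagnitudeSeries-class].
#' @param path output file; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeMagnitudeSeries <- function(series, path) {
  stopifnot(is(series, "MagnitudeSeries"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(index = seq_along(series@values),
                   magnitude = format(series@values, digits = 15,
                                      trim = TRUE, scientific = FALSE))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(participant = series@participantId,
         day = series@day, session = series@session),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
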