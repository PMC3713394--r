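#' Chunk a magnitude series into data entries
#'
#' Splits the acquisition-ordered magnitudes into consecutive disjoint
#' blocks of exactly `window` values (default 100, the basic estimation
#' unit).  A trailing remainder shorter than the window is discarded with a
#' warning; blocks never span participants because a series belongs to one.
#'
#' @param series a [MagnitudeSeries-class].
#' @param window block size, >= 2.
#' @return list of [DataEntry-class] in acquisition order (empty, with a
#'   warning, when the series is shorter than one window).
#' @export
chunkEntries <- function(series, window = 100L) {
  stopifnot(is(series, "MagnitudeSeries"))
  window <- as.integer(window)
  if (window < 2L) stop("window must be >= 2")
  n <- length(series@values)
  nBlocks <- n %/% window
  if (nBlocks == 0L) {
    warning("series shorter than one window (", n, " < ", window,
            "); no entries")
    return(list())
  }
  if (n %% window)
    warning(n %% window, " trailing value(s) discarded (< 1 window)")
  lapply(seq_len(nBlocks), function(k) {
    idx <- ((k - 1L) * window + 1L):(k * window)
    new("DataEntry", entryIndex = k, samples = series@values[idx],
        participantId = series@participantId,
        day = series@day[idx[1L]], session = series@session[idx[1L]])
  })
}

#' Per-entry Gamma signatures with dip-test screening
#'
#' For each data entry in acquisition order: run the dip test on the raw
#' samples and discard multimodal entries (p < `dipAlpha`, default 0.01);
#' drop zero magnitudes (Gamma support is x > 0) with a logged count; fit
#' the Gamma MLE on the survivors.  Output order is acquisition order; the
#' discarded entries are reported in the `discarded` attribute so that
#' `length(output) + discarded = length(input)` always holds.
#'
#' @param entries list of [DataEntry-class] in acquisition order.
#' @param dipAlpha discard threshold for the dip-test p-value.
#' @param nBoot,seed bootstrap controls passed to [dipTest()].
#' @return list of [GammaEstimate-class] for surviving entries, with
#'   attributes `entryIndex` (their acquisition indices), `day`, `session`,
#'   `discarded` (count) and `discardedIndex`.  When everything is
#'   discarded an empty list is returned with a warning: the participant
#'   carries too little usable signal and is excluded downstream.
#' @export
entrySignatures <- function(entries, dipAlpha = 0.01, nBoot = 500L,
                            seed = 1L) {
  if (!length(entries)) return(structure(list(), entryIndex = integer(0),
                                         day = integer(0),
                                         session = integer(0),
                                         discarded = 0L,
                                         discardedIndex = integer(0)))
  keep <- logical(length(entries))
  fits <- vector("list", length(entries))
  nZero <- 0L
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    dt <- dipTest(e@samples, nBoot = nBoot, seed = seed)
    if (dt$p.value < dipAlpha) next
    x <- e@samples[e@samples > 0]
    nZero <- nZero + (length(e@samples) - length(x))
    if (length(x) < 10L) next
    fits[[i]] <- fitGammaMLE(x, dipP = dt$p.value)
    keep[i] <- TRUE
  }
  if (nZero > 0L)
    message(nZero, " zero magnitude(s) dropped before fitting")
  out <- fits[keep]
  if (!length(out))
    warning("all ", length(entries), " entries discarded as multimodal; ",
            "participant should be excluded from the cohort stage")
  structure(out,
    entryIndex = vapply(entries[keep], function(e) e@entryIndex,
                        integer(1)),
    day = vapply(entries[keep], function(e) e@day, integer(1)),
    session = vapply(entries[keep], function(e) e@session, integer(1)),
    discarded = sum(!keep),
    discardedIndex = vapply(entries[!keep], function(e) e@entryIndex,
                            integer(1)))
}

#' Tabulate entry signatures
#'
#' Flattens the output of [entrySignatures()] into a data.frame suitable
#' for delimited-text export.
#'
#' @param signatures result of [entrySignatures()].
#' @param participantId id recorded in the table.
#' @return data.frame with one row per surviving entry.
#' @export
signatureTable <- function(signatures, participantId = NA_character_) {
  if (!length(signatures))
    return(data.frame(participant = character(0), entry = integer(0),
                      shape = numeric(0), scale = numeric(0),
                      shapeLo = numeric(0), shapeHi = numeric(0),
                      scaleLo = numeric(0), scaleHi = numeric(0),
                      dipP = numeric(0), n = integer(0), day = integer(0),
                      session = integer(0)))
  data.frame(
    participant = participantId,
    entry = attr(signatures, "entryIndex"),
    shape = vapply(signatures, shapeParam, numeric(1)),
    scale = vapply(signatures, scaleParam, numeric(1)),
    shapeLo = vapply(signatures, function(e) e@ciShape[1], numeric(1)),
    shapeHi = vapply(signatures, function(e) e@ciShape[2], numeric(1)),
    scaleLo = vapply(signatures, function(e) e@ciScale[1], numeric(1)),
    scaleHi = vapply(signatures, function(e) e@ciScale[2], numeric(1)),
    dipP = vapply(signatures, function(e) e@dipP, numeric(1)),
    n = vapply(signatures, function(e) e@n, integer(1)),
    day = attr(signatures, "day"),
    session = attr(signatures, "session"))
}
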