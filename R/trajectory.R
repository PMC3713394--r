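#' Build a stochastic trajectory from ordered Gamma estimates
#'
#' Places the per-entry (shape, scale) estimates on the Gamma plane in the
#' order in which they were acquired and pieces the per-day segments
#' together into one longitudinal trajectory; day boundaries stay tagged on
#' the points.
#'
#' @param signatures list of [GammaEstimate-class] from
#'   [entrySignatures()] (its `entryIndex`/`day`/`session` attributes are
#'   used when present).
#' @param participantId participant identifier.
#' @param entryIndex,day,session optional explicit tags overriding the
#'   attributes.
#' @return a [StochasticTrajectory-class].
#' @export
buildTrajectory <- function(signatures, participantId = NA_character_,
                            entryIndex = NULL, day = NULL, session = NULL) {
  n <- length(signatures)
  if (n < 2L)
    stop("insufficient trajectory: need >= 2 Gamma-plane points, got ", n)
  if (is.null(entryIndex)) entryIndex <- attr(signatures, "entryIndex")
  if (is.null(entryIndex)) entryIndex <- seq_len(n)
  if (is.null(day)) day <- attr(signatures, "day")
  if (is.null(day)) day <- rep(1L, n)
  if (is.null(session)) session <- attr(signatures, "session")
  if (is.null(session)) session <- rep(1L, n)
  pts <- data.frame(entry = as.integer(entryIndex),
                    shape = vapply(signatures, shapeParam, numeric(1)),
                    scale = vapply(signatures, scaleParam, numeric(1)),
                    day = as.integer(day), session = as.integer(session))
  pts <- pts[order(pts$entry), , drop = FALSE]
  rownames(pts) <- NULL
  new("StochasticTrajectory", participantId = participantId, points = pts)
}

#' Speed profile of a trajectory
#'
#' The shift between consecutive Gamma-plane points is their Euclidean
#' distance on the raw (shape, scale) plane; the acquisition index is the
#' clock, so each shift is a speed per unit step.  Shifts below `cutoff`
#' (default 0.002, the stochastic-motion cutoff) are flagged as stochastic
#' rest and excluded from peak and median statistics.
#'
#' @param traj a [StochasticTrajectory-class] with >= 2 points.
#' @param cutoff stochastic-motion cutoff.
#' @return a [SpeedProfile-class] with one shift per consecutive pair.
#' @export
shiftMagnitudes <- function(traj, cutoff = 0.002) {
  stopifnot(is(traj, "StochasticTrajectory"))
  p <- traj@points
  shifts <- sqrt(diff(p$shape)^2 + diff(p$scale)^2)
  new("SpeedProfile", shifts = shifts, subCutoff = shifts < cutoff,
      cutoff = cutoff)
}

#' Extract speed peaks from a profile
#'
#' The relevant peaks are the shifts strictly above `threshold` (default 1,
#' the Exponential range of the Gamma plane: shape 1 marks the memoryless
#' regime, so plane moves larger than 1 are treated as genuine regime
#' shifts rather than estimation jitter).  Sub-cutoff shifts are never
#' peaks.  Order is preserved.
#'
#' @param profile a [SpeedProfile-class].
#' @param threshold peak threshold.
#' @return numeric vector of peak shifts (possibly empty, with a warning).
#' @export
extractPeaks <- function(profile, threshold = 1) {
  stopifnot(is(profile, "SpeedProfile"))
  peaks <- profile@shifts[!profile@subCutoff & profile@shifts > threshold]
  if (!length(peaks))
    warning("no speed peaks above ", threshold,
            "; participant needs more data")
  peaks
}

#' Per-person stochastic signature from speed peaks
#'
#' Fits the Gamma distribution of the person's speed peaks by MLE; the
#' resulting (shape, scale) point is the person's stochastic signature and
#' its scale is the Fano factor.  Max and median shift are computed over
#' the above-cutoff shifts of the full profile.
#'
#' @param participantId participant identifier.
#' @param peaks speed peaks from [extractPeaks()]; at least 10 are needed
#'   for the distributional fit.
#' @param profile the [SpeedProfile-class] the peaks came from.
#' @param nEntries,nDiscarded optional bookkeeping counts carried along.
#' @return a [PersonSignature-class], or NULL (with a warning) when there
#'   are fewer than 10 peaks -- the participant is excluded.
#' @export
personSignature <- function(participantId, peaks, profile,
                            nEntries = NA_integer_,
                            nDiscarded = NA_integer_) {
  stopifnot(is(profile, "SpeedProfile"))
  if (length(peaks) < 10L) {
    warning("participant ", participantId, " has ", length(peaks),
            " peaks (< 10); excluded from the cohort stage")
    return(NULL)
  }
  fit <- fitGammaMLE(peaks)
  moving <- profile@shifts[!profile@subCutoff]
  new("PersonSignature", participantId = participantId, peakFit = fit,
      fano = fanoFactor(fit), maxShift = max(moving),
      medianShift = median(moving), nPeaks = length(peaks),
      nShifts = length(profile@shifts),
      nEntries = as.integer(nEntries),
      nDiscarded = as.integer(nDiscarded))
}

#' Tabulate person signatures
#'
#' @param signatures list of [PersonSignature-class].
#' @return data.frame with one row per person.
#' @export
personTable <- function(signatures) {
  signatures <- Filter(Negate(is.null), signatures)
  do.call(rbind, lapply(signatures, function(s) data.frame(
    participant = s@participantId,
    shape = s@peakFit@shape, scale = s@peakFit@scale,
    shapeLo = s@peakFit@ciShape[1], shapeHi = s@peakFit@ciShape[2],
    scaleLo = s@peakFit@ciScale[1], scaleHi = s@peakFit@ciScale[2],
    fano = s@fano, maxShift = s@maxShift, medianShift = s@medianShift,
    nPeaks = s@nPeaks, nShifts = s@nShifts, nEntries = s@nEntries,
    nDiscarded = s@nDiscarded)))
}
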