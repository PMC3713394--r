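#' Session of accelerometer summary readings
#'
#' One recording session (roughly one hourly data dump) for one participant:
#' time-ordered readings of the 3-component maximal deviation from the mean
#' acceleration, in device units.
#'
#' @slot participantId opaque participant identifier.
#' @slot dayIndex day number, >= 1.
#' @slot sessionIndex session number within the day, >= 1.
#' @slot readings data.frame with columns `t`, `x_maxdev`, `y_maxdev`,
#'   `z_maxdev` (and optionally `x_mean`, `y_mean`, `z_mean`), ordered by
#'   non-decreasing `t`.
#' @slot nDropped number of rows discarded on read because a max-deviation
#'   component was missing or non-numeric.
#' @exportClass Session
setClass("Session",
  representation(participantId = "character", dayIndex = "integer",
                 sessionIndex = "integer", readings = "data.frame",
                 nDropped = "integer"),
  prototype(nDropped = 0L))

setValidity("Session", function(object) {
  r <- object@readings
  need <- c("t", "x_maxdev", "y_maxdev", "z_maxdev")
  if (!all(need %in% names(r)))
    return(paste("readings must have columns", paste(need, collapse = ", ")))
  if (length(object@dayIndex) != 1L || object@dayIndex < 1L)
    return("dayIndex must be a single integer >= 1")
  if (length(object@sessionIndex) != 1L || object@sessionIndex < 1L)
    return("sessionIndex must be a single integer >= 1")
  if (nrow(r)) {
    if (!all(is.finite(as.matrix(r[, need]))))
      return("all reading components must be finite")
    if (any(r$t < 0)) return("timestamps must be non-negative")
    if (is.unsorted(r$t)) return("readings must be ordered by t")
  }
  TRUE
})

#' Ordered magnitude series for one participant
#'
#' Scalar Euclidean magnitudes of the max-deviation vectors, concatenated in
#' acquisition order across sessions and days, with per-value provenance.
#'
#' @slot participantId participant identifier.
#' @slot values non-negative magnitudes, acquisition order.
#' @slot day,session integer provenance tags, one per value.
#' @exportClass MagnitudeSeries
setClass("MagnitudeSeries",
  representation(participantId = "character", values = "numeric",
                 day = "integer", session = "integer"))

setValidity("MagnitudeSeries", function(object) {
  n <- length(object@values)
  if (length(object@day) != n || length(object@session) != n)
    return("provenance tags must have one entry per value")
  if (n && any(object@values < 0)) return("magnitudes must be >= 0")
  TRUE
})

#' Data entry: the basic estimation unit
#'
#' A block of consecutive magnitude readings (default 100) from which one
#' Gamma-plane point is estimated.
#'
#' @slot entryIndex position in acquisition order, >= 1.
#' @slot samples non-negative magnitudes.
#' @slot participantId,day,session provenance (day/session of the block's
#'   first reading).
#' @exportClass DataEntry
setClass("DataEntry",
  representation(entryIndex = "integer", samples = "numeric",
                 participantId = "character", day = "integer",
                 session = "integer"))

setValidity("DataEntry", function(object) {
  if (object@entryIndex < 1L) return("entryIndex must be >= 1")
  if (!all(is.finite(object@samples)) || any(object@samples < 0))
    return("samples must be finite and >= 0")
  TRUE
})

#' Gamma maximum-likelihood estimate for one data entry
#'
#' Fitted (shape, scale) with 95% confidence intervals, for a data entry or
#' for a person's speed-peak distribution.  The mean is shape*scale, the
#' variance shape*scale^2, so the Fano factor (variance/mean) equals the
#' scale exactly.
#'
#' @slot shape,scale positive Gamma parameters.
#' @slot ciShape,ciScale length-2 numeric, 95% Wald intervals (log scale,
#'   exponentiated back).
#' @slot n number of samples behind the fit.
#' @slot dipP dip-test p-value for the entry (NA when not screened).
#' @exportClass GammaEstimate
setClass("GammaEstimate",
  representation(shape = "numeric", scale = "numeric", ciShape = "numeric",
                 ciScale = "numeric", n = "integer", dipP = "numeric"),
  prototype(dipP = NA_real_))

setValidity("GammaEstimate", function(object) {
  if (object@shape <= 0 || object@scale <= 0)
    return("shape and scale must be positive")
  if (length(object@ciShape) != 2L || length(object@ciScale) != 2L)
    return("confidence intervals must have two bounds")
  if (object@ciShape[1] > object@shape || object@ciShape[2] < object@shape)
    return("ciShape must bracket the shape estimate")
  if (object@ciScale[1] > object@scale || object@ciScale[2] < object@scale)
    return("ciScale must bracket the scale estimate")
  if (!is.na(object@dipP) && (object@dipP < 0 || object@dipP > 1))
    return("dipP must be in [0, 1]")
  TRUE
})

#' Stochastic trajectory on the Gamma plane
#'
#' Acquisition-ordered (shape, scale) points for one participant, pieced
#' together across sessions and days.
#'
#' @slot participantId participant identifier.
#' @slot points data.frame with columns `entry`, `shape`, `scale`, `day`,
#'   `session`, in acquisition order.
#' @exportClass StochasticTrajectory
setClass("StochasticTrajectory",
  representation(participantId = "character", points = "data.frame"))

setValidity("StochasticTrajectory", function(object) {
  p <- object@points
  if (!all(c("entry", "shape", "scale", "day") %in% names(p)))
    return("points needs columns entry, shape, scale, day")
  if (nrow(p) < 2L) return("a trajectory needs at least 2 points")
  if (is.unsorted(p$entry, strictly = TRUE))
    return("points must be in strictly increasing entry order")
  TRUE
})

#' Speed profile of a stochastic trajectory
#'
#' Euclidean shift magnitudes between consecutive Gamma-plane points; shifts
#' below the stochastic-motion cutoff are flagged as rest and excluded from
#' peak statistics.
#'
#' @slot shifts non-negative shift magnitudes, one per consecutive pair.
#' @slot subCutoff logical flags, TRUE where the shift is below `cutoff`.
#' @slot cutoff the stochastic-motion cutoff used (default 0.002).
#' @exportClass SpeedProfile
setClass("SpeedProfile",
  representation(shifts = "numeric", subCutoff = "logical",
                 cutoff = "numeric"))

setValidity("SpeedProfile", function(object) {
  if (length(object@subCutoff) != length(object@shifts))
    return("one sub-cutoff flag per shift required")
  if (length(object@shifts) && any(object@shifts < 0))
    return("shifts must be >= 0")
  TRUE
})

#' Per-person stochastic signature
#'
#' Gamma fit of the person's speed peaks (shifts > threshold along the full
#' longitudinal trajectory), its Fano factor, and summary shift statistics.
#'
#' @slot participantId participant identifier.
#' @slot peakFit [GammaEstimate-class] over the speed peaks.
#' @slot fano variance/mean of the peak fit; equals its scale.
#' @slot maxShift,medianShift maximum and median of the above-cutoff shifts.
#' @slot nPeaks,nShifts,nEntries,nDiscarded bookkeeping counts.
#' @exportClass PersonSignature
setClass("PersonSignature",
  representation(participantId = "character", peakFit = "GammaEstimate",
                 fano = "numeric", maxShift = "numeric",
                 medianShift = "numeric", nPeaks = "integer",
                 nShifts = "integer", nEntries = "integer",
                 nDiscarded = "integer"),
  prototype(nEntries = NA_integer_, nDiscarded = NA_integer_))

setValidity("PersonSignature", function(object) {
  if (!isTRUE(all.equal(object@fano, object@peakFit@scale)))
    return("fano must equal the scale of the peak fit")
  if (object@nPeaks > object@nShifts)
    return("cannot have more peaks than shifts")
  TRUE
})

#' Labelled cohort scatter of per-person signatures
#'
#' One row per participant: signature point (shape, scale), NC/PD label,
#' age, Fano factor, and maximal shift, as used by all cohort statistics.
#'
#' @slot data data.frame with columns `participant`, `label` ("NC"/"PD"),
#'   `age`, `shape`, `scale`, `fano`, `maxShift` (and optionally
#'   `yearsSinceDiagnosis`, `minShift`).
#' @exportClass CohortScatter
setClass("CohortScatter", representation(data = "data.frame"))

setValidity("CohortScatter", function(object) {
  d <- object@data
  need <- c("participant", "label", "age", "shape", "scale", "fano",
            "maxShift")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (!all(d$label %in% c("NC", "PD"))) return("labels must be NC or PD")
  if (any(d$shape <= 0 | d$scale <= 0))
    return("signature points must be strictly positive")
  if (anyDuplicated(d$participant)) return("duplicated participant ids")
  TRUE
})

#' Synthetic participant specification
#'
#' Generative parameters for one synthetic participant: a reflected random
#' walk on (log shape, log scale) with occasional multiplicative regime
#' jumps and occasional bimodal contamination of an entry.
#'
#' @slot personaId identifier.
#' @slot label cohort label, "NC" or "PD".
#' @slot age age in years (cohort metadata).
#' @slot a0,b0 baseline shape and scale, > 0.
#' @slot driftSd per-entry s.d. of the random-walk step on the log
#'   parameters.
#' @slot jumpProb per-entry probability of a regime jump.
#' @slot jumpScale multiplicative jump magnitude; jump factors are drawn
#'   log-uniformly between 1/jumpScale and jumpScale.
#' @slot contaminationProb per-entry probability of bimodal contamination.
#' @slot days,sessionsPerDay,readingsPerSession stream layout;
#'   readingsPerSession >= 100.
#' @slot seed integer RNG seed for this persona.
#' @exportClass Persona
setClass("Persona",
  representation(personaId = "character", label = "character",
                 age = "numeric", a0 = "numeric", b0 = "numeric",
                 driftSd = "numeric", jumpProb = "numeric",
                 jumpScale = "numeric", contaminationProb = "numeric",
                 days = "integer", sessionsPerDay = "integer",
                 readingsPerSession = "integer", seed = "integer"))

setValidity("Persona", function(object) {
  if (object@a0 <= 0 || object@b0 <= 0 || object@jumpScale <= 0)
    return("a0, b0 and jumpScale must be positive")
  probs <- c(object@jumpProb, object@contaminationProb)
  if (any(probs < 0 | probs > 1)) return("probabilities must be in [0, 1]")
  if (object@driftSd < 0) return("driftSd must be >= 0")
  if (object@readingsPerSession < 100L)
    return("readingsPerSession must be >= 100")
  if (object@days < 1L || object@sessionsPerDay < 1L)
    return("days and sessionsPerDay must be >= 1")
  if (!object@label %in% c("NC", "PD")) return("label must be NC or PD")
  TRUE
})

#' Power-law fit y = a * x^b
#'
#' Nonlinear least-squares fit on the original scale, with goodness-of-fit
#' statistics and t-based 95% confidence bounds.
#'
#' @slot coefficient,exponent fitted a and b.
#' @slot ciCoefficient,ciExponent 95% confidence bounds.
#' @slot sse,r2,adjR2,rmse goodness of fit on the original y scale.
#' @slot n number of points.
#' @exportClass PowerFit
setClass("PowerFit",
  representation(coefficient = "numeric", exponent = "numeric",
                 ciCoefficient = "numeric", ciExponent = "numeric",
                 sse = "numeric", r2 = "numeric", adjR2 = "numeric",
                 rmse = "numeric", n = "integer"))

setValidity("PowerFit", function(object) {
  if (object@sse < 0) return("SSE must be >= 0")
  if (!is.na(object@r2) && object@r2 > 1 + 1e-12)
    return("R2 cannot exceed 1")
  TRUE
})

#' Ordinary least-squares line fit y = p1 * x + p2
#'
#' @slot slope,intercept fitted coefficients.
#' @slot ciSlope,ciIntercept 95% confidence bounds.
#' @slot sse,r2,adjR2,rmse goodness of fit.
#' @slot n number of points.
#' @exportClass LinearFit
setClass("LinearFit",
  representation(slope = "numeric", intercept = "numeric",
                 ciSlope = "numeric", ciIntercept = "numeric",
                 sse = "numeric", r2 = "numeric", adjR2 = "numeric",
                 rmse = "numeric", n = "integer"))

setValidity("LinearFit", function(object) {
  if (object@sse < 0) return("SSE must be >= 0")
  TRUE
})

#' k-medians clustering result (city-block metric)
#'
#' @slot assignments cluster index per point.
#' @slot centroids k x d matrix of component-wise medians.
#' @slot cost total within-cluster L1 cost.
#' @slot costTrace per-iteration cost of the winning restart
#'   (non-increasing).
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(assignments = "integer", centroids = "matrix",
                 cost = "numeric", costTrace = "numeric"))

setValidity("ClusterResult", function(object) {
  k <- nrow(object@centroids)
  if (any(object@assignments < 1L | object@assignments > k))
    return("assignments out of range")
  if (length(object@costTrace) &&
      any(diff(object@costTrace) > 1e-8))
    return("cost must be non-increasing over iterations")
  TRUE
})
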