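#' @name accessors
#' @title Accessors for stochsig classes
#'
#' @description Small accessor generics: `participantId()`, `shapeParam()`,
#' `scaleParam()`, `magnitudes()`, `trajectoryPoints()`, `shiftValues()`,
#' `fanoFactor()`, `estMean()`, `estVariance()`, `scatterData()`.
#'
#' @param object an object of the appropriate stochsig class.
#' @return the slot value; see individual methods.
NULL

#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))

#' @rdname accessors
#' @export
setGeneric("shapeParam", function(object) standardGeneric("shapeParam"))

#' @rdname accessors
#' @export
setGeneric("scaleParam", function(object) standardGeneric("scaleParam"))

#' @rdname accessors
#' @export
setGeneric("magnitudes", function(object) standardGeneric("magnitudes"))

#' @rdname accessors
#' @export
setGeneric("trajectoryPoints",
           function(object) standardGeneric("trajectoryPoints"))

#' @rdname accessors
#' @export
setGeneric("shiftValues", function(object) standardGeneric("shiftValues"))

#' Fano factor (variance-to-mean ratio)
#'
#' For a Gamma(shape, scale) distribution the variance-to-mean ratio is
#' (shape * scale^2) / (shape * scale) = scale, so the Fano factor of a
#' [GammaEstimate-class] is its scale parameter exactly.  High values flag
#' noisy, unreliable signatures; the Exponential regime sits at shape 1.
#'
#' @param object a [GammaEstimate-class] or [PersonSignature-class].
#' @return positive scalar, the variance/mean ratio.
#' @examples
#' est <- gammaEstimate(shape = 0.7476, scale = 13.4048, n = 100L)
#' fanoFactor(est)  # 13.4048, the scale itself
#' @export
setGeneric("fanoFactor", function(object) standardGeneric("fanoFactor"))

#' @rdname accessors
#' @export
setGeneric("estMean", function(object) standardGeneric("estMean"))

#' @rdname accessors
#' @export
setGeneric("estVariance", function(object) standardGeneric("estVariance"))

#' @rdname accessors
#' @export
setGeneric("scatterData", function(object) standardGeneric("scatterData"))

setMethod("participantId", "Session", function(object) object@participantId)
setMethod("participantId", "MagnitudeSeries",
          function(object) object@participantId)
setMethod("participantId", "StochasticTrajectory",
          function(object) object@participantId)
setMethod("participantId", "PersonSignature",
          function(object) object@participantId)

setMethod("shapeParam", "GammaEstimate", function(object) object@shape)
setMethod("scaleParam", "GammaEstimate", function(object) object@scale)
setMethod("shapeParam", "PersonSignature",
          function(object) object@peakFit@shape)
setMethod("scaleParam", "PersonSignature",
          function(object) object@peakFit@scale)

setMethod("magnitudes", "MagnitudeSeries", function(object) object@values)
setMethod("magnitudes", "DataEntry", function(object) object@samples)

setMethod("trajectoryPoints", "StochasticTrajectory",
          function(object) object@points)

setMethod("shiftValues", "SpeedProfile", function(object) object@shifts)

setMethod("fanoFactor", "GammaEstimate", function(object) object@scale)
setMethod("fanoFactor", "PersonSignature", function(object) object@fano)

setMethod("estMean", "GammaEstimate",
          function(object) object@shape * object@scale)
setMethod("estVariance", "GammaEstimate",
          function(object) object@shape * object@scale^2)

setMethod("scatterData", "CohortScatter", function(object) object@data)

setMethod("length", "MagnitudeSeries", function(x) length(x@values))

setMethod("show", "GammaEstimate", function(object) {
  cat(sprintf(
    "GammaEstimate: shape %.4f [%.4f, %.4f], scale %.4f [%.4f, %.4f]\n",
    object@shape, object@ciShape[1], object@ciShape[2],
    object@scale, object@ciScale[1], object@ciScale[2]))
  cat(sprintf("  n = %d, Fano = %.4f, dip p = %s\n", object@n, object@scale,
              ifelse(is.na(object@dipP), "not screened",
                     format(object@dipP, digits = 3))))
})

setMethod("show", "MagnitudeSeries", function(object) {
  cat(sprintf("MagnitudeSeries for %s: %d readings over %d day(s)\n",
              object@participantId, length(object@values),
              length(unique(object@day))))
})

setMethod("show", "StochasticTrajectory", function(object) {
  cat(sprintf("StochasticTrajectory for %s: %d Gamma-plane points, %d day(s)\n",
              object@participantId, nrow(object@points),
              length(unique(object@points$day))))
})

setMethod("show", "SpeedProfile", function(object) {
  cat(sprintf("SpeedProfile: %d shifts (%d below cutoff %.3g)\n",
              length(object@shifts), sum(object@subCutoff), object@cutoff))
})

setMethod("show", "PersonSignature", function(object) {
  cat(sprintf(
    "PersonSignature for %s: peaks Gamma(%.4f, %.4f), Fano %.4f\n",
    object@participantId, object@peakFit@shape, object@peakFit@scale,
    object@fano))
  cat(sprintf("  %d peaks / %d shifts, max shift %.4f, median shift %.4f\n",
              object@nPeaks, object@nShifts, object@maxShift,
              object@medianShift))
})

setMethod("show", "CohortScatter", function(object) {
  tab <- table(object@data$label)
  cat(sprintf("CohortScatter: %d participants (%s)\n", nrow(object@data),
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
})

setMethod("show", "PowerFit", function(object) {
  cat(sprintf(
    "PowerFit y = a*x^b: a = %.4f (%.4f, %.4f), b = %.4f (%.4f, %.4f)\n",
    object@coefficient, object@ciCoefficient[1], object@ciCoefficient[2],
    object@exponent, object@ciExponent[1], object@ciExponent[2]))
  cat(sprintf("  SSE %.4f, R2 %.4f, adj R2 %.4f, RMSE %.4f (n = %d)\n",
              object@sse, object@r2, object@adjR2, object@rmse, object@n))
})

setMethod("show", "LinearFit", function(object) {
  cat(sprintf(
    "LinearFit y = p1*x + p2: p1 = %.4f (%.4f, %.4f), p2 = %.4f (%.4f, %.4f)\n",
    object@slope, object@ciSlope[1], object@ciSlope[2],
    object@intercept, object@ciIntercept[1], object@ciIntercept[2]))
  cat(sprintf("  SSE %.4f, R2 %.4f, adj R2 %.4f, RMSE %.4f (n = %d)\n",
              object@sse, object@r2, object@adjR2, object@rmse, object@n))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d, total L1 cost %.4f\n",
              nrow(object@centroids), object@cost))
  print(object@centroids)
})

setMethod("show", "Persona", function(object) {
  cat(sprintf(
    "Persona %s (%s, age %g): Gamma(%.3f, %.3f), drift %.3f, jumps p=%.3f x%g\n",
    object@personaId, object@label, object@age, object@a0, object@b0,
    object@driftSd, object@jumpProb, object@jumpScale))
})
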