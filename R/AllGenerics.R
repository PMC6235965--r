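#' Accessors and generics
#'
#' Accessor generics for the package's S4 containers. These are preferred over
#' direct slot access.
#'
#' @param object An object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("throughput", function(object) standardGeneric("throughput"))

#' @rdname accessors
#' @export
setGeneric("loadedEvents", function(object) standardGeneric("loadedEvents"))

#' @rdname accessors
#' @export
setGeneric("rejectedEvents",
           function(object) standardGeneric("rejectedEvents"))

#' @rdname accessors
#' @export
setGeneric("interLoadIntervals",
           function(object) standardGeneric("interLoadIntervals"))

#' @rdname accessors
#' @export
setGeneric("eventLog", function(object) standardGeneric("eventLog"))

#' @rdname accessors
#' @export
setGeneric("overshootCount",
           function(object) standardGeneric("overshootCount"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("sensorId", function(object) standardGeneric("sensorId"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("stateName", function(object) standardGeneric("stateName"))

#' @rdname accessors
#' @export
setGeneric("trajectoryPoints",
           function(object) standardGeneric("trajectoryPoints"))

#' Mass accumulation rate
#'
#' Least-squares slope of buoyant mass against time for one cell trajectory,
#' in pg/h.
#'
#' @param object A [CellTrajectory()] (>= 2 points).
#' @return Numeric slope in pg/h.
#' @export
setGeneric("mar", function(object) standardGeneric("mar"))

#' Mass-normalized mass accumulation rate
#'
#' [mar()] divided by the trajectory's first-point buoyant mass, in 1/h.
#'
#' @param object A [CellTrajectory()].
#' @return Numeric rate in 1/h.
#' @export
setGeneric("marPerMass", function(object) standardGeneric("marPerMass"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("throughput", "SimResult", function(object) object@throughput)
#' @rdname accessors
setMethod("loadedEvents", "SimResult", function(object) object@loadedEvents)
#' @rdname accessors
setMethod("rejectedEvents", "SimResult",
          function(object) object@rejectedEvents)
#' @rdname accessors
setMethod("interLoadIntervals", "SimResult",
          function(object) object@interLoadIntervals)
#' @rdname accessors
setMethod("eventLog", "SimResult", function(object) object@eventLog)
#' @rdname accessors
setMethod("overshootCount", "SimResult",
          function(object) object@overshootCount)
#' @rdname accessors
setMethod("sampleRate", "ResonanceTrace", function(object) object@sampleRate)
#' @rdname accessors
setMethod("traceValues", "ResonanceTrace", function(object) object@values)
#' @rdname accessors
setMethod("sensorId", "ResonanceTrace", function(object) object@sensorId)
#' @rdname accessors
setMethod("pixels", "Frame", function(object) object@pixels)
#' @rdname accessors
setMethod("stateName", "ControllerState", function(object) object@state)
#' @rdname accessors
setMethod("trajectoryPoints", "CellTrajectory",
          function(object) object@points)

## ---- show ----------------------------------------------------------------

setMethod("show", "ControllerState", function(object) {
    cat("ControllerState:", object@state,
        if (object@awaitingVerdict) "(awaiting ROI 3 verdict)" else "", "\n")
})

setMethod("show", "FlowCommand", function(object) {
    cat(sprintf("FlowCommand: sampling %+.4g nL/s, measurement %+.4g nL/s\n",
                object@sampling, object@measurement))
})

setMethod("show", "ControllerPolicy", function(object) {
    cat("ControllerPolicy\n",
        sprintf("  duty cycle        : %g s\n", object@dutyCycle),
        sprintf("  area window       : [%g, %g] px^2\n",
                object@areaMin, object@areaMax),
        sprintf("  x-y ratio max     : %g\n", object@xyRatioMax),
        sprintf("  min contrast      : %s\n",
                if (object@minContrast > 0) format(object@minContrast)
                else "disabled"),
        sprintf("  queue/reject flush: %g / %g s\n",
                object@queueFlushDuration, object@rejectFlushDuration),
        sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n",
        sprintf("  concentration   : %g particles/uL\n", object@concentration),
        sprintf("  measurement flow: %g uL/s (transit %g s)\n",
                object@measurementFlow, object@transitTime),
        sprintf("  seek flow       : %g x, camera %g fps\n",
                object@seekFlowMultiplier, object@cameraFps),
        sprintf("  duty cycle      : %g s, match window %g s\n",
                object@dutyCycle, object@matchWindow),
        sprintf("  duration        : %g s, seed %g\n",
                object@duration, object@seed),
        sprintf("  debris/doublets : %g / %g\n",
                object@debrisFraction, object@doubletFraction),
        sep = "")
})

setMethod("show", "SimResult", function(object) {
    cat(sprintf("SimResult (%s loading)\n", object@mode),
        sprintf("  loaded   : %d events (%.3g per h)\n",
                nrow(object@loadedEvents), object@throughput),
        sprintf("  rejected : %d, overshoots: %d, still in channel: %d\n",
                nrow(object@rejectedEvents), object@overshootCount,
                object@nRemaining),
        sprintf("  duration : %g s\n", object@duration),
        sep = "")
})

setMethod("show", "ResonanceTrace", function(object) {
    cat(sprintf(
        "ResonanceTrace: sensor %d, %d samples at %g Hz (%.3g s)\n",
        object@sensorId, length(object@values), object@sampleRate,
        length(object@values) / object@sampleRate))
})

setMethod("show", "FilterSettings", function(object) {
    cat("FilterSettings\n",
        sprintf("  Savitzky-Golay : window %d, order %d\n",
                object@sgWindow, object@sgOrder),
        sprintf("  baseline window: %d samples\n", object@baselineWindow),
        sprintf("  median length  : %d samples\n", object@medianLength),
        sprintf("  threshold      : %g Hz\n", object@threshold),
        sep = "")
})

setMethod("show", "Frame", function(object) {
    cat(sprintf("Frame: %d x %d px at %g um/px, t = %g s\n",
                ncol(object@pixels), nrow(object@pixels), object@pixelPitch,
                object@timestamp))
})

setMethod("show", "CellTrajectory", function(object) {
    cat(sprintf("CellTrajectory %d: %d points", object@cellId,
                nrow(object@points)))
    if (nrow(object@points) >= 2)
        cat(sprintf(", mass %.3g pg, MAR %.3g pg/h", firstMass(object),
                    mar(object)))
    cat("\n")
})

setMethod("show", "BoxSummary", function(object) {
    cat(sprintf(
        "BoxSummary: median %.4g [Q1 %.4g, Q3 %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
        object@median, object@q1, object@q3, object@whiskerLow,
        object@whiskerHigh, length(object@outliers)))
})
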