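#' @import methods
#' @importFrom stats rnorm rexp rlnorm runif median quantile coef lm sd
#' @importFrom utils packageVersion read.delim write.table head tail
#' @importFrom graphics legend
NULL

.FLUIDIC_STATES <- c("LOAD", "SEEK", "QUEUE", "REJECT")

#' The four fluidic states
#'
#' Names of the fluidic states of the active-loading controller. `LOAD` is the
#' baseline state (sampling inflow equals measurement-channel flow, so entry is
#' governed by Poisson statistics, as in passive loading); `SEEK` scans the
#' sampling channel at a high flow rate to find the next particle; `QUEUE`
#' briefly flushes a waiting particle upstream so that no more than one
#' particle is admitted per duty cycle; `REJECT` briefly reverses the
#' measurement-channel flow to expel an unwanted particle.
#'
#' @return Character vector of the four state names.
#' @examples
#' fluidicStates()
#' @export
fluidicStates <- function() .FLUIDIC_STATES

## ---------------------------------------------------------------------------
## ControllerPolicy
## ---------------------------------------------------------------------------

#' @rdname ControllerPolicy
#' @export
setClass("ControllerPolicy",
    representation(
        dutyCycle = "numeric",
        areaMin = "numeric",
        areaMax = "numeric",
        xyRatioMax = "numeric",
        minContrast = "numeric",
        queueFlushDuration = "numeric",
        rejectFlushDuration = "numeric"
    )
)

setValidity("ControllerPolicy", function(object) {
    msg <- character()
    if (length(object@dutyCycle) != 1L || !is.finite(object@dutyCycle) ||
        object@dutyCycle <= 0)
        msg <- c(msg, "'dutyCycle' must be a single positive number (seconds)")
    if (!(object@areaMin < object@areaMax))
        msg <- c(msg, "'areaMin' must be smaller than 'areaMax'")
    if (object@areaMin <= 0)
        msg <- c(msg, "'areaMin' must be positive")
    if (object@xyRatioMax < 1)
        msg <- c(msg, "'xyRatioMax' must be >= 1")
    if (object@minContrast < 0)
        msg <- c(msg, "'minContrast' must be >= 0 (0 disables the bound)")
    if (object@queueFlushDuration <= 0 || object@rejectFlushDuration <= 0)
        msg <- c(msg, "flush durations must be positive")
    if (length(msg)) msg else TRUE
})

#' Controller policy: duty cycle and geometric acceptance bounds
#'
#' Bundles the user-set parameters of the active-loading controller: the
#' loading duty cycle (minimum spacing between accepted loads, set to match
#' the downstream measurement's required inter-cell spacing), the inclusive
#' cross-sectional area window and maximum x-y ratio that a particle imaged at
#' ROI 3 must satisfy to be accepted, an optional minimum mean-contrast bound
#' (disabled at 0), and the dwell times of the transient QUEUE and REJECT
#' flush states.
#'
#' @param dutyCycle Loading duty cycle in seconds (> 0). Default 15 s, the
#'   spacing used for serial SMR growth measurements.
#' @param areaMin,areaMax Inclusive bounds on particle cross-sectional area in
#'   pixel^2.
#' @param xyRatioMax Maximum bounding-box x-y ratio (max/min extent, >= 1).
#' @param minContrast Minimum mean contrast (intensity delta) for acceptance;
#'   0 disables the contrast criterion.
#' @param queueFlushDuration,rejectFlushDuration Dwell time in seconds of one
#'   QUEUE (upstream flush) or REJECT (reversed measurement flow) excursion.
#' @return A `ControllerPolicy` object.
#' @examples
#' ControllerPolicy(dutyCycle = 9)
#' @export
ControllerPolicy <- function(dutyCycle = 15, areaMin = 60, areaMax = 300,
                             xyRatioMax = 1.5, minContrast = 0,
                             queueFlushDuration = 0.5,
                             rejectFlushDuration = 0.5) {
    new("ControllerPolicy", dutyCycle = dutyCycle, areaMin = areaMin,
        areaMax = areaMax, xyRatioMax = xyRatioMax, minContrast = minContrast,
        queueFlushDuration = queueFlushDuration,
        rejectFlushDuration = rejectFlushDuration)
}

## ---------------------------------------------------------------------------
## ControllerState & FlowCommand
## ---------------------------------------------------------------------------

#' @rdname ControllerState
#' @export
setClass("ControllerState",
    representation(state = "character", awaitingVerdict = "logical"))

setValidity("ControllerState", function(object) {
    msg <- character()
    if (length(object@state) != 1L || !(object@state %in% .FLUIDIC_STATES))
        msg <- c(msg, sprintf("'state' must be one of %s",
                              paste(.FLUIDIC_STATES, collapse = ", ")))
    if (length(object@awaitingVerdict) != 1L || is.na(object@awaitingVerdict))
        msg <- c(msg, "'awaitingVerdict' must be TRUE or FALSE")
    if (isTRUE(object@awaitingVerdict) &&
        length(object@state) == 1L && object@state != "LOAD")
        msg <- c(msg, "a verdict can only be pending in the LOAD state")
    if (length(msg)) msg else TRUE
})

#' Controller state
#'
#' The full state of the loading controller: which of the four fluidic states
#' is active, plus whether an ROI 3 verdict is pending (set between the ROI 4
#' entry event and the immediately following ROI 3 geometry event).
#'
#' @param state One of `fluidicStates()`. The system powers up in `LOAD`, the
#'   unique default state.
#' @param awaitingVerdict Logical; `TRUE` only between an ROI 4 event and its
#'   paired ROI 3 event.
#' @return A `ControllerState` object.
#' @examples
#' ControllerState("SEEK")
#' @export
ControllerState <- function(state = "LOAD", awaitingVerdict = FALSE) {
    new("ControllerState", state = state, awaitingVerdict = awaitingVerdict)
}

#' @rdname FlowCommand
#' @export
setClass("FlowCommand",
    representation(sampling = "numeric", measurement = "numeric"))

setValidity("FlowCommand", function(object) {
    if (length(object@sampling) != 1L || length(object@measurement) != 1L ||
        !all(is.finite(c(object@sampling, object@measurement))))
        "'sampling' and 'measurement' must be single finite numbers (nL/s)"
    else TRUE
})

#' Signed channel flow command
#'
#' Volumetric flow rates commanded in each channel, in nL/s. Positive sampling
#' flow points toward the downstream sampling port; positive measurement flow
#' points into the measurement channel.
#'
#' @param sampling,measurement Signed volumetric rates in nL/s.
#' @return A `FlowCommand` object.
#' @examples
#' FlowCommand(sampling = 0.05, measurement = 0.05)
#' @export
FlowCommand <- function(sampling, measurement) {
    new("FlowCommand", sampling = sampling, measurement = measurement)
}

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' @rdname SimulationConfig
#' @export
setClass("SimulationConfig",
    representation(
        concentration = "numeric",       # particles / uL
        measurementFlow = "numeric",     # uL / s
        seekFlowMultiplier = "numeric",
        dutyCycle = "numeric",           # s
        cameraFps = "numeric",
        pneumaticLatency = "numeric",    # s (mean)
        latencyModel = "character",      # deterministic | lognormal
        latencySdlog = "numeric",
        transitTime = "numeric",         # s
        matchWindow = "numeric",         # s
        duration = "numeric",            # s
        seed = "numeric",
        debrisFraction = "numeric",
        doubletFraction = "numeric",
        samplingChannelArea = "numeric"  # um^2
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    pos <- c(measurementFlow = object@measurementFlow,
             dutyCycle = object@dutyCycle, cameraFps = object@cameraFps,
             transitTime = object@transitTime,
             matchWindow = object@matchWindow, duration = object@duration,
             samplingChannelArea = object@samplingChannelArea)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
        msg <- c(msg, sprintf("positive values required for: %s",
                              paste(bad, collapse = ", ")))
    if (object@concentration < 0)
        msg <- c(msg, "'concentration' must be >= 0")
    if (object@seekFlowMultiplier < 1)
        msg <- c(msg, "'seekFlowMultiplier' must be >= 1")
    if (object@pneumaticLatency < 0)
        msg <- c(msg, "'pneumaticLatency' must be >= 0")
    if (!(object@latencyModel %in% c("deterministic", "lognormal")))
        msg <- c(msg, "'latencyModel' must be 'deterministic' or 'lognormal'")
    fr <- c(object@debrisFraction, object@doubletFraction)
    if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
        msg <- c(msg,
            "'debrisFraction' + 'doubletFraction' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Simulator configuration
#'
#' All parameters of the event-driven two-channel device simulator. The
#' default measurement flow of 5e-5 uL/s follows from the measurement-channel
#' cross-section (20 um x 25 um) and an 80 um detector region crossed in the
#' target transit time of 0.8 s. The sampling channel (100 um x 30 um) sets
#' the seek-state particle velocity, and with it the overshoot distance caused
#' by pneumatic latency.
#'
#' @param concentration Sample concentration in particles/uL.
#' @param measurementFlow Measurement-channel volumetric flow, uL/s.
#' @param seekFlowMultiplier Seek-state sampling flow as a multiple (>= 1) of
#'   the measurement flow.
#' @param dutyCycle Loading duty cycle in seconds.
#' @param cameraFps Camera frame rate; ROI events are only visible on the
#'   1/`cameraFps` time grid.
#' @param pneumaticLatency Mean pneumatic response time, seconds.
#' @param latencyModel `"deterministic"` (every response takes exactly
#'   `pneumaticLatency`) or `"lognormal"` (lognormal with that mean).
#' @param latencySdlog Log-sd of the lognormal latency model.
#' @param transitTime Target detector transit time, seconds.
#' @param matchWindow Passive matching window: minimum gap to the previous
#'   entry for a successful measurement, seconds.
#' @param duration Simulated duration, seconds.
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   event logs.
#' @param debrisFraction,doubletFraction Probability that a generated particle
#'   is debris or a doublet (remainder are single cells).
#' @param samplingChannelArea Sampling-channel cross-section, um^2.
#' @return A `SimulationConfig` object.
#' @examples
#' cfg <- SimulationConfig(concentration = 50, duration = 3600)
#' seekFlow(cfg)
#' @export
SimulationConfig <- function(concentration = 50, measurementFlow = 5e-5,
                             seekFlowMultiplier = 20, dutyCycle = 15,
                             cameraFps = 60, pneumaticLatency = 0.05,
                             latencyModel = "deterministic",
                             latencySdlog = 0.25, transitTime = 0.8,
                             matchWindow = 0.8, duration = 3600, seed = 1,
                             debrisFraction = 0, doubletFraction = 0,
                             samplingChannelArea = 3000) {
    new("SimulationConfig", concentration = concentration,
        measurementFlow = measurementFlow,
        seekFlowMultiplier = seekFlowMultiplier, dutyCycle = dutyCycle,
        cameraFps = cameraFps, pneumaticLatency = pneumaticLatency,
        latencyModel = latencyModel, latencySdlog = latencySdlog,
        transitTime = transitTime, matchWindow = matchWindow,
        duration = duration, seed = seed, debrisFraction = debrisFraction,
        doubletFraction = doubletFraction,
        samplingChannelArea = samplingChannelArea)
}

## ---------------------------------------------------------------------------
## SimResult
## ---------------------------------------------------------------------------

#' @rdname SimResult
#' @export
setClass("SimResult",
    representation(
        mode = "character",
        loadedEvents = "data.frame",
        rejectedEvents = "data.frame",
        overshootCount = "integer",
        throughput = "numeric",          # events / h
        interLoadIntervals = "numeric",  # s
        eventLog = "data.frame",
        duration = "numeric",
        nGenerated = "integer",
        nRemaining = "integer",
        config = "SimulationConfig"
    )
)

setValidity("SimResult", function(object) {
    msg <- character()
    if (!(object@mode %in% c("passive", "active")))
        msg <- c(msg, "'mode' must be 'passive' or 'active'")
    expThr <- 3600 * nrow(object@loadedEvents) / object@duration
    if (!isTRUE(all.equal(object@throughput, expThr)))
        msg <- c(msg, "throughput must equal 3600 * nLoaded / duration")
    if (object@nGenerated < nrow(object@loadedEvents) +
        nrow(object@rejectedEvents))
        msg <- c(msg, "more events than generated particles")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ThroughputParams
## ---------------------------------------------------------------------------

#' @rdname ThroughputParams
#' @export
setClass("ThroughputParams",
    representation(
        measurementFlow = "numeric",   # uL/s
        matchWindow = "numeric",       # s
        dutyCycle = "numeric",         # s
        seekFlowMultiplier = "numeric",
        cameraFps = "numeric",
        overshootPenalty = "numeric"   # s, mean recovery time per load
    )
)

setValidity("ThroughputParams", function(object) {
    v <- c(object@measurementFlow, object@matchWindow, object@dutyCycle,
           object@cameraFps)
    msg <- character()
    if (any(!is.finite(v)) || any(v <= 0))
        msg <- c(msg, "flow, windows and frame rate must be positive")
    if (object@seekFlowMultiplier < 1)
        msg <- c(msg, "'seekFlowMultiplier' must be >= 1")
    if (object@overshootPenalty < 0)
        msg <- c(msg, "'overshootPenalty' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Closed-form throughput model parameters
#'
#' Parameters of the concentration-dependent throughput model. Passive
#' throughput depends on the measurement flow and the matching window;
#' active throughput depends on the duty cycle, the seek flow (multiplier
#' times measurement flow), the camera frame rate (frame-quantization delay)
#' and the mean overshoot-recovery penalty per load.
#'
#' @param measurementFlow Measurement-channel flow, uL/s.
#' @param matchWindow Passive matching window, seconds.
#' @param dutyCycle Active loading duty cycle, seconds.
#' @param seekFlowMultiplier Seek flow as a multiple of measurement flow.
#' @param cameraFps Camera frame rate, frames/s.
#' @param overshootPenalty Mean recovery time per load caused by pneumatic
#'   latency, seconds (2 x 50 ms latency by default).
#' @return A `ThroughputParams` object.
#' @examples
#' ThroughputParams()
#' @export
ThroughputParams <- function(measurementFlow = 5e-5, matchWindow = 0.8,
                             dutyCycle = 15, seekFlowMultiplier = 20,
                             cameraFps = 60, overshootPenalty = 0.1) {
    new("ThroughputParams", measurementFlow = measurementFlow,
        matchWindow = matchWindow, dutyCycle = dutyCycle,
        seekFlowMultiplier = seekFlowMultiplier, cameraFps = cameraFps,
        overshootPenalty = overshootPenalty)
}

#' Derive throughput-model parameters from a simulator configuration
#'
#' @param config A [SimulationConfig()].
#' @return A [ThroughputParams()] with matching parameters, including the
#'   overshoot penalty implied by the configured pneumatic latency.
#' @examples
#' throughputParams(SimulationConfig(dutyCycle = 9))
#' @export
throughputParams <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    ThroughputParams(measurementFlow = config@measurementFlow,
                     matchWindow = config@matchWindow,
                     dutyCycle = config@dutyCycle,
                     seekFlowMultiplier = config@seekFlowMultiplier,
                     cameraFps = config@cameraFps,
                     overshootPenalty = 2 * config@pneumaticLatency)
}

## ---------------------------------------------------------------------------
## ResonanceTrace & FilterSettings
## ---------------------------------------------------------------------------

#' @rdname ResonanceTrace
#' @export
setClass("ResonanceTrace",
    representation(sampleRate = "numeric", values = "numeric",
                   sensorId = "integer"))

setValidity("ResonanceTrace", function(object) {
    msg <- character()
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
        msg <- c(msg, "'sampleRate' must be a single positive number (Hz)")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "'values' must be finite")
    if (length(msg)) msg else TRUE
})

#' Resonant-frequency trace
#'
#' A uniformly sampled resonant-frequency offset time series from one SMR
#' cantilever. Cell transits appear as transient frequency depressions whose
#' depth is proportional to buoyant mass.
#'
#' @param values Frequency offsets in Hz.
#' @param sampleRate Sampling rate in Hz.
#' @param sensorId Integer sensor index along the serial device.
#' @return A `ResonanceTrace` object.
#' @examples
#' ResonanceTrace(rnorm(100), sampleRate = 100)
#' @export
ResonanceTrace <- function(values, sampleRate, sensorId = 1L) {
    new("ResonanceTrace", sampleRate = sampleRate,
        values = as.numeric(values), sensorId = as.integer(sensorId))
}

#' @rdname FilterSettings
#' @export
setClass("FilterSettings",
    representation(sgWindow = "integer", sgOrder = "integer",
                   baselineWindow = "integer", medianLength = "integer",
                   threshold = "numeric"))

setValidity("FilterSettings", function(object) {
    msg <- character()
    if (object@sgWindow %% 2L == 0L || object@sgWindow <= object@sgOrder)
        msg <- c(msg, "'sgWindow' must be odd and greater than 'sgOrder'")
    if (object@baselineWindow %% 2L == 0L || object@baselineWindow < 3L)
        msg <- c(msg, "'baselineWindow' must be odd and >= 3")
    if (object@medianLength %% 2L == 0L || object@medianLength < 1L)
        msg <- c(msg, "'medianLength' must be odd")
    if (!is.finite(object@threshold) || object@threshold <= 0)
        msg <- c(msg, "'threshold' must be positive")
    if (length(msg)) msg else TRUE
})

#' Trace-filtering settings
#'
#' Settings of the occupancy pipeline: Savitzky-Golay smoothing window and
#' polynomial order, the running-median baseline window of the nonlinear
#' high-pass (much longer than a transit so the baseline tracks drift but not
#' transits), the median-filter frame length applied before threshold
#' detection (49 samples by default), and the detection threshold in Hz.
#'
#' @param sgWindow Savitzky-Golay window length in samples (odd).
#' @param sgOrder Savitzky-Golay polynomial order (< `sgWindow`).
#' @param baselineWindow Running-median baseline window in samples (odd);
#'   default 801 samples, about ten transit durations at 100 Hz.
#' @param medianLength Median-filter frame length in samples (odd, default 49).
#' @param threshold Detection threshold in Hz.
#' @return A `FilterSettings` object.
#' @examples
#' FilterSettings(threshold = 1)
#' @export
FilterSettings <- function(sgWindow = 11, sgOrder = 3, baselineWindow = 801,
                           medianLength = 49, threshold = 1) {
    new("FilterSettings", sgWindow = as.integer(sgWindow),
        sgOrder = as.integer(sgOrder),
        baselineWindow = as.integer(baselineWindow),
        medianLength = as.integer(medianLength), threshold = threshold)
}

## ---------------------------------------------------------------------------
## Frame
## ---------------------------------------------------------------------------

#' @rdname Frame
#' @export
setClass("Frame",
    representation(pixels = "matrix", pixelPitch = "numeric",
                   timestamp = "numeric"))

setValidity("Frame", function(object) {
    msg <- character()
    if (!is.numeric(object@pixels))
        msg <- c(msg, "'pixels' must be a numeric matrix")
    else if (any(object@pixels < 0) || any(object@pixels > 255))
        msg <- c(msg, "pixel intensities must lie in [0, 255]")
    if (object@pixelPitch <= 0)
        msg <- c(msg, "'pixelPitch' must be positive (um per pixel)")
    if (length(msg)) msg else TRUE
})

#' Bright-field camera frame
#'
#' An 8-bit grayscale frame of the junction region. Pixel origin is the
#' top-left corner, x increases to the right (columns), y downward (rows);
#' `pixels[y + 1, x + 1]` is the intensity at 0-based coordinate (x, y).
#'
#' @param pixels Numeric matrix of intensities in \[0, 255\] (rows = y,
#'   columns = x).
#' @param pixelPitch Physical pixel size, um per pixel.
#' @param timestamp Acquisition time, seconds.
#' @return A `Frame` object.
#' @examples
#' Frame(matrix(200, 40, 60))
#' @export
Frame <- function(pixels, pixelPitch = 0.8, timestamp = 0) {
    new("Frame", pixels = pixels, pixelPitch = pixelPitch,
        timestamp = timestamp)
}

## ---------------------------------------------------------------------------
## CellTrajectory & BoxSummary
## ---------------------------------------------------------------------------

#' @rdname CellTrajectory
#' @export
setClass("CellTrajectory",
    representation(cellId = "integer", points = "data.frame"))

setValidity("CellTrajectory", function(object) {
    p <- object@points
    msg <- character()
    if (!all(c("sensor_id", "time", "mass") %in% names(p)))
        msg <- c(msg, "'points' needs columns sensor_id, time, mass")
    else {
        if (nrow(p) && any(!is.finite(p$mass)))
            msg <- c(msg, "masses must be finite")
        if (nrow(p) > 1 && any(diff(p$time) <= 0))
            msg <- c(msg, "point times must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' Per-cell mass trajectory
#'
#' The sequence of (time, buoyant mass) points a single cell produces as it
#' passes the 10-12 mass sensors of the serial device. The mass accumulation
#' rate [mar()] is the least-squares slope of mass against time; the
#' mass-normalized rate divides by the cell's first-point mass.
#'
#' @param points data.frame with columns `sensor_id`, `time` (seconds,
#'   strictly increasing) and `mass` (pg).
#' @param cellId Integer id.
#' @return A `CellTrajectory` object.
#' @examples
#' tr <- CellTrajectory(data.frame(sensor_id = 1:3, time = c(0, 60, 120),
#'                                 mass = c(50, 50.1, 50.2)))
#' mar(tr)
#' @export
CellTrajectory <- function(points, cellId = 1L) {
    new("CellTrajectory", cellId = as.integer(cellId),
        points = as.data.frame(points))
}

#' @rdname BoxSummary
#' @export
setClass("BoxSummary",
    representation(median = "numeric", q1 = "numeric", q3 = "numeric",
                   whiskerLow = "numeric", whiskerHigh = "numeric",
                   outliers = "numeric"))

setValidity("BoxSummary", function(object) {
    if (!(object@q1 <= object@median && object@median <= object@q3))
        "q1 <= median <= q3 must hold"
    else TRUE
})
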