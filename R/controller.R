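## Pure decision logic of the active-loading finite-state machine.
##
## The controller consumes region-of-interest (ROI) events produced by the
## imaging front end and emits fluidic state transitions plus the flow command
## each state implies. It is a pure function of (state, event, policy,
## elapsed-time): it holds no clock of its own, so identical inputs always
## give identical outputs and a recorded event log can be replayed exactly.

#' Create an ROI event
#'
#' @param roiId Integer ROI id in 1..4. ROI 1 detects particles in the seek
#'   state; ROI 2 detects the particle waiting for the duty cycle in the load
#'   state; ROI 4 detects entry into the measurement channel; ROI 3 images the
#'   entered particle for the accept/reject verdict.
#' @param time Event time in seconds.
#' @param geometry For ROI 3 events only: a [detectedParticle()] geometry
#'   summary of the imaged particle.
#' @return A list of class `RoiEvent`.
#' @examples
#' roiEvent(1, time = 2.5)
#' @export
roiEvent <- function(roiId, time = 0, geometry = NULL) {
    if (length(roiId) != 1L || is.na(roiId) || !(roiId %in% 1:4))
        stop("invalid-event: 'roiId' must be one of 1, 2, 3, 4")
    structure(list(roiId = as.integer(roiId), time = time,
                   geometry = geometry), class = "RoiEvent")
}

#' Geometry summary of a detected particle
#'
#' @param area Cross-sectional area in pixel^2 (> 0).
#' @param xyRatio Bounding-box max/min extent ratio (>= 1).
#' @param meanContrast Mean intensity delta against background.
#' @param centroid Numeric (x, y) centroid in pixels.
#' @return A one-row data.frame with the geometry fields.
#' @examples
#' detectedParticle(area = 180, xyRatio = 1.1)
#' @export
detectedParticle <- function(area, xyRatio = 1, meanContrast = NA_real_,
                             centroid = c(NA_real_, NA_real_)) {
    data.frame(centroid_x = centroid[1], centroid_y = centroid[2],
               area = area, xy_ratio = xyRatio, mean_contrast = meanContrast)
}

#' Accept/reject verdict on particle geometry
#'
#' A particle imaged at ROI 3 is accepted iff its area lies inside the
#' inclusive policy window, its x-y ratio does not exceed the policy bound,
#' and (when the contrast bound is enabled) its mean contrast is at least
#' `minContrast`. Everything else - debris, doublets, aggregates - is
#' rejected. The decision is deterministic and threshold-inclusive.
#'
#' @param geometry A [detectedParticle()] row (fields `area`, `xy_ratio`,
#'   optionally `mean_contrast`).
#' @param policy A [ControllerPolicy()].
#' @return `"accept"` or `"reject"`.
#' @examples
#' pol <- ControllerPolicy()
#' verdict(detectedParticle(180, 1.0), pol)
#' verdict(detectedParticle(600, 1.0), pol)   # doublet-sized: reject
#' @export
verdict <- function(geometry, policy) {
    area <- geometry$area
    xy <- geometry$xy_ratio
    if (length(area) != 1L || !is.finite(area) || area <= 0)
        stop("invalid-geometry: 'area' must be a single positive number")
    if (!is.finite(xy) || xy < 1)
        stop("invalid-geometry: 'xy_ratio' must be finite and >= 1")
    ok <- area >= policy@areaMin && area <= policy@areaMax &&
        xy <= policy@xyRatioMax
    if (ok && policy@minContrast > 0) {
        mc <- geometry$mean_contrast
        ok <- is.finite(mc) && mc >= policy@minContrast
    }
    if (ok) "accept" else "reject"
}

#' Flow command implied by a fluidic state
#'
#' LOAD: sampling inflow equals measurement flow, so every particle reaching
#' the junction enters the measurement channel. SEEK: sampling flow raised to
#' `seekFlowMultiplier` times the measurement flow with the measurement flow
#' unchanged. QUEUE: sampling flow reversed (upstream flush), measurement flow
#' unchanged. REJECT: measurement flow briefly reversed while the sampling
#' flow pushes downstream so the rejected particle is not recaptured.
#'
#' @param state A state name from [fluidicStates()] or a
#'   [ControllerState()].
#' @param measurementFlow Measurement-channel flow in uL/s.
#' @param seekFlowMultiplier Seek/queue/reject sampling flow as a multiple of
#'   the measurement flow.
#' @return A [FlowCommand()] in nL/s.
#' @examples
#' flowCommand("LOAD")
#' flowCommand("QUEUE")
#' @export
flowCommand <- function(state, measurementFlow = 5e-5,
                        seekFlowMultiplier = 20) {
    if (is(state, "ControllerState")) state <- state@state
    qm <- measurementFlow * 1e3           # uL/s -> nL/s
    qs <- seekFlowMultiplier * qm
    switch(state,
        LOAD = FlowCommand(sampling = qm, measurement = qm),
        SEEK = FlowCommand(sampling = qs, measurement = qm),
        QUEUE = FlowCommand(sampling = -qs, measurement = qm),
        REJECT = FlowCommand(sampling = qs, measurement = -qm),
        stop("unknown fluidic state: ", state))
}

#' Advance the controller by one ROI event
#'
#' Implements the transition table of the active-loading state machine:
#' \itemize{
#'   \item SEEK + ROI 1: particle found in the sampling channel, switch to
#'     LOAD to capture it.
#'   \item LOAD + ROI 2 with `timeSinceLastLoad < dutyCycle`: too early -
#'     switch to QUEUE (upstream flush); after the queue dwell the controller
#'     returns to LOAD via [onExpiry()]. With the duty cycle already elapsed
#'     the particle is simply admitted (no QUEUE).
#'   \item LOAD + ROI 4: particle entered the measurement channel; the
#'     controller stays in LOAD awaiting the immediate ROI 3 verdict.
#'   \item pending verdict + ROI 3: [verdict()] on the attached geometry -
#'     accept starts the next cycle (SEEK), reject switches to REJECT; after
#'     the reject dwell [onExpiry()] returns to SEEK.
#' }
#' Events that are not meaningful in the current state (e.g. ROI 1 while
#' loading) leave the state unchanged with outcome `"ignored"`. The
#' controller never produces two `"accepted"` outcomes within one duty cycle
#' provided `timeSinceLastLoad` is measured from the previous accepted load.
#'
#' @param state A [ControllerState()].
#' @param event An [roiEvent()]; ROI 3 events must carry geometry.
#' @param policy A [ControllerPolicy()].
#' @param timeSinceLastLoad Seconds since the previous *accepted* load
#'   (rejected particles do not reset this clock).
#' @param measurementFlow,seekFlowMultiplier Passed to [flowCommand()].
#' @return A list with elements `state` (new [ControllerState()]), `command`
#'   (the [FlowCommand()] of the new state) and `outcome` (one of
#'   `"seek-detect"`, `"queued"`, `"admitted"`, `"await-verdict"`,
#'   `"accepted"`, `"rejected"`, `"ignored"`).
#' @examples
#' pol <- ControllerPolicy(dutyCycle = 15)
#' onRoiEvent(ControllerState("SEEK"), roiEvent(1), pol, 20)$state
#' @export
onRoiEvent <- function(state, event, policy, timeSinceLastLoad,
                       measurementFlow = 5e-5, seekFlowMultiplier = 20) {
    stopifnot(is(state, "ControllerState"))
    if (!inherits(event, "RoiEvent"))
        event <- do.call(roiEvent, event)
    res <- .transition(state@state, state@awaitingVerdict, event$roiId,
                       event$geometry, policy, timeSinceLastLoad)
    list(state = ControllerState(res$state, res$await),
         command = flowCommand(res$state, measurementFlow,
                               seekFlowMultiplier),
         outcome = res$outcome)
}

# S4-free FSM core shared by onRoiEvent() and replayEvents().
.transition <- function(s, await, id, geometry, policy, timeSinceLastLoad) {
    if (length(id) != 1L || is.na(id) || !(id %in% 1:4))
        stop("invalid-event: unknown roi_id ", id)
    if (id == 3L && !await)
        stop("protocol-order: ROI 3 event without a preceding ROI 4 event")
    outcome <- "ignored"
    if (s == "SEEK" && id == 1L) {
        s <- "LOAD"; outcome <- "seek-detect"
    } else if (s == "LOAD" && id == 2L && !await) {
        # 1 ns tolerance so grid-quantized times exactly at the duty
        # boundary count as elapsed
        if (timeSinceLastLoad < policy@dutyCycle - 1e-9) {
            s <- "QUEUE"; outcome <- "queued"
        } else {
            outcome <- "admitted"      # duty elapsed: particle proceeds
        }
    } else if (s == "LOAD" && id == 4L && !await) {
        await <- TRUE; outcome <- "await-verdict"
    } else if (id == 3L && await) {
        if (is.null(geometry))
            stop("invalid-event: ROI 3 event requires geometry")
        await <- FALSE
        if (verdict(geometry, policy) == "accept") {
            s <- "SEEK"; outcome <- "accepted"
        } else {
            s <- "REJECT"; outcome <- "rejected"
        }
    }
    list(state = s, await = await, outcome = outcome)
}

#' Timed expiry of a transient state
#'
#' QUEUE and REJECT are transient states with a bounded dwell time. On expiry
#' of the queue flush the controller returns to LOAD (the particle drifts
#' back toward the junction); on expiry of the reject flush it returns to
#' SEEK to look for the next particle.
#'
#' @param state A [ControllerState()] in QUEUE or REJECT.
#' @param measurementFlow,seekFlowMultiplier Passed to [flowCommand()].
#' @return As [onRoiEvent()], with outcome `"queue-expired"` or
#'   `"reject-expired"`.
#' @examples
#' onExpiry(ControllerState("QUEUE"))$state
#' @export
onExpiry <- function(state, measurementFlow = 5e-5, seekFlowMultiplier = 20) {
    stopifnot(is(state, "ControllerState"))
    if (state@state == "QUEUE") {
        s <- "LOAD"; outcome <- "queue-expired"
    } else if (state@state == "REJECT") {
        s <- "SEEK"; outcome <- "reject-expired"
    } else {
        stop("state ", state@state, " has no timed dwell")
    }
    list(state = ControllerState(s, FALSE),
         command = flowCommand(s, measurementFlow, seekFlowMultiplier),
         outcome = outcome)
}

#' The controller transition table
#'
#' A machine-readable enumeration of every transition of the loading state
#' machine, as implemented by [onRoiEvent()] and [onExpiry()].
#'
#' @return data.frame with columns `state`, `trigger`, `condition`,
#'   `next_state`, `outcome`.
#' @examples
#' transitionTable()
#' @export
transitionTable <- function() {
    data.frame(
        state = c("SEEK", "LOAD", "LOAD", "LOAD", "LOAD", "LOAD",
                  "QUEUE", "REJECT"),
        trigger = c("ROI1", "ROI2", "ROI2", "ROI4", "ROI3", "ROI3",
                    "timer", "timer"),
        condition = c("", "elapsed < duty_cycle", "elapsed >= duty_cycle",
                      "", "verdict accept", "verdict reject",
                      "queue_flush_duration elapsed",
                      "reject_flush_duration elapsed"),
        next_state = c("LOAD", "QUEUE", "LOAD", "LOAD", "SEEK", "REJECT",
                       "LOAD", "SEEK"),
        outcome = c("seek-detect", "queued", "admitted", "await-verdict",
                    "accepted", "rejected", "queue-expired",
                    "reject-expired"),
        stringsAsFactors = FALSE)
}

#' Replay a sequence of ROI events through the controller
#'
#' Drives [onRoiEvent()]/[onExpiry()] over a time-ordered event table,
#' maintaining the duty-cycle clock (time since the last *accepted* load) and
#' automatically expiring QUEUE/REJECT dwells before the next event. This is
#' the reference driver used by the simulator to derive its state log, and
#' the function with which a recorded log can be re-verified.
#'
#' @param events data.frame with columns `time`, `roi_id` and (for ROI 3
#'   rows) `area`, `xy_ratio`, optionally `mean_contrast`; an optional
#'   `particle_id` column is carried through to the log.
#' @param policy A [ControllerPolicy()].
#' @param initial Initial state name (default `"LOAD"`, the system's default
#'   state; simulations typically start in `"SEEK"`).
#' @param measurementFlow,seekFlowMultiplier Passed to [flowCommand()].
#' @return data.frame log with one row per processed event (timer expiries
#'   included): `time_s`, `roi_id` (NA for timers), `state_before`,
#'   `state_after`, `outcome`, `verdict`, `particle_id`.
#' @examples
#' ev <- data.frame(time = c(1, 2), roi_id = c(1, 4),
#'                  area = NA, xy_ratio = NA)
#' replayEvents(ev, ControllerPolicy(), initial = "SEEK")
#' @export
replayEvents <- function(events, policy, initial = "LOAD",
                         measurementFlow = 5e-5, seekFlowMultiplier = 20) {
    events <- as.data.frame(events)
    if (nrow(events) && is.unsorted(events$time))
        stop("event times must be nondecreasing")
    n <- nrow(events)
    state <- ControllerState(initial)
    lastAccept <- -Inf
    dwellStart <- NA_real_
    N <- 2L * n
    timeS <- numeric(N); roiId <- integer(N); pid <- integer(N)
    sBefore <- character(N); sAfter <- character(N)
    outc <- character(N); verd <- rep(NA_character_, N)
    k <- 0L
    hasContrast <- "mean_contrast" %in% names(events)
    hasPid <- "particle_id" %in% names(events)
    evRoi <- as.integer(events$roi_id)
    evTime <- events$time
    evPid <- if (hasPid) as.integer(events$particle_id)
    qf <- policy@queueFlushDuration
    rf <- policy@rejectFlushDuration
    s <- state@state
    await <- state@awaitingVerdict
    for (i in seq_len(n)) {
        tm <- evTime[i]
        # expire any transient dwell that ends before this event
        if (s == "QUEUE" || s == "REJECT") {
            dwell <- if (s == "QUEUE") qf else rf
            if (tm >= dwellStart + dwell) {
                before <- s
                s <- if (s == "QUEUE") "LOAD" else "SEEK"
                k <- k + 1L
                timeS[k] <- dwellStart + dwell; roiId[k] <- NA_integer_
                pid[k] <- NA_integer_
                sBefore[k] <- before; sAfter[k] <- s
                outc[k] <- if (s == "LOAD") "queue-expired"
                           else "reject-expired"
            }
        }
        geom <- NULL
        if (evRoi[i] == 3L)
            geom <- list(area = events$area[i],
                         xy_ratio = events$xy_ratio[i],
                         mean_contrast = if (hasContrast)
                             events$mean_contrast[i] else NA_real_)
        before <- s
        res <- .transition(s, await, evRoi[i], geom, policy, tm - lastAccept)
        s <- res$state
        await <- res$await
        if (res$outcome == "accepted") lastAccept <- tm
        if (res$outcome == "queued" || res$outcome == "rejected")
            dwellStart <- tm
        k <- k + 1L
        timeS[k] <- tm; roiId[k] <- evRoi[i]
        pid[k] <- if (hasPid) evPid[i] else NA_integer_
        sBefore[k] <- before; sAfter[k] <- s
        outc[k] <- res$outcome
        if (res$outcome == "accepted") verd[k] <- "accept"
        else if (res$outcome == "rejected") verd[k] <- "reject"
    }
    idx <- seq_len(k)
    data.frame(time_s = timeS[idx], roi_id = roiId[idx],
               state_before = sBefore[idx], state_after = sAfter[idx],
               outcome = outc[idx], verdict = verd[idx],
               particle_id = pid[idx])
}
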