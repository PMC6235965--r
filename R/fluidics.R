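## Event-driven stochastic simulator of the two-channel device.
##
## The spatial model is one-dimensional: each particle is indexed by the
## cumulative sampling-channel volume that must be pumped before it reaches
## the junction (inter-particle volumes are Exp(concentration), the volume
## representation of a Poisson process). Under a constant flow Q the arrival
## times are then Poisson with rate c*Q, and under the switching flows of
## active loading the same volume coordinates simply advance at the seek
## flow. Queue-state oscillations net zero pumped volume, so the volume clock
## only advances while seeking (active) or loading (passive).

#' Derived flow quantities
#'
#' `seekFlow()` is the seek-state sampling flow in uL/s; `seekVelocity()` the
#' corresponding particle velocity in the sampling channel in um/s.
#'
#' @param config A [SimulationConfig()].
#' @return Numeric scalar.
#' @examples
#' seekVelocity(SimulationConfig())
#' @export
seekFlow <- function(config) {
    config@seekFlowMultiplier * config@measurementFlow
}

#' @rdname seekFlow
#' @export
seekVelocity <- function(config) {
    seekFlow(config) * 1e9 / config@samplingChannelArea   # uL/s -> um^3/s
}

#' Generate a synthetic particle population
#'
#' Draws the particle stream of one run: cumulative inter-particle volumes
#' are Exp(`concentration`), so junction arrival times under any constant
#' flow Q form a homogeneous Poisson process with rate `c * Q`. Kinds (cell,
#' debris, doublet) are drawn independently with the configured fractions,
#' and each particle carries the geometry summary (area, x-y ratio, mean
#' contrast) its bright-field image would yield: cells are round discs of
#' 8.8-15.2 um diameter, debris is small and irregular, doublets are merged
#' pairs with roughly doubled area and elongated bounding box.
#'
#' @param config A [SimulationConfig()]; `config@seed` fixes the draw.
#' @param mode `"active"` or `"passive"` - sets the pumped-volume horizon
#'   (seek flow vs measurement flow over `duration`).
#' @return data.frame with one row per particle: `id`, `kind`, `size_um`,
#'   `volume_ul` (cumulative volume coordinate), `created_at` (arrival time
#'   under the mode's constant flow, seconds), `area_px2`, `xy_ratio`,
#'   `mean_contrast`.
#' @examples
#' pop <- generatePopulation(SimulationConfig(concentration = 50))
#' table(pop$kind)
#' @export
generatePopulation <- function(config, mode = c("active", "passive")) {
    stopifnot(is(config, "SimulationConfig"))
    mode <- match.arg(mode)
    if (config@duration <= 0)
        stop("configuration error: 'duration' must be positive")
    cc <- config@concentration
    flow <- if (mode == "active") seekFlow(config) else config@measurementFlow
    vMax <- config@duration * flow
    if (cc <= 0 || vMax <= 0) {
        return(data.frame(id = integer(), kind = character(),
                          size_um = numeric(), volume_ul = numeric(),
                          created_at = numeric(), area_px2 = numeric(),
                          xy_ratio = numeric(), mean_contrast = numeric()))
    }
    withSeed(childSeed(config@seed, 1L), {
        # draw in chunks until the cumulative volume passes the horizon
        vols <- numeric(0)
        last <- 0
        repeat {
            nDraw <- max(64L, ceiling(1.2 * (vMax - last) * cc))
            vols <- c(vols, rexp(nDraw, rate = cc))
            cum <- cumsum(vols)
            last <- cum[length(cum)]
            if (last > vMax) break
        }
        v <- cum[cum <= vMax]
        n <- length(v)
        kind <- sample(c("cell", "debris", "doublet"), n, replace = TRUE,
                       prob = c(1 - config@debrisFraction -
                                config@doubletFraction,
                                config@debrisFraction,
                                config@doubletFraction))
        geo <- .particleGeometry(kind)
        data.frame(id = seq_len(n), kind = kind, size_um = geo$size_um,
                   volume_ul = v, created_at = v / flow,
                   area_px2 = geo$area_px2, xy_ratio = geo$xy_ratio,
                   mean_contrast = geo$mean_contrast)
    })
}

# Geometry summaries by particle kind (pixel pitch 0.8 um/px). Cells mimic
# 12 um lymphocytic-leukemia-like cells; debris is small/irregular; doublets
# are merged pairs. Distributions are shared with the imaging fixtures.
.PIXEL_PITCH <- 0.8

.particleGeometry <- function(kind) {
    n <- length(kind)
    size <- numeric(n); area <- numeric(n); xy <- numeric(n); mc <- numeric(n)
    isC <- kind == "cell"; isD <- kind == "debris"; isB <- kind == "doublet"
    size[isC] <- pmin(pmax(rnorm(sum(isC), 12, 1.2), 8.8), 15.2)
    # subcellular fragments: 3-6 um (larger clumps fall under doublets)
    size[isD] <- pmin(pmax(rlnorm(sum(isD), meanlog = log(4), sdlog = 0.4),
                           3), 6)
    size[isB] <- pmin(pmax(rnorm(sum(isB), 12, 1.2), 8.8), 15.2)
    rpx <- size / (2 * .PIXEL_PITCH)
    area[isC] <- pi * rpx[isC]^2
    area[isD] <- pi * rpx[isD]^2
    area[isB] <- 1.85 * pi * rpx[isB]^2
    xy[isC] <- 1 + abs(rnorm(sum(isC), 0, 0.06))
    xy[isD] <- 1 + rexp(sum(isD), rate = 2)
    xy[isB] <- 1.6 + abs(rnorm(sum(isB), 0, 0.2))
    mc[isC | isB] <- rnorm(sum(isC | isB), 40, 5)
    mc[isD] <- pmax(rnorm(sum(isD), 15, 5), 1)
    list(size_um = size, area_px2 = area, xy_ratio = xy, mean_contrast = mc)
}

#' Pneumatic overshoot model
#'
#' Distance a particle travels past the measurement-channel entrance because
#' the pneumatic controls respond with non-zero latency: the seek velocity
#' times a latency draw (deterministic or lognormal with the given mean).
#' Recovery from an overshoot takes one queue-like flow reversal of about two
#' latency periods, which increases the mean inter-load time.
#'
#' @param seekVelocity Particle velocity in the seek state, um/s.
#' @param latency Mean pneumatic latency, seconds.
#' @param model `"deterministic"` or `"lognormal"`.
#' @param sdlog Log-sd for the lognormal model.
#' @param n Number of draws.
#' @return Numeric vector of overshoot distances in um.
#' @examples
#' overshootDistance(1000, 0.05)   # 50 um
#' @export
overshootDistance <- function(seekVelocity, latency,
                              model = c("deterministic", "lognormal"),
                              sdlog = 0.25, n = 1) {
    stopifnot(seekVelocity >= 0, latency >= 0)
    model <- match.arg(model)
    seekVelocity * .latencyDraw(n, latency, model, sdlog)
}

.latencyDraw <- function(n, latency, model, sdlog) {
    if (latency == 0) return(rep(0, n))
    if (model == "deterministic") rep(latency, n)
    else rlnorm(n, meanlog = log(latency) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate passive loading
#'
#' All arriving particles enter the measurement channel in arrival order (the
#' load state's equal-flow condition); a particle yields a successful
#' measurement only when its gap to the previous entry is at least the
#' matching window `config@matchWindow`. There is no debris rejection.
#'
#' @param config A [SimulationConfig()].
#' @return A [`SimResult`][SimResult-class] with the matching failures
#'   recorded as rejected events (reason `"matching-failure"`).
#' @examples
#' res <- runPassive(SimulationConfig(concentration = 50, duration = 3600))
#' throughput(res)
#' @export
runPassive <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    pop <- generatePopulation(config, "passive")
    arrived <- pop[pop$created_at <= config@duration, , drop = FALSE]
    n <- nrow(arrived)
    ok <- if (n) c(TRUE, diff(arrived$created_at) >= config@matchWindow)
          else logical(0)
    loaded <- data.frame(time = arrived$created_at[ok],
                         particle_id = arrived$id[ok],
                         kind = arrived$kind[ok])
    rejected <- data.frame(time = arrived$created_at[!ok],
                           particle_id = arrived$id[!ok],
                           reason = rep("matching-failure", sum(!ok)))
    log <- data.frame(time_s = arrived$created_at,
                      roi_id = rep(NA_integer_, n),
                      state_before = rep("LOAD", n),
                      state_after = rep("LOAD", n),
                      outcome = ifelse(ok, "measured", "matching-failure"),
                      verdict = rep(NA_character_, n),
                      particle_id = arrived$id)
    new("SimResult", mode = "passive", loadedEvents = loaded,
        rejectedEvents = rejected, overshootCount = 0L,
        throughput = 3600 * nrow(loaded) / config@duration,
        interLoadIntervals = if (nrow(loaded) > 1) diff(loaded$time)
                             else numeric(0),
        eventLog = log, duration = config@duration,
        nGenerated = nrow(pop), nRemaining = nrow(pop) - n, config = config)
}

#' Simulate active loading
#'
#' Controller-driven run. After each load the system seeks at
#' `seekFlowMultiplier` times the measurement flow; the next particle is
#' detected at ROI 1 on the camera frame grid, overshoots the junction by
#' `seekVelocity * latency` (recovered by one flow reversal costing about two
#' latency periods), queues until the duty cycle since the last *accepted*
#' load has elapsed, and is then admitted. ROI 4 detects entry and ROI 3's
#' geometry verdict accepts cells and rejects debris/doublets per the policy
#' (a rejection costs `rejectFlushDuration` and does not reset the duty
#' clock). The state log is produced by replaying the generated ROI events
#' through the controller ([replayEvents()]), so it reproduces exactly.
#'
#' A warning is logged (not thrown) when the seek velocity is so high, or the
#' frame rate so low, that a particle can cross a 50 um ROI between frames.
#'
#' @param config A [SimulationConfig()].
#' @param policy A [ControllerPolicy()]; its duty cycle is taken from
#'   `config@dutyCycle`.
#' @return A [`SimResult`][SimResult-class].
#' @examples
#' cfg <- SimulationConfig(concentration = 50, dutyCycle = 9,
#'                         duration = 1800)
#' res <- runActive(cfg)
#' throughput(res)
#' @export
runActive <- function(config, policy = ControllerPolicy()) {
    stopifnot(is(config, "SimulationConfig"), is(policy, "ControllerPolicy"))
    policy@dutyCycle <- config@dutyCycle
    validObject(policy)
    pop <- generatePopulation(config, "active")
    qs <- seekFlow(config)
    vSeek <- seekVelocity(config)
    dt <- 1 / config@cameraFps
    if (vSeek * dt > 50)
        warning("camera frame rate too low for the seek velocity: ",
                "particles can cross a 50 um ROI between frames",
                call. = FALSE)
    duty <- config@dutyCycle
    dur <- config@duration
    qf <- policy@queueFlushDuration
    rf <- policy@rejectFlushDuration

    n <- nrow(pop)
    lat <- withSeed(childSeed(config@seed, 2L),
                    .latencyDraw(n, config@pneumaticLatency,
                                 config@latencyModel, config@latencySdlog))
    recov <- 2 * lat                       # overshoot-recovery reversal time

    # event assembly buffers (ROI events only; controller replays them)
    evTime <- list(); evRoi <- list(); evPid <- list()
    addEv <- local({
        i <- 0L
        function(time, roi, pid) {
            i <<- i + 1L
            evTime[[i]] <<- time; evRoi[[i]] <<- roi; evPid[[i]] <<- pid
        }
    })

    t <- 0; vPump <- 0; lastAccept <- -Inf
    nOver <- 0L
    for (i in seq_len(n)) {
        wait <- (pop$volume_ul[i] - vPump) / qs
        tDet <- ceilToGrid(t + wait, dt)
        if (tDet > dur) break
        vPump <- pop$volume_ul[i]
        if (lat[i] > 0) nOver <- nOver + 1L
        ready <- tDet + recov[i]
        tLoad <- ceilToGrid(max(ready, lastAccept + duty), dt)
        if (tLoad > dur) break
        addEv(tDet, 1L, pop$id[i])                        # ROI 1: seek hit
        # queue flushes while the duty cycle is incomplete; the last flush
        # must expire (dwell qf) before the load instant
        qEnd <- min(lastAccept + duty, tLoad - qf) - 1e-9
        if (ready <= qEnd)
            for (qt in seq(ready, qEnd, by = 2 * qf))
                addEv(qt, 2L, pop$id[i])
        addEv(tLoad, 2L, pop$id[i])                       # admitted pass
        addEv(tLoad, 4L, pop$id[i])                       # entry detected
        addEv(tLoad, 3L, pop$id[i])                       # verdict image
        geom <- list(area = pop$area_px2[i], xy_ratio = pop$xy_ratio[i],
                     mean_contrast = pop$mean_contrast[i])
        if (verdict(geom, policy) == "accept") {
            lastAccept <- tLoad
            t <- tLoad
        } else {
            t <- tLoad + rf
        }
    }

    # events are assembled in chronological order; ties at the load instant
    # keep the physical ROI 2 -> ROI 4 -> ROI 3 ordering
    events <- data.frame(time = as.numeric(unlist(evTime)),
                         roi_id = as.integer(unlist(evRoi)),
                         particle_id = as.integer(unlist(evPid)))
    if (nrow(events)) {
        g <- pop[match(events$particle_id, pop$id), ]
        events$area <- g$area_px2
        events$xy_ratio <- g$xy_ratio
        events$mean_contrast <- g$mean_contrast
        log <- replayEvents(events, policy, initial = "SEEK",
                            measurementFlow = config@measurementFlow,
                            seekFlowMultiplier = config@seekFlowMultiplier)
    } else {
        log <- data.frame(time_s = numeric(), roi_id = integer(),
                          state_before = character(),
                          state_after = character(), outcome = character(),
                          verdict = character(), particle_id = integer())
    }

    acc <- log[!is.na(log$verdict) & log$verdict == "accept", ]
    rej <- log[!is.na(log$verdict) & log$verdict == "reject", ]
    loaded <- data.frame(time = acc$time_s, particle_id = acc$particle_id,
                         kind = pop$kind[match(acc$particle_id, pop$id)])
    rejected <- data.frame(time = rej$time_s, particle_id = rej$particle_id,
                           reason = if (nrow(rej)) paste0("geometry-",
                               pop$kind[match(rej$particle_id, pop$id)])
                               else character(0))
    new("SimResult", mode = "active", loadedEvents = loaded,
        rejectedEvents = rejected, overshootCount = nOver,
        throughput = 3600 * nrow(loaded) / dur,
        interLoadIntervals = if (nrow(loaded) > 1) diff(loaded$time)
                             else numeric(0),
        eventLog = log, duration = dur, nGenerated = n,
        nRemaining = n - nrow(loaded) - nrow(rejected), config = config)
}
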