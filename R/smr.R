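## Resonant-frequency signal chain: synthetic traces, occupancy detection,
## transit times, buoyant-mass estimation, multi-sensor matching, and MAR.
##
## A cell transiting an SMR cantilever depresses the resonant frequency; the
## occupancy pipeline is Savitzky-Golay smoothing, a nonlinear high-pass
## (running-median baseline subtraction, window much longer than a transit),
## magnitude thresholding with median filtering (frame length 49), giving a
## binary occupancy series whose run lengths are the transit times. Run
## boundaries are refined at half the run's plateau depth so the reported
## duration is unbiased by smoothing-induced edge spread.

#' Synthesize a resonant-frequency trace
#'
#' Baseline plus linear drift plus rectangular frequency depressions with
#' raised-cosine edges (the half-amplitude point of each edge sits exactly on
#' the nominal transit boundary) plus Gaussian noise.
#'
#' @param transits data.frame with columns `start`, `duration` (seconds) and
#'   `depth` (Hz, positive = depression depth). Must not overlap.
#' @param sampleRate Hz.
#' @param noiseSd Gaussian noise sd, Hz.
#' @param drift Linear baseline drift, Hz/s.
#' @param duration Trace length in seconds; default covers the last transit
#'   plus two seconds.
#' @param edgeTime Rise/fall time of the smoothed edges, seconds (default
#'   0.02 s = 2 samples at 100 Hz).
#' @param seed Integer seed.
#' @param sensorId Sensor index stored on the trace.
#' @return A [ResonanceTrace()].
#' @examples
#' tr <- synthTrace(data.frame(start = 2, duration = 0.8, depth = 10),
#'                  sampleRate = 100, noiseSd = 1, seed = 7)
#' @export
synthTrace <- function(transits, sampleRate = 100, noiseSd = 0, drift = 0,
                       duration = NULL, edgeTime = 0.02, seed = 1,
                       sensorId = 1L) {
    transits <- transits[order(transits$start), , drop = FALSE]
    if (nrow(transits) > 1) {
        ends <- transits$start + transits$duration
        if (any(transits$start[-1] < ends[-nrow(transits)]))
            stop("fixture error: transits overlap")
    }
    if (is.null(duration))
        duration <- if (nrow(transits))
            max(transits$start + transits$duration) + 2 else 2
    n <- round(duration * sampleRate)
    tt <- (seq_len(n) - 1) / sampleRate
    x <- drift * tt
    for (i in seq_len(nrow(transits))) {
        s <- transits$start[i]; e <- s + transits$duration[i]
        d <- transits$depth[i]
        # raised-cosine step centered on each boundary
        rise <- rep(0, n)
        rise[tt >= s + edgeTime / 2] <- 1
        sel <- tt > s - edgeTime / 2 & tt < s + edgeTime / 2
        rise[sel] <- (1 - cos(pi * (tt[sel] - s + edgeTime / 2) /
                              edgeTime)) / 2
        fall <- rep(0, n)
        fall[tt >= e + edgeTime / 2] <- 1
        sel <- tt > e - edgeTime / 2 & tt < e + edgeTime / 2
        fall[sel] <- (1 - cos(pi * (tt[sel] - e + edgeTime / 2) /
                              edgeTime)) / 2
        x <- x - d * (rise - fall)
    }
    if (noiseSd > 0)
        x <- x + withSeed(seed, rnorm(n, 0, noiseSd))
    ResonanceTrace(x, sampleRate = sampleRate, sensorId = sensorId)
}

#' Binary occupancy from a resonance trace
#'
#' The filtering pipeline: Savitzky-Golay smoothing, running-median baseline
#' subtraction (the nonlinear high-pass: the baseline window is much longer
#' than a transit so drift is tracked but transits are not), magnitude
#' thresholding of the median-filtered (length `medianLength`) signal, then
#' half-depth boundary refinement of each detected run. Below-threshold
#' samples are 0, occupied samples 1.
#'
#' @param trace A [ResonanceTrace()], longer than the filter windows.
#' @param settings A [FilterSettings()].
#' @return Integer 0/1 vector, one element per sample.
#' @examples
#' tr <- synthTrace(data.frame(start = 2, duration = 0.8, depth = 10),
#'                  sampleRate = 100, noiseSd = 1, seed = 7)
#' occ <- occupancy(tr, FilterSettings(threshold = 1))
#' transitTimes(occ, sampleRate(tr))
#' @export
occupancy <- function(trace, settings = FilterSettings()) {
    stopifnot(is(trace, "ResonanceTrace"), is(settings, "FilterSettings"))
    x <- trace@values
    n <- length(x)
    if (n <= max(settings@sgWindow, settings@baselineWindow,
                 settings@medianLength))
        stop("input error: trace shorter than the filter windows")
    sm <- signal::sgolayfilt(x, p = settings@sgOrder, n = settings@sgWindow)
    base <- stats::runmed(sm, settings@baselineWindow, endrule = "median")
    mag <- abs(sm - base)
    med <- stats::runmed(mag, settings@medianLength)
    cand <- med >= settings@threshold
    occ <- integer(n)
    r <- rle(cand)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
        from <- starts[k]; to <- ends[k]
        lo <- if (k > 1 && r$values[k - 1] == FALSE) starts[k - 1] else 1L
        hi <- if (k < length(r$values)) ends[k + 1] else n
        half <- stats::median(mag[from:to]) / 2
        # expand outward while above half depth, then trim inward
        while (from > lo && mag[from - 1L] >= half) from <- from - 1L
        while (from <= to && mag[from] < half) from <- from + 1L
        while (to < hi && mag[to + 1L] >= half) to <- to + 1L
        while (to >= from && mag[to] < half) to <- to - 1L
        if (to >= from) occ[from:to] <- 1L
    }
    occ
}

#' Transit times from a binary occupancy series
#'
#' One duration per maximal run of ones: run length divided by the sample
#' rate. Order-preserving.
#'
#' @param occupancy Integer/logical 0-1 vector.
#' @param sampleRate Hz.
#' @return Numeric vector of durations in seconds (empty if never occupied).
#' @examples
#' transitTimes(c(0, 0, 1, 1, 1, 0, 1, 1, 0), 100)
#' @export
transitTimes <- function(occupancy, sampleRate) {
    if (!all(occupancy %in% c(0, 1)))
        stop("input error: occupancy must be binary")
    r <- rle(as.integer(occupancy))
    r$lengths[r$values == 1L] / sampleRate
}

#' Buoyant mass from a trace segment
#'
#' Estimates the frequency-depression depth of the single transit contained
#' in `segment` as baseline minus plateau: the baseline is the median of the
#' out-of-transit samples and the plateau is the median of the interior of
#' the transit run (edges trimmed by half the smoothing window), made robust
#' against noise-extremum bias. Mass = `calibration * depth`.
#'
#' @param segment Numeric trace segment (Hz) containing one transit, with
#'   baseline on both sides.
#' @param calibration Sensitivity in pg/Hz.
#' @param settings A [FilterSettings()] (smoothing and edge handling).
#' @return Buoyant mass in pg.
#' @examples
#' tr <- synthTrace(data.frame(start = 2, duration = 0.8, depth = 2),
#'                  sampleRate = 100)
#' peakMass(traceValues(tr), calibration = 25)   # 50 pg
#' @export
peakMass <- function(segment, calibration, settings = FilterSettings()) {
    if (!length(segment)) stop("empty segment")
    x <- if (length(segment) > 3 * settings@sgWindow)
        signal::sgolayfilt(segment, p = settings@sgOrder,
                           n = settings@sgWindow) else segment
    base0 <- stats::median(x)
    dep <- base0 - x
    dmax <- max(dep)
    if (dmax <= 0) return(0)
    run <- which(dep >= dmax / 2)
    trim <- settings@sgWindow %/% 2
    interior <- run[run >= min(run) + trim & run <= max(run) - trim]
    if (!length(interior)) interior <- run
    base <- stats::median(x[-seq(min(run), max(run))])
    if (!is.finite(base)) base <- base0
    calibration * (base - stats::median(x[interior]))
}

#' Match per-sensor mass events into cell trajectories
#'
#' Greedy in-order matching across consecutive sensors: an event at sensor
#' i links to the downstream event at sensor i+1 whose time lies within
#' `expectedGap` plus/minus `tolerance` - but only when that candidate is
#' unique in both directions. Ambiguous events (two cells closer than the
#' matching resolution) and out-of-window events are matching failures;
#' trajectories need at least two linked points.
#'
#' @param events data.frame with columns `sensor_id`, `time` (seconds,
#'   sorted within each sensor) and `mass` (pg).
#' @param expectedGap Expected sensor-to-sensor travel time, seconds.
#' @param tolerance Matching window half-width, seconds (default 20% of the
#'   gap).
#' @return List of [CellTrajectory()] objects.
#' @examples
#' ev <- data.frame(sensor_id = rep(1:3, each = 1),
#'                  time = c(0, 60, 120), mass = c(50, 50.1, 50.2))
#' matchCells(ev, expectedGap = 60)
#' @export
matchCells <- function(events, expectedGap, tolerance = 0.2 * expectedGap) {
    stopifnot(all(c("sensor_id", "time", "mass") %in% names(events)))
    sensors <- sort(unique(events$sensor_id))
    byS <- lapply(sensors, function(s) {
        e <- events[events$sensor_id == s, ]
        if (is.unsorted(e$time))
            stop("input error: events must be time-sorted within sensors")
        e
    })
    # chain id per event; links propagate chains downstream
    chain <- lapply(byS, function(e) rep(NA_integer_, nrow(e)))
    nextChain <- 0L
    for (si in seq_len(length(sensors) - 1L)) {
        up <- byS[[si]]; dn <- byS[[si + 1L]]
        if (!nrow(up) || !nrow(dn)) next
        expect <- up$time + expectedGap
        for (j in seq_len(nrow(up))) {
            candDn <- which(abs(dn$time - expect[j]) <= tolerance)
            if (length(candDn) != 1L) next          # none or ambiguous
            candUp <- which(abs(dn$time[candDn] - expect) <= tolerance)
            if (length(candUp) != 1L) next          # contested downstream
            if (is.na(chain[[si]][j])) {
                nextChain <- nextChain + 1L
                chain[[si]][j] <- nextChain
            }
            chain[[si + 1L]][candDn] <- chain[[si]][j]
        }
    }
    ids <- sort(unique(unlist(chain)))
    out <- list()
    for (id in ids) {
        pts <- do.call(rbind, lapply(seq_along(byS), function(si) {
            sel <- which(chain[[si]] == id)
            if (length(sel)) byS[[si]][sel, c("sensor_id", "time", "mass")]
        }))
        if (nrow(pts) >= 2) {
            pts <- pts[order(pts$time), ]
            rownames(pts) <- NULL
            out[[length(out) + 1L]] <-
                CellTrajectory(pts, cellId = length(out) + 1L)
        }
    }
    out
}

#' @describeIn mar Least-squares slope of mass (pg) against time (s),
#'   reported per hour.
setMethod("mar", "CellTrajectory", function(object) {
    p <- object@points
    if (nrow(p) < 2)
        stop("insufficient-data: MAR needs at least 2 points")
    3600 * unname(coef(lm(mass ~ time, data = p))[2])
})

#' First-point buoyant mass of a trajectory
#'
#' @param object A [CellTrajectory()].
#' @return Mass in pg.
#' @export
firstMass <- function(object) {
    stopifnot(is(object, "CellTrajectory"), nrow(object@points) >= 1)
    object@points$mass[1]
}

#' @describeIn marPerMass MAR divided by first-point mass.
setMethod("marPerMass", "CellTrajectory", function(object) {
    m <- firstMass(object)
    if (m <= 0) stop("first-point mass must be positive")
    mar(object) / m
})

#' Per-cell summary table for a set of trajectories
#'
#' @param trajectories List of [CellTrajectory()] (>= 2 points each).
#' @return data.frame: `cell_id`, `n_points`, `mass_pg`, `mar_pg_per_h`,
#'   `mar_per_mass_per_h`.
#' @examples
#' tr <- synthTrajectories(3, seed = 1)
#' trajectoryTable(tr)
#' @export
trajectoryTable <- function(trajectories) {
    do.call(rbind, lapply(trajectories, function(tr) {
        data.frame(cell_id = tr@cellId, n_points = nrow(tr@points),
                   mass_pg = firstMass(tr), mar_pg_per_h = mar(tr),
                   mar_per_mass_per_h = marPerMass(tr))
    }))
}

#' Simulate noisy linear-growth trajectories
#'
#' Fixture generator for recovery studies and downstream statistics: each
#' cell grows linearly in buoyant mass across evenly spaced sensors with
#' Gaussian measurement noise.
#'
#' @param n Number of cells.
#' @param nSensors Points per trajectory (10-12 for the serial device).
#' @param gap Sensor-to-sensor time, seconds (default 120 s: a cell spends
#'   roughly twenty minutes crossing the sensor array).
#' @param massMean,massSd Initial buoyant mass distribution, pg.
#' @param marMean,marSd True MAR distribution, pg/h.
#' @param noiseSd Per-point mass noise, pg (default 0.05 pg, the
#'   tens-of-femtograms precision scale of SMR mass sensors).
#' @param seed Integer seed.
#' @return List with one [CellTrajectory()] per cell; the true rates are in
#'   `attr(, "trueMar")`.
#' @examples
#' tr <- synthTrajectories(5, seed = 2)
#' mar(tr[[1]])
#' @export
synthTrajectories <- function(n, nSensors = 11, gap = 120, massMean = 50,
                              massSd = 8, marMean = 2, marSd = 0.5,
                              noiseSd = 0.05, seed = 1) {
    withSeed(seed, {
        m0 <- rnorm(n, massMean, massSd)
        rate <- rnorm(n, marMean, marSd)    # pg/h
        out <- vector("list", n)
        for (i in seq_len(n)) {
            tt <- (seq_len(nSensors) - 1) * gap
            mass <- m0[i] + rate[i] * tt / 3600 + rnorm(nSensors, 0, noiseSd)
            out[[i]] <- CellTrajectory(
                data.frame(sensor_id = seq_len(nSensors), time = tt,
                           mass = mass), cellId = i)
        }
        attr(out, "trueMar") <- rate
        out
    })
}
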