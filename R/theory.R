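## Closed-form concentration-dependent throughput for passive and active
## loading.
##
## Passive loading: particles enter the measurement channel as a Poisson
## process with rate lambda = c * Q_m. A cell yields a usable measurement only
## when the gap to the previous entry is at least the matching window t_match,
## so the measured rate is lambda * exp(-lambda * t_match): it rises with
## concentration, peaks at lambda = 1/t_match, then falls as matching
## failures take over.
##
## Active loading is a renewal process. After each accepted load the system
## seeks the next particle at the high sampling flow Q_s = m * Q_m
## (wait ~ Exp(c * Q_s)), detection is quantized to the camera frame grid
## (mean delay 1/(2 fps)), and pneumatic latency costs a mean overshoot-
## recovery penalty. A particle found before the duty cycle has elapsed is
## queued and loads exactly at the duty boundary, so the mean cycle length is
## E[max(t_duty, W)] with W the total seek delay. Throughput saturates at
## 3600/t_duty for concentrated samples and approaches Q_s/Q_m times the
## passive rate for dilute ones.

#' Particle arrival rate at the measurement-channel junction
#'
#' @param c Concentration in particles/uL (vectorized).
#' @param Qm Volumetric flow in uL/s.
#' @return Rate in particles/s.
#' @examples
#' arrivalRate(100, 1e-4)   # 0.01 /s
#' @export
arrivalRate <- function(c, Qm) {
    stopifnot(all(c >= 0), Qm >= 0)
    c * Qm
}

#' Passive-loading throughput
#'
#' Measured-cell rate `3600 * lambda * exp(-lambda * t_match)` with
#' `lambda = c * Qm`: the rate of Poisson arrivals whose preceding gap is at
#' least the matching window. Unimodal in concentration with maximum
#' `3600/(e * t_match)` at `c* = 1/(Qm * t_match)`.
#'
#' @param c Concentration in particles/uL (vectorized).
#' @param params A [ThroughputParams()].
#' @return Throughput in cells/h.
#' @examples
#' passiveThroughput(50, ThroughputParams())
#' @export
passiveThroughput <- function(c, params = ThroughputParams()) {
    lam <- arrivalRate(c, params@measurementFlow)
    3600 * lam * exp(-lam * params@matchWindow)
}

#' Mean seek overhead
#'
#' Mean time for the seek state to bring the next particle to ROI 1:
#' exponential waiting `1/(c * Qs)` at the seek flow plus the mean
#' frame-quantization delay `1/(2 * cameraFps)`. Decreasing in concentration.
#'
#' @inheritParams passiveThroughput
#' @return Mean seek time in seconds (`Inf` at c = 0).
#' @examples
#' meanSeekTime(50, ThroughputParams())
#' @export
meanSeekTime <- function(c, params = ThroughputParams()) {
    qs <- params@seekFlowMultiplier * params@measurementFlow
    ifelse(c > 0, 1 / (c * qs), Inf) + 0.5 / params@cameraFps
}

#' Active-loading throughput
#'
#' `3600 / E[max(t_duty, W)]` where `W = w0 + Exp(c * Qs)` is the seek delay
#' (`w0` = frame-quantization delay plus mean overshoot-recovery penalty).
#' For `w0 < t_duty` the mean cycle is
#' `t_duty + exp(-c Qs (t_duty - w0)) / (c Qs)`; queued particles load
#' exactly at the duty boundary, so throughput saturates at `3600/t_duty` for
#' concentrated samples and is nondecreasing in concentration.
#'
#' @inheritParams passiveThroughput
#' @return Throughput in cells/h.
#' @examples
#' activeThroughput(c(2, 50, 1000), ThroughputParams())
#' @export
activeThroughput <- function(c, params = ThroughputParams()) {
    lamS <- arrivalRate(c, params@seekFlowMultiplier * params@measurementFlow)
    w0 <- 0.5 / params@cameraFps + params@overshootPenalty
    duty <- params@dutyCycle
    cycle <- if (w0 >= duty) w0 + 1 / lamS
             else duty + exp(-lamS * (duty - w0)) / lamS
    out <- 3600 / cycle
    out[lamS <= 0] <- 0
    out
}

#' Active/passive throughput ratio
#'
#' @inheritParams passiveThroughput
#' @return Dimensionless speedup; `Inf` where passive throughput is zero.
#' @examples
#' speedup(50, ThroughputParams(dutyCycle = 9))
#' @export
speedup <- function(c, params = ThroughputParams()) {
    p <- passiveThroughput(c, params)
    a <- activeThroughput(c, params)
    ifelse(p > 0, a / p, Inf)
}

#' Theoretical throughput curve over a concentration grid
#'
#' @param params A [ThroughputParams()].
#' @param concentrations Concentration grid in particles/uL; defaults to a
#'   log-spaced grid over 1-1000, the experimentally covered range.
#' @return data.frame with columns `concentration`, `passive`, `active`,
#'   `speedup` (all throughputs in cells/h).
#' @examples
#' head(throughputCurve())
#' @export
throughputCurve <- function(params = ThroughputParams(),
                            concentrations = 10^seq(0, 3, length.out = 121)) {
    data.frame(concentration = concentrations,
               passive = passiveThroughput(concentrations, params),
               active = activeThroughput(concentrations, params),
               speedup = speedup(concentrations, params))
}

#' Plot a throughput curve
#'
#' Log-log comparison of the passive (dashed) and active (solid) theoretical
#' throughput limits.
#'
#' @param curve Output of [throughputCurve()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `curve`.
#' @export
plotThroughputCurve <- function(curve, ...) {
    graphics::matplot(curve$concentration, cbind(curve$active, curve$passive),
        type = "l", lty = c(1, 2), col = c("black", "grey40"), log = "xy",
        xlab = "concentration (particles/uL)", ylab = "throughput (events/h)",
        ...)
    graphics::legend("bottomright", c("active", "passive"), lty = c(1, 2),
                     col = c("black", "grey40"), bty = "n")
    invisible(curve)
}
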