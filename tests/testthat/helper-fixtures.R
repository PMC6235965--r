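# Shared fixtures and independent oracles.

defaultPolicy <- function(...) ControllerPolicy(...)

quickConfig <- function(...) {
    args <- list(...)
    if (is.null(args$duration)) args$duration <- 600
    do.call(SimulationConfig, args)
}

# Independent type-7 quantile: direct order-statistic interpolation.
bruteQuantile7 <- function(x, p) {
    x <- sort(x)
    n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    q <- x[lo]
    if (lo < n) q <- q + (h - lo) * (x[lo + 1] - x[lo])
    q
}

# Brute-force Tukey box summary built only from order statistics.
bruteBox <- function(x) {
    q1 <- bruteQuantile7(x, 0.25)
    q3 <- bruteQuantile7(x, 0.75)
    iqr <- q3 - q1
    if (iqr == 0) inside <- x >= q1 & x <= q3
    else inside <- x > q1 - 1.5 * iqr & x < q3 + 1.5 * iqr
    list(median = bruteQuantile7(x, 0.5), q1 = q1, q3 = q3,
         whiskerLow = if (any(inside)) min(x[inside]) else q1,
         whiskerHigh = if (any(inside)) max(x[inside]) else q3,
         outliers = sort(x[!inside]))
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of group
# assignments (tie-free data only).
enumRankSumP <- function(a, b) {
    n <- length(a); m <- length(b)
    pooled <- c(a, b)
    ranks <- rank(pooled)
    wObs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
    combos <- utils::combn(n + m, n)
    ws <- apply(combos, 2, function(idx) {
        sum(ranks[idx]) - n * (n + 1) / 2
    })
    pLo <- mean(ws <= wObs)
    pHi <- mean(ws >= wObs)
    min(1, 2 * min(pLo, pHi))
}

# Render one labeled object and classify it; NA when nothing is detected.
classifyObject <- function(object, policy, seed) {
    roi <- roiSpec(3, 0, 0, 80, 60)
    bg <- renderFrame(sceneSpec(noiseSd = 0), c(60, 80))
    fr <- renderFrame(objectScene(object), c(60, 80), seed = seed)
    det <- detectParticles(fr, roi, bg)
    if (!nrow(det)) return(NA_character_)
    verdict(det[which.max(det$area), ], policy)
}

# Physically ordered random event stream for duty-cycle stress tests: every
# particle crosses ROI1 -> ROI2 (refiring while queued) -> ROI4 -> ROI3.
dutyHarnessEvents <- function(nTarget, policy, seed, acceptProb = 0.6) {
    duty <- policy@dutyCycle
    set.seed(seed)
    local({
        time <- numeric(0); roi <- integer(0); area <- numeric(0)
        t <- 0; lastAcc <- -Inf
        add <- function(tt, id, ar) {
            time[length(time) + 1L] <<- tt
            roi[length(roi) + 1L] <<- id
            area[length(area) + 1L] <<- ar
        }
        while (length(time) < nTarget) {
            t <- t + rexp(1, 0.5)              # seek wait
            add(t, 1L, NA)                     # ROI1 detection
            t <- t + 0.05
            qf <- policy@queueFlushDuration
            # queue refires; the last flush must expire before admission
            while (t < lastAcc + duty - qf - 1e-9) {
                add(t, 2L, NA)
                t <- t + 2 * qf
            }
            t <- max(t, lastAcc + duty)
            add(t, 2L, NA)                     # admitted
            ar <- if (runif(1) < acceptProb)
                (policy@areaMin + policy@areaMax) / 2
            else 2 * policy@areaMax
            add(t, 4L, NA)
            add(t, 3L, ar)
            if (ar <= policy@areaMax) lastAcc <- t
            else t <- t + policy@rejectFlushDuration
        }
        data.frame(time = time, roi_id = roi, area = area, xy_ratio = 1)
    })
}
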