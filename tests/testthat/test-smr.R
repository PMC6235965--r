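# SMR signal chain: trace synthesis, occupancy, transit times, masses,
# matching, MAR.

oneTransit <- function(depth = 10, noiseSd = 0, seed = 1, start = 4.605,
                       duration = 0.8, drift = 0, total = 12) {
    synthTrace(data.frame(start = start, duration = duration,
                          depth = depth),
               sampleRate = 100, noiseSd = noiseSd, drift = drift,
               duration = total, seed = seed)
}

test_that("trace synthesis is exact and seeded", {
    flat <- synthTrace(data.frame(start = numeric(), duration = numeric(),
                                  depth = numeric()), 100, duration = 3)
    expect_true(all(traceValues(flat) == 0))
    tr <- oneTransit()
    expect_equal(sum(traceValues(tr) < -5), 80, tolerance = 0.02)
    n1 <- oneTransit(noiseSd = 1, seed = 3)
    n2 <- oneTransit(noiseSd = 1, seed = 3)
    expect_identical(traceValues(n1), traceValues(n2))
    expect_error(synthTrace(data.frame(start = c(1, 1.5),
                                       duration = c(0.8, 0.8),
                                       depth = c(5, 5)), 100),
                 "overlap")
})

test_that("occupancy recovers transit durations to one sample", {
    set <- FilterSettings(threshold = 1)
    # noiseless: exact to within one sample period
    tt0 <- transitTimes(occupancy(oneTransit(), set), 100)
    expect_length(tt0, 1)
    expect_lt(abs(tt0 - 0.8), 0.01 + 1e-9)
    # SNR 10 across seeds: within two sample periods
    for (s in 1:8) {
        tt <- transitTimes(occupancy(oneTransit(noiseSd = 1, seed = s),
                                     set), 100)
        expect_length(tt, 1)
        expect_lt(abs(tt - 0.8), 0.02 + 1e-9)
    }
    expect_error(occupancy(ResonanceTrace(rnorm(100), 100), set),
                 "shorter")
})

test_that("pure noise stays below threshold at 5 sigma", {
    set <- FilterSettings(threshold = 5)
    runs <- vapply(1:20, function(s) {
        tr <- synthTrace(data.frame(start = numeric(),
                                    duration = numeric(),
                                    depth = numeric()),
                         100, noiseSd = 1, duration = 100, seed = s)
        length(transitTimes(occupancy(tr, set), 100))
    }, numeric(1))
    expect_identical(sum(runs), 0)   # 2e5 samples, zero false runs
})

test_that("baseline drift is rejected by the nonlinear high-pass", {
    set <- FilterSettings(threshold = 1)
    trD <- synthTrace(data.frame(start = 14.605, duration = 0.8,
                                 depth = 10),
                      100, noiseSd = 1, drift = 0.1, duration = 30,
                      seed = 2)
    tt <- transitTimes(occupancy(trD, set), 100)
    expect_length(tt, 1)
    expect_lt(abs(tt - 0.8), 0.02 + 1e-9)
    # drift alone triggers nothing
    drift0 <- synthTrace(data.frame(start = numeric(),
                                    duration = numeric(),
                                    depth = numeric()),
                         100, noiseSd = 1, drift = 0.1, duration = 30,
                         seed = 3)
    expect_length(transitTimes(occupancy(drift0, set), 100), 0)
})

test_that("transits shorter than the median-filter half-length vanish", {
    set <- FilterSettings(threshold = 1)
    short <- synthTrace(data.frame(start = 4.605, duration = 0.2,
                                   depth = 2), 100, duration = 12)
    expect_length(transitTimes(occupancy(short, set), 100), 0)
    ok <- synthTrace(data.frame(start = 4.605, duration = 0.3,
                                depth = 2), 100, duration = 12)
    expect_length(transitTimes(occupancy(ok, set), 100), 1)
})

test_that("transit times are run lengths over the sample rate", {
    expect_length(transitTimes(rep(0, 50), 100), 0)
    expect_equal(transitTimes(c(rep(0, 10), rep(1, 80), rep(0, 10)), 100),
                 0.8)
    expect_equal(transitTimes(c(0, 1, 1, 0, 0, 1, 1, 1, 0), 10),
                 c(0.2, 0.3))
    expect_error(transitTimes(c(0, 2, 1), 100), "binary")
})

test_that("peak mass is calibration times depression depth", {
    tr <- oneTransit(depth = 2)
    expect_equal(peakMass(traceValues(tr), 25), 50, tolerance = 0.01)
    expect_equal(peakMass(rep(3, 500), 25), 0)
    expect_error(peakMass(numeric(0), 25), "empty")
    # recovery study: mean over seeds within 2% of truth at SNR 10
    est <- vapply(1:200, function(s)
        peakMass(traceValues(oneTransit(depth = 2, noiseSd = 0.2,
                                        seed = s)), 25), numeric(1))
    expect_equal(mean(est), 50, tolerance = 0.02)
})

test_that("cells are matched across sensors in order", {
    # one cell, twelve sensors, exact gaps
    ev <- data.frame(sensor_id = 1:12, time = (0:11) * 120,
                     mass = 50 + (0:11) * 0.05)
    tr <- matchCells(ev, expectedGap = 120)
    expect_length(tr, 1)
    expect_identical(nrow(trajectoryPoints(tr[[1]])), 12L)
    # two cells closer than the tolerance are ambiguous: both dropped
    ev2 <- rbind(data.frame(sensor_id = 1, time = c(0, 5), mass = c(50, 60)),
                 data.frame(sensor_id = 2, time = c(120, 125),
                            mass = c(50, 60)))
    expect_length(matchCells(ev2, 120, tolerance = 24), 0)
    # well-separated cells both survive
    ev3 <- rbind(data.frame(sensor_id = 1, time = c(0, 60), mass = c(50, 60)),
                 data.frame(sensor_id = 2, time = c(120, 180),
                            mass = c(50, 60)))
    tr3 <- matchCells(ev3, 120, tolerance = 24)
    expect_length(tr3, 2)
    expect_error(matchCells(data.frame(sensor_id = c(1, 1),
                                       time = c(5, 1), mass = c(1, 2)),
                            120), "sorted")
})

test_that("matching failures follow the Poisson collision rate", {
    lam <- 0.05; tol <- 7.5; gap <- 120
    set.seed(31)
    nRep <- 6
    fracs <- vapply(seq_len(nRep), function(r) {
        t1 <- cumsum(rexp(400, lam))
        ev <- rbind(data.frame(sensor_id = 1, time = t1, mass = 50),
                    data.frame(sensor_id = 2, time = t1 + gap, mass = 50))
        tr <- matchCells(ev, gap, tolerance = tol)
        length(tr) / 400
    }, numeric(1))
    pExp <- exp(-lam * 2 * tol)       # matching window = 2 * tolerance
    se <- sd(fracs) / sqrt(nRep)
    expect_lt(abs(mean(fracs) - pExp), 3 * se + 0.01)
})

test_that("MAR is the least-squares slope with the right invariances", {
    tr <- CellTrajectory(data.frame(sensor_id = 1:4,
                                    time = c(0, 3600, 7200, 10800),
                                    mass = c(50, 50.5, 51, 51.5)))
    expect_equal(mar(tr), 0.5)
    expect_equal(marPerMass(tr), 0.5 / 50)
    flat <- CellTrajectory(data.frame(sensor_id = 1:3,
                                      time = c(0, 60, 120),
                                      mass = rep(42, 3)))
    expect_equal(mar(flat), 0)
    expect_error(mar(CellTrajectory(data.frame(sensor_id = 1, time = 0,
                                               mass = 50))),
                 "insufficient-data")
    # time-origin shift invariance, mass-unit equivariance
    sh <- CellTrajectory(data.frame(sensor_id = 1:4,
                                    time = c(0, 3600, 7200, 10800) + 500,
                                    mass = c(50, 50.5, 51, 51.5)))
    expect_equal(mar(sh), mar(tr))
    sc <- CellTrajectory(data.frame(sensor_id = 1:4,
                                    time = c(0, 3600, 7200, 10800),
                                    mass = 10 * c(50, 50.5, 51, 51.5)))
    expect_equal(mar(sc), 10 * mar(tr))
})

test_that("slope recovery over noisy trajectories is essentially unbiased", {
    trs <- synthTrajectories(500, seed = 17)
    est <- vapply(trs, mar, numeric(1))
    bias <- mean(est - attr(trs, "trueMar"))
    expect_lt(abs(bias) / mean(attr(trs, "trueMar")), 0.01)
    tab <- trajectoryTable(trs)
    expect_identical(nrow(tab), 500L)
    expect_equal(tab$mar_per_mass_per_h,
                 tab$mar_pg_per_h / tab$mass_pg)
})
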