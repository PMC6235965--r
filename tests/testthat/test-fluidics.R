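# Event-driven simulator: population statistics, passive/active runs,
# conservation, spacing, overshoot.

test_that("population arrivals are Poisson with rate c*Q", {
    # closed-form moments: lambda*T = 50 uL^-1 * 1e-4 uL/s * 1e5 s = 500
    counts <- vapply(1:300, function(s) {
        cfg <- SimulationConfig(concentration = 50, measurementFlow = 1e-4,
                                duration = 1e5, seed = s)
        pop <- generatePopulation(cfg, "passive")
        sum(pop$created_at <= cfg@duration)
    }, numeric(1))
    expect_equal(mean(counts), 500, tolerance = 0.02)    # ~3 SE
    expect_equal(var(counts), 500, tolerance = 0.25)     # ~3 SE of variance
})

test_that("population generation is seeded, typed and validated", {
    cfg <- quickConfig(concentration = 100, debrisFraction = 0.3,
                       doubletFraction = 0.1, duration = 5e4)
    p1 <- generatePopulation(cfg)
    p2 <- generatePopulation(cfg)
    expect_identical(p1, p2)
    expect_false(any(duplicated(p1$id)))
    expect_true(all(p1$size_um > 0))
    fr <- table(p1$kind) / nrow(p1)
    expect_equal(unname(fr[["debris"]]), 0.3, tolerance = 0.15)
    # zero concentration gives an empty population
    expect_identical(
        nrow(generatePopulation(quickConfig(concentration = 0))), 0L)
    expect_error(SimulationConfig(duration = -5), "positive")
    expect_error(SimulationConfig(debrisFraction = 0.7,
                                  doubletFraction = 0.5), "fraction",
                 ignore.case = TRUE)
})

test_that("passive loading applies the matching-window rule", {
    # a single particle in the channel is one measurement, no intervals
    cfg <- SimulationConfig(concentration = 2, measurementFlow = 5e-5,
                            duration = 12000, seed = 5)
    res <- runPassive(cfg)
    expect_equal(throughput(res),
                 3600 * nrow(loadedEvents(res)) / cfg@duration)
    if (nrow(loadedEvents(res)) == 1)
        expect_length(interLoadIntervals(res), 0)
    # dilute limit: essentially every arrival is measurable
    frac <- vapply(1:10, function(s) {
        cfg <- SimulationConfig(concentration = 5, duration = 3600, seed = s)
        r <- runPassive(cfg)
        n <- nrow(loadedEvents(r)) + nrow(rejectedEvents(r))
        if (n == 0) return(NA_real_)
        nrow(loadedEvents(r)) / n
    }, numeric(1))
    expect_gt(mean(frac, na.rm = TRUE), 0.99)
    # conservation
    expect_identical(nrow(loadedEvents(res)) + nrow(rejectedEvents(res)) +
                     res@nRemaining, res@nGenerated)
})

test_that("passive simulation matches the closed form within 3 SE", {
    p <- ThroughputParams()
    for (cc in c(50, 1000)) {
        thr <- vapply(1:10, function(s)
            throughput(runPassive(SimulationConfig(concentration = cc,
                                                   duration = 3600,
                                                   seed = s))), numeric(1))
        se <- max(sd(thr) / sqrt(length(thr)), 1e-9)
        expect_lt(abs(mean(thr) - passiveThroughput(cc, p)),
                  3 * se + 0.002 * passiveThroughput(cc, p))
    }
})

test_that("active loading spaces accepted loads by the duty cycle", {
    cfg <- SimulationConfig(concentration = 100, duration = 3600,
                            dutyCycle = 15, seed = 2)
    res <- runActive(cfg)
    expect_s4_class(res, "SimResult")
    expect_true(all(interLoadIntervals(res) >=
                    cfg@dutyCycle - 1 / cfg@cameraFps))
    expect_identical(nrow(loadedEvents(res)) + nrow(rejectedEvents(res)) +
                     res@nRemaining, res@nGenerated)
    # byte-identical logs under the same seed
    res2 <- runActive(cfg)
    expect_identical(eventLog(res), eventLog(res2))
})

test_that("a pure-debris sample produces only rejections", {
    cfg <- SimulationConfig(concentration = 100, duration = 1800,
                            debrisFraction = 1, seed = 3)
    res <- runActive(cfg)
    expect_identical(nrow(loadedEvents(res)), 0L)
    expect_gt(nrow(rejectedEvents(res)), 0L)
    expect_true(all(grepl("debris", rejectedEvents(res)$reason)))
})

test_that("doublets and debris are rejected by geometry, cells accepted", {
    cfg <- SimulationConfig(concentration = 100, duration = 3600,
                            debrisFraction = 0.2, doubletFraction = 0.2,
                            seed = 8)
    res <- runActive(cfg)
    expect_true(all(loadedEvents(res)$kind == "cell"))
    expect_gt(nrow(rejectedEvents(res)), 0)
})

test_that("overshoot model scales with latency and slows loading", {
    expect_equal(overshootDistance(1000, 0), 0)
    expect_equal(overshootDistance(1000, 0.05), 50)
    expect_equal(overshootDistance(800, 0.1), 80)
    set.seed(1)
    d <- overshootDistance(1000, 0.05, model = "lognormal", n = 2000)
    expect_equal(mean(d), 50, tolerance = 0.05)

    # paired seeds: latency strictly increases the mean inter-load time
    for (s in 1:3) {
        fast <- runActive(SimulationConfig(concentration = 10,
                                           duration = 3600,
                                           pneumaticLatency = 0, seed = s))
        slow <- runActive(SimulationConfig(concentration = 10,
                                           duration = 3600,
                                           pneumaticLatency = 0.05,
                                           seed = s))
        expect_gt(mean(interLoadIntervals(slow)),
                  mean(interLoadIntervals(fast)))
        expect_identical(fast@overshootCount, 0L)
        expect_gt(slow@overshootCount, 0L)
    }
})

test_that("a low frame rate for the seek velocity is flagged, not fatal", {
    cfg <- SimulationConfig(concentration = 10, duration = 60,
                            cameraFps = 2, seekFlowMultiplier = 1000,
                            measurementFlow = 5e-4)
    expect_warning(runActive(cfg), "frame rate")
})
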