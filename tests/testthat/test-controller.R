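# Finite-state controller: transition table, verdicts, purity, duty cycle.

test_that("ROI-triggered transitions follow the transition table", {
    pol <- defaultPolicy(dutyCycle = 15)

    # seek hit switches to load with equal channel flows
    r <- onRoiEvent(ControllerState("SEEK"), roiEvent(1, 1.0), pol, 100)
    expect_identical(stateName(r$state), "LOAD")
    expect_identical(r$outcome, "seek-detect")
    expect_equal(r$command@sampling, r$command@measurement)

    # early ROI2 queues the particle, reversing the sampling flow only
    r <- onRoiEvent(ControllerState("LOAD"), roiEvent(2, 5), pol, 5)
    expect_identical(stateName(r$state), "QUEUE")
    expect_identical(r$outcome, "queued")
    expect_lt(r$command@sampling, 0)
    expect_gt(r$command@measurement, 0)

    # with the duty cycle elapsed the particle is admitted, no queue
    r <- onRoiEvent(ControllerState("LOAD"), roiEvent(2, 16), pol, 16)
    expect_identical(stateName(r$state), "LOAD")
    expect_identical(r$outcome, "admitted")

    # entry (ROI4) arms the verdict; a passing ROI3 verdict starts the next
    # seek cycle, a failing one switches to reject with reversed
    # measurement flow
    r <- onRoiEvent(ControllerState("LOAD"), roiEvent(4, 16.1), pol, 16.1)
    expect_true(r$state@awaitingVerdict)
    ok <- detectedParticle(area = (pol@areaMin + pol@areaMax) / 2, 1.0)
    r2 <- onRoiEvent(r$state, roiEvent(3, 16.1, ok), pol, 16.1)
    expect_identical(stateName(r2$state), "SEEK")
    expect_identical(r2$outcome, "accepted")
    bad <- detectedParticle(area = 2 * pol@areaMax, 1.0)
    r3 <- onRoiEvent(r$state, roiEvent(3, 16.1, bad), pol, 16.1)
    expect_identical(stateName(r3$state), "REJECT")
    expect_lt(r3$command@measurement, 0)

    # transient dwell expiries
    expect_identical(stateName(onExpiry(ControllerState("QUEUE"))$state),
                     "LOAD")
    expect_identical(stateName(onExpiry(ControllerState("REJECT"))$state),
                     "SEEK")
    expect_error(onExpiry(ControllerState("LOAD")), "no timed dwell")

    # the exported table matches the implemented outcomes
    tab <- transitionTable()
    expect_setequal(tab$state[tab$trigger == "timer"], c("QUEUE", "REJECT"))
    expect_identical(tab$next_state[tab$trigger == "ROI1"], "LOAD")
})

test_that("invalid events are rejected with protocol errors", {
    pol <- defaultPolicy()
    expect_error(roiEvent(5), "invalid-event")
    expect_error(roiEvent(0), "invalid-event")
    expect_error(
        onRoiEvent(ControllerState("LOAD"), roiEvent(3, 1, NULL), pol, 1),
        "protocol-order")
    st <- onRoiEvent(ControllerState("LOAD"), roiEvent(4, 1), pol, 20)$state
    expect_error(onRoiEvent(st, roiEvent(3, 1, NULL), pol, 20),
                 "geometry")
})

test_that("geometry verdict is deterministic and threshold-inclusive", {
    pol <- defaultPolicy(areaMin = 60, areaMax = 300, xyRatioMax = 1.5)
    mid <- (60 + 300) / 2
    expect_identical(verdict(detectedParticle(mid, 1.0), pol), "accept")
    expect_identical(verdict(detectedParticle(600, 1.0), pol), "reject")
    # inclusive at both boundaries
    expect_identical(verdict(detectedParticle(300, 1.5), pol), "accept")
    expect_identical(verdict(detectedParticle(60, 1.0), pol), "accept")
    expect_identical(verdict(detectedParticle(59.99, 1.0), pol), "reject")
    expect_identical(verdict(detectedParticle(mid, 1.51), pol), "reject")
    expect_error(verdict(detectedParticle(-3, 1.0), pol),
                 "invalid-geometry")
    # optional contrast bound
    polC <- defaultPolicy(minContrast = 20)
    expect_identical(
        verdict(detectedParticle(mid, 1.0, meanContrast = 10), polC),
        "reject")
    expect_identical(
        verdict(detectedParticle(mid, 1.0, meanContrast = 25), polC),
        "accept")
})

test_that("flow commands implement the four fluidic states", {
    qm <- 5e-5 * 1e3
    expect_equal(flowCommand("LOAD")@sampling, qm)
    expect_equal(flowCommand("SEEK")@sampling, 20 * qm)
    expect_equal(flowCommand("SEEK")@measurement, qm)
    expect_equal(flowCommand("QUEUE")@sampling, -20 * qm)
    expect_equal(flowCommand("QUEUE")@measurement, qm)
    expect_equal(flowCommand("REJECT")@measurement, -qm)
    expect_gt(flowCommand("REJECT")@sampling, 0)
})

test_that("the controller is pure and replays deterministically", {
    pol <- defaultPolicy()
    ev <- roiEvent(1, 2.0)
    r1 <- onRoiEvent(ControllerState("SEEK"), ev, pol, 30)
    r2 <- onRoiEvent(ControllerState("SEEK"), ev, pol, 30)
    expect_identical(r1$outcome, r2$outcome)
    expect_identical(stateName(r1$state), stateName(r2$state))

    events <- dutyHarnessEvents(400, pol, seed = 42)
    log1 <- replayEvents(events, pol, initial = "SEEK")
    log2 <- replayEvents(events, pol, initial = "SEEK")
    expect_identical(log1, log2)
})

test_that("rejects are entered only via failed verdicts and exit to seek", {
    pol <- defaultPolicy()
    events <- dutyHarnessEvents(2000, pol, seed = 7, acceptProb = 0.5)
    log <- replayEvents(events, pol, initial = "SEEK")
    enter <- which(log$state_after == "REJECT" &
                   log$state_before != "REJECT")
    expect_true(all(log$outcome[enter] == "rejected"))
    expect_true(all(log$roi_id[enter] == 3L))
    # every reject dwell ends in SEEK
    leave <- which(log$state_before == "REJECT" &
                   log$state_after != "REJECT")
    expect_true(all(log$state_after[leave] == "SEEK"))
})
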