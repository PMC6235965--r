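# Frame synthesis, detection geometry, stream classification.

discScene <- function(cx = 30, cy = 20, d = 12, contrast = 40,
                      noiseSd = 0, ecc = 0, angle = 0) {
    sceneSpec(data.frame(kind = "cell", cx = cx, cy = cy, diameter = d,
                         eccentricity = ecc, angle = angle,
                         contrast = contrast), noiseSd = noiseSd)
}

test_that("rendering is deterministic and respects scene bounds", {
    bgOnly <- renderFrame(sceneSpec(noiseSd = 0), c(40, 60))
    expect_true(all(pixels(bgOnly) == 200))
    f1 <- renderFrame(discScene(noiseSd = 2), c(40, 60), seed = 9)
    f2 <- renderFrame(discScene(noiseSd = 2), c(40, 60), seed = 9)
    expect_identical(pixels(f1), pixels(f2))
    f3 <- renderFrame(discScene(noiseSd = 2), c(40, 60), seed = 10)
    expect_false(identical(pixels(f1), pixels(f3)))
    expect_error(renderFrame(discScene(cx = 58), c(40, 60)), "scene error")
    expect_true(all(pixels(f1) >= 0 & pixels(f1) <= 255))
})

test_that("a rendered disc is detected with its analytic geometry", {
    fr <- renderFrame(discScene(), c(40, 60))
    bg <- renderFrame(sceneSpec(noiseSd = 0), c(40, 60))
    det <- detectParticles(fr, roiSpec(3, 0, 0, 60, 40), bg,
                           threshold = 20)
    expect_identical(nrow(det), 1L)
    expect_equal(det$area, pi * 6^2, tolerance = 0.15)
    expect_equal(det$xy_ratio, 1, tolerance = 0.05)
    expect_equal(det$centroid_x, 30, tolerance = 0.5)
    expect_equal(det$centroid_y, 20, tolerance = 0.5)
    # blank frame and out-of-ROI object give no detections
    expect_identical(nrow(detectParticles(bg, roiSpec(3, 0, 0, 60, 40),
                                          bg)), 0L)
    expect_identical(nrow(detectParticles(fr, roiSpec(1, 45, 0, 60, 40),
                                          bg)), 0L)
    expect_error(detectParticles(fr, roiSpec(1, 0, 0, 10, 10),
                                 matrix(200, 10, 10)), "shape")
})

test_that("noiseless ellipse areas track the analytic area", {
    for (ecc in c(0, 0.6, 0.8)) {
        a <- 8; b <- a * sqrt(1 - ecc^2)
        fr <- renderFrame(discScene(cx = 30, cy = 25, d = 16, ecc = ecc),
                          c(50, 60))
        bg <- renderFrame(sceneSpec(noiseSd = 0), c(50, 60))
        det <- detectParticles(fr, roiSpec(3, 0, 0, 60, 50), bg,
                               threshold = 20)
        perim <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
        expect_lt(abs(det$area - pi * a * b), 2 * perim)
        expect_equal(det$xy_ratio, a / b, tolerance = 0.25)
    }
})

test_that("detection is translation-equivariant", {
    sc1 <- discScene(cx = 25, cy = 18)
    sc2 <- discScene(cx = 25 + 9, cy = 18 + 6)
    bg <- renderFrame(sceneSpec(noiseSd = 0), c(50, 70))
    d1 <- detectParticles(renderFrame(sc1, c(50, 70)),
                          roiSpec(1, 10, 5, 45, 35), bg, threshold = 20)
    d2 <- detectParticles(renderFrame(sc2, c(50, 70)),
                          roiSpec(1, 19, 11, 54, 41), bg, threshold = 20)
    expect_equal(d1$area, d2$area)
    expect_equal(d1$xy_ratio, d2$xy_ratio)
    expect_equal(d2$centroid_x - d1$centroid_x, 9)
    expect_equal(d2$centroid_y - d1$centroid_y, 6)
})

test_that("diagonally touching pixels form one 8-connected component", {
    m <- matrix(200, 20, 20)
    m[5, 5] <- m[6, 6] <- m[7, 7] <- 100     # diagonal chain
    det <- detectParticles(m, roiSpec(1, 0, 0, 20, 20),
                           matrix(200, 20, 20), threshold = 50,
                           minArea = 1)
    expect_identical(nrow(det), 1L)
    expect_equal(det$area, 3)
})

test_that("stream classification deduplicates multi-frame crossings", {
    bg <- renderFrame(sceneSpec(noiseSd = 0), c(40, 80))
    # one cell drifting through ROI 1 over five frames
    frames <- lapply(0:4, function(k)
        renderFrame(discScene(cx = 20 + 3 * k, cy = 20, noiseSd = 1),
                    c(40, 80), timestamp = k / 60, seed = 100 + k))
    ev <- classifyStream(frames, roiSpec(1, 5, 5, 75, 35),
                         defaultPolicy(), bg)
    expect_identical(nrow(ev), 1L)
    expect_identical(ev$roi_id, 1L)
    expect_true(is.na(ev$verdict))
})

test_that("a doublet merges into one oversized component and is rejected", {
    pol <- defaultPolicy()
    ob <- data.frame(kind = "doublet", diameter_px = 15, eccentricity = 0,
                     contrast = 40)
    bg <- renderFrame(sceneSpec(noiseSd = 0), c(60, 80))
    fr <- renderFrame(objectScene(ob), c(60, 80), seed = 5)
    det <- detectParticles(fr, roiSpec(3, 0, 0, 80, 60), bg)
    expect_identical(nrow(det), 1L)       # merged, not two objects
    expect_gt(det$xy_ratio, pol@xyRatioMax)
    expect_identical(verdict(det, pol), "reject")
    ev <- classifyStream(list(fr), roiSpec(3, 0, 0, 80, 60), pol, bg)
    expect_identical(ev$verdict, "reject")
})

test_that("labeled synthetic streams classify at >= 95% accuracy", {
    pol <- defaultPolicy()
    objs <- sampleObjectStream(200, cellFraction = 0.7,
                               debrisFraction = 0.3, seed = 11)
    got <- vapply(seq_len(nrow(objs)), function(i)
        classifyObject(objs[i, ], pol, seed = 1000 + i), character(1))
    want <- ifelse(objs$kind == "cell", "accept", "reject")
    acc <- mean(!is.na(got) & got == want)
    expect_gte(acc, 0.95)
})
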