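## Synthetic bright-field frames and the detection/classification pipeline
## behind ROI events and the accept/reject verdict.
##
## Conventions: pixel origin top-left, x to the right (columns), y down
## (rows); ROI rectangles are half-open [x0, x1) x [y0, y1) in 0-based pixel
## coordinates, so membership is unambiguous. Objects are dark ellipses on a
## bright background with additive Gaussian noise; detection thresholds
## |frame - background| so that bright or dark objects both register.

#' Build a scene specification
#'
#' @param objects data.frame with one row per object: `kind` (cell, debris,
#'   doublet or bead), `cx`, `cy` (center, 0-based px), `diameter` (px),
#'   `eccentricity` in \[0, 1) (semi-minor axis `= a * sqrt(1 - e^2)`),
#'   `angle` (radians, major-axis orientation) and `contrast` (intensity
#'   drop).
#' @param background Background intensity level (default 200).
#' @param noiseSd Additive Gaussian noise sd (>= 0).
#' @return A list of class `SceneSpec`.
#' @examples
#' sceneSpec(data.frame(kind = "cell", cx = 30, cy = 20, diameter = 12,
#'                      eccentricity = 0, angle = 0, contrast = 40))
#' @export
sceneSpec <- function(objects = NULL, background = 200, noiseSd = 2) {
    if (is.null(objects))
        objects <- data.frame(kind = character(), cx = numeric(),
                              cy = numeric(), diameter = numeric(),
                              eccentricity = numeric(), angle = numeric(),
                              contrast = numeric())
    stopifnot(noiseSd >= 0,
              all(c("kind", "cx", "cy", "diameter", "contrast") %in%
                  names(objects)))
    if (is.null(objects$eccentricity)) objects$eccentricity <- 0
    if (is.null(objects$angle)) objects$angle <- 0
    structure(list(objects = objects, background = background,
                   noiseSd = noiseSd), class = "SceneSpec")
}

#' Define an ROI rectangle
#'
#' @param roiId Integer id 1-4.
#' @param x0,y0,x1,y1 Half-open rectangle bounds in 0-based pixel
#'   coordinates.
#' @return One-row data.frame.
#' @examples
#' roiSpec(1, 10, 0, 40, 30)
#' @export
roiSpec <- function(roiId, x0, y0, x1, y1) {
    stopifnot(roiId %in% 1:4, x0 < x1, y0 < y1)
    data.frame(roi_id = as.integer(roiId), x0 = x0, y0 = y0, x1 = x1,
               y1 = y1)
}

#' Render a synthetic bright-field frame
#'
#' Dark elliptical objects on a bright background with additive Gaussian
#' noise, clamped to \[0, 255\]. Deterministic under `seed`.
#'
#' @param scene A [sceneSpec()].
#' @param frameShape Integer (rows, cols) = (height, width) in px.
#' @param pixelPitch um per pixel.
#' @param timestamp Frame time in seconds.
#' @param seed Integer seed for the noise draw.
#' @return A [Frame()].
#' @examples
#' sc <- sceneSpec(data.frame(kind = "cell", cx = 30, cy = 20, diameter = 12,
#'                            eccentricity = 0, angle = 0, contrast = 40))
#' renderFrame(sc, c(40, 60), seed = 1)
#' @export
renderFrame <- function(scene, frameShape = c(60, 80), pixelPitch = 0.8,
                        timestamp = 0, seed = 1) {
    stopifnot(inherits(scene, "SceneSpec"))
    h <- frameShape[1]; w <- frameShape[2]
    px <- matrix(scene$background, nrow = h, ncol = w)
    ob <- scene$objects
    for (i in seq_len(nrow(ob))) {
        a <- ob$diameter[i] / 2
        ecc <- ob$eccentricity[i]
        b <- a * sqrt(1 - ecc^2)
        if (ob$cx[i] - a < -0.5 || ob$cx[i] + a > w - 0.5 ||
            ob$cy[i] - a < -0.5 || ob$cy[i] + a > h - 0.5)
            stop("scene error: object ", i, " extends beyond the frame")
        xs <- rep(0:(w - 1), each = h) - ob$cx[i]
        ys <- rep(0:(h - 1), times = w) - ob$cy[i]
        co <- cos(ob$angle[i]); si <- sin(ob$angle[i])
        u <- xs * co + ys * si
        v <- -xs * si + ys * co
        inside <- (u / a)^2 + (v / b)^2 <= 1
        px[inside] <- px[inside] - ob$contrast[i]
    }
    if (scene$noiseSd > 0)
        px <- px + withSeed(seed, rnorm(h * w, 0, scene$noiseSd))
    px <- round(pmin(pmax(px, 0), 255))
    Frame(px, pixelPitch = pixelPitch, timestamp = timestamp)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with a union-find pass over the label adjacency.
.label8 <- function(mask) {
    lab <- EBImage::bwlabel(mask)
    nl <- max(lab)
    if (nl < 2) return(lab)
    h <- nrow(lab); w <- ncol(lab)
    pairs <- rbind(
        cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
        cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))   # up-right
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    parent <- seq_len(nl)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(nrow(pairs))) {
        a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(nl), find, integer(1))
    dense <- match(root, sort(unique(root)))
    out <- lab
    out[lab > 0] <- dense[lab[lab > 0]]
    out
}

#' Detect particles inside an ROI
#'
#' Background subtraction, absolute-intensity thresholding, 8-connected
#' component labeling, and per-component geometry: centroid, area,
#' bounding-box x-y ratio (max/min extent, orientation-free), and mean
#' contrast. Only pixels inside the half-open ROI rectangle participate.
#'
#' @param frame A [Frame()].
#' @param roi An [roiSpec()] row.
#' @param background A [Frame()] (or matrix) of the empty channel, same
#'   shape.
#' @param threshold Absolute intensity-delta threshold.
#' @param minArea Minimum component area in px^2.
#' @return data.frame with columns `centroid_x`, `centroid_y`, `area`,
#'   `xy_ratio`, `mean_contrast`, one row per detected particle.
#' @examples
#' sc <- sceneSpec(data.frame(kind = "cell", cx = 30, cy = 20, diameter = 12,
#'                            eccentricity = 0, angle = 0, contrast = 40),
#'                 noiseSd = 0)
#' fr <- renderFrame(sc, c(40, 60))
#' bg <- renderFrame(sceneSpec(noiseSd = 0), c(40, 60))
#' detectParticles(fr, roiSpec(3, 0, 0, 60, 40), bg, threshold = 20)
#' @export
detectParticles <- function(frame, roi, background, threshold = 15,
                            minArea = 3) {
    px <- if (is(frame, "Frame")) frame@pixels else frame
    bg <- if (is(background, "Frame")) background@pixels else background
    if (!all(dim(px) == dim(bg)))
        stop("input error: frame and background shapes differ")
    diffImg <- abs(px - bg)
    mask <- matrix(FALSE, nrow(px), ncol(px))
    rows <- (roi$y0 + 1):roi$y1
    cols <- (roi$x0 + 1):roi$x1
    mask[rows, cols] <- diffImg[rows, cols] >= threshold
    lab <- .label8(mask)
    nl <- max(lab)
    out <- data.frame(centroid_x = numeric(), centroid_y = numeric(),
                      area = numeric(), xy_ratio = numeric(),
                      mean_contrast = numeric())
    if (nl == 0) return(out)
    idx <- which(lab > 0, arr.ind = TRUE)
    lv <- lab[lab > 0]
    for (l in seq_len(nl)) {
        sel <- lv == l
        n <- sum(sel)
        if (n < minArea) next
        ys <- idx[sel, 1] - 1; xs <- idx[sel, 2] - 1   # 0-based
        ext <- c(diff(range(xs)) + 1, diff(range(ys)) + 1)
        out <- rbind(out, data.frame(
            centroid_x = mean(xs), centroid_y = mean(ys), area = n,
            xy_ratio = max(ext) / min(ext),
            mean_contrast = mean(diffImg[lab == l])))
    }
    out
}

#' Classify a frame stream into ROI events
#'
#' Runs [detectParticles()] on every frame/ROI pair and deduplicates
#' multi-frame crossings by nearest-centroid tracking (a detection continues
#' an existing track when its centroid lies within `maxDisplacement` of the
#' track's last position; default half the ROI width). One event is emitted
#' per object per ROI crossing, at its first detection; ROI 3 events carry
#' the geometry and the [verdict()] under `policy`.
#'
#' @param frames List of [Frame()] objects, time-ordered.
#' @param rois data.frame of [roiSpec()] rows.
#' @param policy A [ControllerPolicy()] for ROI 3 verdicts.
#' @param background Background [Frame()] or matrix.
#' @param threshold,minArea Passed to [detectParticles()].
#' @param maxDisplacement Tracking gate in px; `NULL` for half ROI width.
#' @return data.frame of events: `time`, `roi_id`, `centroid_x`,
#'   `centroid_y`, `area`, `xy_ratio`, `mean_contrast`, `verdict` (NA
#'   except for ROI 3).
#' @export
classifyStream <- function(frames, rois, policy, background, threshold = 15,
                           minArea = 3, maxDisplacement = NULL) {
    times <- vapply(frames, function(f) f@timestamp, numeric(1))
    if (is.unsorted(times)) stop("frames must be time-ordered")
    events <- list()
    tracks <- list()    # per roi: data.frame(x, y, active)
    for (r in seq_len(nrow(rois)))
        tracks[[r]] <- data.frame(x = numeric(), y = numeric())
    for (f in seq_along(frames)) {
        for (r in seq_len(nrow(rois))) {
            roi <- rois[r, ]
            gate <- if (is.null(maxDisplacement)) (roi$x1 - roi$x0) / 2
                    else maxDisplacement
            det <- detectParticles(frames[[f]], roi, background, threshold,
                                   minArea)
            prev <- tracks[[r]]
            isNew <- rep(TRUE, nrow(det))
            if (nrow(det) && nrow(prev)) {
                for (d in seq_len(nrow(det))) {
                    dd <- sqrt((prev$x - det$centroid_x[d])^2 +
                               (prev$y - det$centroid_y[d])^2)
                    if (any(dd <= gate)) isNew[d] <- FALSE
                }
            }
            for (d in which(isNew)) {
                ev <- data.frame(time = times[f], roi_id = roi$roi_id,
                                 det[d, ], verdict = NA_character_)
                if (roi$roi_id == 3L)
                    ev$verdict <- verdict(det[d, ], policy)
                events[[length(events) + 1L]] <- ev
            }
            tracks[[r]] <- data.frame(x = det$centroid_x,
                                      y = det$centroid_y)
        }
    }
    if (!length(events))
        return(data.frame(time = numeric(), roi_id = integer(),
                          centroid_x = numeric(), centroid_y = numeric(),
                          area = numeric(), xy_ratio = numeric(),
                          mean_contrast = numeric(),
                          verdict = character()))
    out <- do.call(rbind, events)
    rownames(out) <- NULL
    out
}

#' Synthetic labeled object stream
#'
#' Draws `n` objects (cells, debris, doublets with the given fractions) with
#' the same geometry distributions the fluidic simulator uses, for
#' classifier validation against known labels. Doublets are rendered as two
#' overlapping discs (one merged component).
#'
#' @param n Number of objects.
#' @param cellFraction,debrisFraction,doubletFraction Mixture weights
#'   (normalized internally).
#' @param seed Integer seed.
#' @return data.frame: `kind`, `diameter_px`, `eccentricity`, `contrast`.
#' @examples
#' head(sampleObjectStream(10, seed = 1))
#' @export
sampleObjectStream <- function(n, cellFraction = 0.7, debrisFraction = 0.3,
                               doubletFraction = 0, seed = 1) {
    pr <- c(cellFraction, debrisFraction, doubletFraction)
    pr <- pr / sum(pr)
    withSeed(seed, {
        kind <- sample(c("cell", "debris", "doublet"), n, replace = TRUE,
                       prob = pr)
        dia <- numeric(n); ecc <- numeric(n); ctr <- numeric(n)
        isC <- kind == "cell"; isD <- kind == "debris"
        isB <- kind == "doublet"
        dia[isC] <- pmin(pmax(rnorm(sum(isC), 12, 1.2), 8.8), 15.2) /
            .PIXEL_PITCH
        dia[isD] <- pmin(pmax(rlnorm(sum(isD), log(4), 0.4), 3), 6) /
            .PIXEL_PITCH
        dia[isB] <- pmin(pmax(rnorm(sum(isB), 12, 1.2), 8.8), 15.2) /
            .PIXEL_PITCH
        ecc[isC] <- pmin(abs(rnorm(sum(isC), 0, 0.15)), 0.5)
        ecc[isD] <- pmin(0.75 + abs(rnorm(sum(isD), 0, 0.15)), 0.92)
        ecc[isB] <- 0
        ctr[isC | isB] <- rnorm(sum(isC | isB), 40, 5)
        ctr[isD] <- pmax(rnorm(sum(isD), 30, 5), 18)
        data.frame(kind = kind, diameter_px = dia, eccentricity = ecc,
                   contrast = ctr)
    })
}

#' Render one labeled object as a single-object scene
#'
#' Helper for classifier validation: places the object (or, for doublets,
#' the overlapping disc pair) at the given center.
#'
#' @param object One row of [sampleObjectStream()].
#' @param center (cx, cy) in 0-based px.
#' @param background,noiseSd Scene parameters.
#' @return A [sceneSpec()].
#' @export
objectScene <- function(object, center = c(40, 30), background = 200,
                        noiseSd = 2) {
    if (object$kind == "doublet") {
        off <- 0.35 * object$diameter_px
        ob <- data.frame(kind = "doublet",
                         cx = center[1] + c(-off, off),
                         cy = center[2],
                         diameter = object$diameter_px,
                         eccentricity = 0, angle = 0,
                         contrast = object$contrast)
    } else {
        ob <- data.frame(kind = object$kind, cx = center[1], cy = center[2],
                         diameter = object$diameter_px,
                         eccentricity = object$eccentricity,
                         angle = 0, contrast = object$contrast)
    }
    sceneSpec(ob, background = background, noiseSd = noiseSd)
}
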