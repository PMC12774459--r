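# Synthetic scenarios with known ground truth. ERM regions are defined
# in en face coordinates and inverse-projected to per-B-scan detections,
# so the projection round-trip is exactly checkable -- something real
# patient data cannot provide.

# pixel-centre rasterization of an en face shape (continuous coords,
# 0-based: pixel (r, c) has centre (c - 0.5, r - 0.5) in 1-based R terms)
.shapeMask <- function(shape, geometry) {
    h <- geometry@enfaceHeight
    w <- geometry@enfaceWidth
    xc <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
    yc <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
    if (shape$type == "rect") {
        xc >= shape$x0 & xc < shape$x1 & yc >= shape$y0 & yc < shape$y1
    } else {
        ((xc - shape$cx) / shape$rx)^2 + ((yc - shape$cy) / shape$ry)^2 <= 1
    }
}

.shapeBBox <- function(shape) {
    if (shape$type == "rect") {
        c(shape$x0, shape$x1, shape$y0, shape$y1)
    } else {
        c(
            shape$cx - shape$rx, shape$cx + shape$rx,
            shape$cy - shape$ry, shape$cy + shape$ry
        )
    }
}

.checkShapeInFrame <- function(shape, geometry) {
    bb <- .shapeBBox(shape)
    if (bb[1L] < 0 || bb[2L] > geometry@enfaceWidth ||
        bb[3L] < 0 || bb[4L] > geometry@enfaceHeight) {
        stop("ERM shape extends outside the en face frame")
    }
}

.shiftShape <- function(shape, dx) {
    if (shape$type == "rect") {
        shape$x0 <- shape$x0 + dx
        shape$x1 <- shape$x1 + dx
    } else {
        shape$cx <- shape$cx + dx
    }
    shape
}

# continuous along-axis extent of the shape over a perpendicular band
# [b0, b1); NULL when the band misses the shape
.shapeSpan <- function(shape, b0, b1, axis = c("x", "y")) {
    axis <- match.arg(axis)
    if (shape$type == "rect") {
        perp <- if (axis == "x") c(shape$y0, shape$y1) else c(shape$x0, shape$x1)
        along <- if (axis == "x") c(shape$x0, shape$x1) else c(shape$y0, shape$y1)
        if (perp[1L] >= b1 || perp[2L] <= b0) {
            return(NULL)
        }
        along
    } else {
        cPerp <- if (axis == "x") shape$cy else shape$cx
        rPerp <- if (axis == "x") shape$ry else shape$rx
        cAlong <- if (axis == "x") shape$cx else shape$cy
        rAlong <- if (axis == "x") shape$rx else shape$ry
        lo <- max(b0, cPerp - rPerp)
        hi <- min(b1, cPerp + rPerp)
        if (hi <= lo) {
            return(NULL)
        }
        pStar <- min(max(cPerp, lo), hi) # widest cross-section in band
        hw <- rAlong * sqrt(max(0, 1 - ((pStar - cPerp) / rPerp)^2))
        if (hw < 1e-6) {
            return(NULL)
        }
        c(cAlong - hw, cAlong + hw)
    }
}

# in-range (clinically relevant) thickened-retina mask of the blob field
.blobInRange <- function(spec, geometry, range = c(220, 500)) {
    tm <- genThicknessMap(spec, geometry, noise = FALSE)
    v <- tm@grid
    tm@validMask & v >= range[1L] & v <= range[2L]
}

# translate the ERM shape along +x until the fraction of the ERM region
# overlapping the in-range thickened retina matches the target
.shapeForOverlap <- function(spec, geometry) {
    target <- spec@overlapTarget
    shape <- spec@ermShape
    rir <- .blobInRange(spec, geometry)
    frac <- function(dx) {
        m <- .shapeMask(.shiftShape(shape, dx), geometry)
        sum(m & rir) / max(1L, sum(m))
    }
    bb <- .shapeBBox(shape)
    dxMax <- geometry@enfaceWidth - bb[2L] # stay inside the frame
    f0 <- frac(0)
    fFar <- frac(dxMax)
    if (target > f0 + 1e-9 || target < fFar - 1e-9) {
        stop(sprintf(
            "overlap target %.2f not attainable (reachable range [%.3f, %.3f])",
            target, fFar, f0
        ))
    }
    lo <- 0
    hi <- dxMax
    for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (frac(mid) >= target) lo <- mid else hi <- mid
    }
    .shiftShape(shape, lo)
}

#' Generate per-B-scan detections from a synthetic ERM region
#'
#' For every scan line whose band intersects the ERM shape, the bounding
#' interval of the intersection is computed in en face coordinates and
#' inverse-mapped through the linear coordinate scaling back to B-scan
#' pixels. Deterministic given the spec.
#'
#' @param spec a \linkS4class{ScenarioSpec}; if its
#'   \code{overlapTarget} is set, the ERM shape is first translated
#'   along x until that fraction of it overlaps the in-range thickened
#'   retina.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param confidence confidence assigned to every emitted detection.
#' @return a \linkS4class{DetectionSet}.
#' @examples
#' spec <- ScenarioSpec(ermShape = list(
#'     type = "rect", x0 = 100, x1 = 300, y0 = 0, y1 = 19
#' ))
#' genDetections(spec) # one horizontal detection (scan 0) + verticals
#' @export
genDetections <- function(spec, geometry = ScanGeometry(),
                          confidence = 0.9) {
    stopifnot(is(spec, "ScenarioSpec"))
    validObject(spec)
    shape <- if (is.na(spec@overlapTarget)) {
        spec@ermShape
    } else {
        .shapeForOverlap(spec, geometry)
    }
    .checkShapeInFrame(shape, geometry)
    rows <- list()
    for (orientation in c("horizontal", "vertical")) {
        axis <- if (orientation == "horizontal") "x" else "y"
        extent <- if (orientation == "horizontal") {
            geometry@enfaceWidth
        } else {
            geometry@enfaceHeight
        }
        for (k in seq_len(geometry@nScans) - 1L) {
            band <- scanBand(k, orientation, geometry)
            span <- .shapeSpan(shape, band[["start"]], band[["end"]], axis)
            if (is.null(span)) next
            span <- c(max(0, span[1L]), min(extent, span[2L]))
            if (span[2L] <= span[1L]) next
            rows[[length(rows) + 1L]] <- data.frame(
                orientation = orientation, scanIndex = k,
                x0 = span[1L] * geometry@bscanWidth / extent,
                x1 = span[2L] * geometry@bscanWidth / extent,
                confidence = confidence, stringsAsFactors = FALSE
            )
        }
    }
    d <- if (length(rows)) {
        do.call(rbind, rows)
    } else {
        data.frame(
            orientation = character(), scanIndex = integer(),
            x0 = numeric(), x1 = numeric(), confidence = numeric()
        )
    }
    new("DetectionSet", detections = d, geometry = geometry)
}

#' Generate a smooth synthetic thickness map
#'
#' A radial paraboloid blob:
#' \code{background + (peak - background) * max(0, 1 - d^2)} with
#' \code{d} the normalized elliptical distance from the blob centre,
#' evaluated at pixel centres, plus optional Gaussian noise seeded from
#' the spec.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param noise add Gaussian noise of sd \code{thicknessBlob$noiseSd}
#'   (default TRUE; ignored when the sd is 0 or unset).
#' @return a \linkS4class{ThicknessMap}.
#' @examples
#' tm <- genThicknessMap(ScenarioSpec())
#' range(thicknessValues(tm))
#' @export
genThicknessMap <- function(spec, geometry = ScanGeometry(), noise = TRUE) {
    stopifnot(is(spec, "ScenarioSpec"))
    b <- spec@thicknessBlob
    h <- geometry@enfaceHeight
    w <- geometry@enfaceWidth
    xc <- matrix(rep(seq_len(w) - 0.5, each = h), nrow = h)
    yc <- matrix(rep(seq_len(h) - 0.5, times = w), nrow = h)
    d2 <- ((xc - b$cx) / b$rx)^2 + ((yc - b$cy) / b$ry)^2
    grid <- b$background + (b$peak - b$background) * pmax(1 - d2, 0)
    sdNoise <- if (is.null(b$noiseSd)) 0 else b$noiseSd
    if (noise && sdNoise > 0) {
        set.seed(spec@seed)
        grid <- pmax(grid + matrix(stats::rnorm(h * w, 0, sdNoise), h, w), 0)
    }
    ThicknessMap(grid, geometry = geometry)
}

#' Generate synthetic observer ratings
#'
#' Each case draws a latent quality score from
#' \code{N(latentMean, latentSd)}; each rater reports
#' \code{round(latent + raterShift + N(0, noiseSd))} clipped to the
#' 1..5 Likert range. Deterministic given the spec seed.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @param nCases number of cases (default 30).
#' @return an \linkS4class{ObserverStudy}.
#' @examples
#' genRatings(ScenarioSpec(seed = 42), nCases = 30)
#' @export
genRatings <- function(spec, nCases = 30L) {
    stopifnot(is(spec, "ScenarioSpec"))
    rm <- spec@ratingModel
    if (any(rm$latentMean < 1) || any(rm$latentMean > 5)) {
        stop("rating model mean must lie in [1, 5]")
    }
    set.seed(spec@seed)
    latent <- stats::rnorm(nCases, rm$latentMean, rm$latentSd)
    nr <- length(rm$raterShift)
    m <- vapply(seq_len(nr), function(r) {
        raw <- latent + rm$raterShift[r] +
            stats::rnorm(nCases, 0, rm$noiseSd)
        as.integer(pmin(5L, pmax(1L, round(raw))))
    }, integer(nCases))
    colnames(m) <- paste0("rater", seq_len(nr))
    ObserverStudy(m)
}

#' Write a complete synthetic scenario directory
#'
#' Emits everything a full pipeline run consumes: detection files in
#' both dialects (YOLO-style txt directory and a JSON manifest), the
#' thickness map as CSV and 16-bit TIFF, an observer ratings CSV, and a
#' ground-truth JSON recording the seed, the true en face shape pixel
#' count and the measured ERM / thickened-retina overlap fraction.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @param dir output directory (created if missing).
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param nCases observer-study size.
#' @return invisibly, a list with the generated objects and file paths.
#' @examples
#' \donttest{
#' out <- simulateScenario(ScenarioSpec(seed = 3), tempfile())
#' out$paths$manifest
#' }
#' @export
simulateScenario <- function(spec, dir, geometry = ScanGeometry(),
                             nCases = 30L) {
    stopifnot(is(spec, "ScenarioSpec"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dets <- genDetections(spec, geometry)
    tmap <- genThicknessMap(spec, geometry)
    study <- genRatings(spec, nCases)

    yoloDir <- file.path(dir, "detections_yolo")
    manifest <- file.path(dir, "detections.json")
    writeDetections(dets, yoloDir, dialect = "yolo_txt")
    writeDetections(dets, manifest, dialect = "json")
    csvPath <- file.path(dir, "thickness.csv")
    tifPath <- file.path(dir, "thickness.tif")
    writeThicknessMap(tmap, csvPath)
    writeThicknessMap(tmap, tifPath)
    ratingsPath <- file.path(dir, "ratings.csv")
    writeRatings(study, ratingsPath)

    shape <- if (is.na(spec@overlapTarget)) {
        spec@ermShape
    } else {
        .shapeForOverlap(spec, geometry)
    }
    truthMask <- .shapeMask(shape, geometry)
    rir <- .blobInRange(spec, geometry)
    truth <- list(
        seed = spec@seed,
        shape = shape,
        trueShapePixels = sum(truthMask),
        trueOverlapFraction = sum(truthMask & rir) / max(1L, sum(truthMask)),
        nDetections = length(dets)
    )
    truthPath <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA)

    invisible(list(
        detections = dets, thickness = tmap, ratings = study, truth = truth,
        paths = list(
            yoloDir = yoloDir, manifest = manifest, thicknessCsv = csvPath,
            thicknessTiff = tifPath, ratings = ratingsPath, truth = truthPath
        )
    ))
}
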