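#' @import methods
NULL

#' Scan-pattern geometry of an SD-OCT acquisition
#'
#' Describes the raster geometry linking B-scans to the en face frame:
#' B-scan pixel dimensions, en face frame dimensions, and the number of
#' parallel scan lines per orientation. The default corresponds to a
#' device acquiring 768 x 496 pixel B-scans over a 496 x 496 en face
#' frame with 25 horizontal and 25 vertical scan lines.
#'
#' @slot bscanWidth integer, B-scan width in pixels (along-scan axis).
#' @slot bscanHeight integer, B-scan height in pixels (depth axis).
#' @slot enfaceWidth integer, en face frame width in pixels.
#' @slot enfaceHeight integer, en face frame height in pixels.
#' @slot nScans integer, number of scan lines per orientation.
#'
#' @export
setClass("ScanGeometry",
    representation(
        bscanWidth = "integer",
        bscanHeight = "integer",
        enfaceWidth = "integer",
        enfaceHeight = "integer",
        nScans = "integer"
    ),
    prototype(
        bscanWidth = 768L,
        bscanHeight = 496L,
        enfaceWidth = 496L,
        enfaceHeight = 496L,
        nScans = 25L
    )
)

setValidity("ScanGeometry", function(object) {
    v <- c(
        bscanWidth = object@bscanWidth, bscanHeight = object@bscanHeight,
        enfaceWidth = object@enfaceWidth, enfaceHeight = object@enfaceHeight,
        nScans = object@nScans
    )
    if (length(v) != 5L || anyNA(v)) {
        return("all geometry fields must be single non-missing integers")
    }
    if (any(v < 1L)) {
        return(sprintf(
            "geometry fields must be positive integers (got %s)",
            paste(names(v)[v < 1L], collapse = ", ")
        ))
    }
    TRUE
})

#' @param bscanWidth,bscanHeight B-scan dimensions in pixels.
#' @param enfaceWidth,enfaceHeight en face frame dimensions in pixels.
#' @param nScans number of scan lines per orientation.
#' @return \code{ScanGeometry()} returns a \code{ScanGeometry} object.
#' @examples
#' geom <- ScanGeometry()
#' geom
#' @rdname ScanGeometry-class
#' @export
ScanGeometry <- function(bscanWidth = 768L, bscanHeight = 496L,
                         enfaceWidth = 496L, enfaceHeight = 496L,
                         nScans = 25L) {
    new("ScanGeometry",
        bscanWidth = as.integer(bscanWidth),
        bscanHeight = as.integer(bscanHeight),
        enfaceWidth = as.integer(enfaceWidth),
        enfaceHeight = as.integer(enfaceHeight),
        nScans = as.integer(nScans)
    )
}

setMethod("show", "ScanGeometry", function(object) {
    cat(sprintf(
        "ScanGeometry: B-scan %d x %d px, en face %d x %d px, %d scans/orientation\n",
        object@bscanWidth, object@bscanHeight,
        object@enfaceWidth, object@enfaceHeight, object@nScans
    ))
})

#' A set of per-B-scan ERM bounding-box detections
#'
#' Holds the lateral extent of every ERM detection as a half-open pixel
#' interval \code{[x0, x1)} on the B-scan x-axis, together with the scan
#' index, scan orientation and detector confidence, plus the acquisition
#' geometry the coordinates refer to.
#'
#' @slot detections data.frame with columns \code{orientation}
#'   (\code{"horizontal"} or \code{"vertical"}), \code{scanIndex}
#'   (0-based), \code{x0}, \code{x1} (pixels, \code{0 <= x0 < x1 <=
#'   bscanWidth}) and \code{confidence} (in \code{[0, 1]}).
#' @slot geometry a \linkS4class{ScanGeometry}.
#'
#' @export
setClass("DetectionSet",
    representation(detections = "data.frame", geometry = "ScanGeometry")
)

setValidity("DetectionSet", function(object) {
    d <- object@detections
    g <- object@geometry
    needed <- c("orientation", "scanIndex", "x0", "x1", "confidence")
    if (!all(needed %in% names(d))) {
        return(sprintf(
            "detections must have columns %s",
            paste(needed, collapse = ", ")
        ))
    }
    if (nrow(d) == 0L) {
        return(TRUE)
    }
    if (!all(d$orientation %in% c("horizontal", "vertical"))) {
        return("orientation must be 'horizontal' or 'vertical'")
    }
    if (any(d$scanIndex < 0L) || any(d$scanIndex >= g@nScans)) {
        return(sprintf("scanIndex must lie in [0, %d)", g@nScans))
    }
    if (any(d$x0 < 0) || any(d$x1 > g@bscanWidth)) {
        return(sprintf("x coordinates must lie in [0, %d]", g@bscanWidth))
    }
    if (any(d$x0 >= d$x1)) {
        return("degenerate detection: x0 must be strictly less than x1")
    }
    if (any(d$confidence < 0) || any(d$confidence > 1)) {
        return("confidence must lie in [0, 1]")
    }
    TRUE
})

#' @param orientation character vector, \code{"horizontal"} or
#'   \code{"vertical"} per detection.
#' @param scanIndex integer vector of 0-based scan indices.
#' @param x0,x1 numeric vectors of B-scan x-coordinates in pixels,
#'   \code{x0 < x1}.
#' @param confidence numeric vector of detector confidences in
#'   \code{[0, 1]}.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @return \code{DetectionSet()} returns a \code{DetectionSet}.
#' @examples
#' ds <- DetectionSet(
#'     orientation = "horizontal", scanIndex = 12L,
#'     x0 = 100, x1 = 500, confidence = 0.9
#' )
#' length(ds)
#' @rdname DetectionSet-class
#' @export
DetectionSet <- function(orientation = character(), scanIndex = integer(),
                         x0 = numeric(), x1 = numeric(),
                         confidence = numeric(), geometry = ScanGeometry()) {
    n <- max(length(orientation), length(scanIndex), length(x0), length(x1))
    if (length(confidence) == 0L && n > 0L) {
        confidence <- rep(1, n)
    }
    d <- data.frame(
        orientation = as.character(orientation),
        scanIndex = as.integer(scanIndex),
        x0 = as.numeric(x0),
        x1 = as.numeric(x1),
        confidence = as.numeric(confidence),
        stringsAsFactors = FALSE
    )
    new("DetectionSet", detections = d, geometry = geometry)
}

#' @rdname DetectionSet-class
#' @param x a \code{DetectionSet}.
#' @export
setMethod("length", "DetectionSet", function(x) nrow(x@detections))

#' @rdname DetectionSet-class
#' @param row.names,optional,... passed on as in
#'   \code{\link[base]{as.data.frame}}.
#' @export
setMethod(
    "as.data.frame", "DetectionSet",
    function(x, row.names = NULL, optional = FALSE, ...) x@detections
)

setMethod("show", "DetectionSet", function(object) {
    d <- object@detections
    cat(sprintf(
        "DetectionSet: %d detection(s) (%d horizontal, %d vertical)\n",
        nrow(d), sum(d$orientation == "horizontal"),
        sum(d$orientation == "vertical")
    ))
    show(object@geometry)
})

#' Epiretinal projection image (EPI) mask
#'
#' The en face ERM mask obtained by projecting every B-scan detection
#' onto the en face frame and merging the projected rectangles. The
#' \code{grid} slot is the binary union; \code{coverage} counts how many
#' detections contributed to each pixel.
#'
#' @slot grid logical matrix, \code{enfaceHeight x enfaceWidth}, TRUE at
#'   projected ERM pixels.
#' @slot coverage integer matrix of the same shape counting contributing
#'   detections per pixel.
#' @slot geometry the \linkS4class{ScanGeometry} the mask lives in.
#'
#' @seealso \code{\link{buildEPI}}
#' @export
setClass("EPIMask",
    representation(
        grid = "matrix", coverage = "matrix", geometry = "ScanGeometry"
    )
)

setValidity("EPIMask", function(object) {
    g <- object@geometry
    dims <- c(g@enfaceHeight, g@enfaceWidth)
    if (!identical(dim(object@grid), as.integer(dims))) {
        return("grid shape does not match geometry")
    }
    if (!identical(dim(object@coverage), as.integer(dims))) {
        return("coverage shape does not match geometry")
    }
    if (!is.logical(object@grid)) {
        return("grid must be logical")
    }
    if (any(object@coverage < 0L)) {
        return("coverage must be non-negative")
    }
    if (!identical(unname(object@grid), unname(object@coverage >= 1L))) {
        return("grid must equal coverage >= 1")
    }
    TRUE
})

setMethod("show", "EPIMask", function(object) {
    n <- sum(object@grid)
    tot <- length(object@grid)
    cat(sprintf(
        "EPIMask: %d x %d, %d ERM pixel(s) (%.2f%% of frame), max coverage %d\n",
        nrow(object@grid), ncol(object@grid), n, 100 * n / tot,
        max(object@coverage)
    ))
})

#' Retinal thickness map
#'
#' A per-pixel retinal thickness grid in micrometres registered to the
#' en face frame, with a validity mask marking measured pixels.
#'
#' @slot grid numeric matrix of thickness values in micrometres.
#' @slot validMask logical matrix marking measured pixels.
#' @slot geometry the \linkS4class{ScanGeometry}.
#'
#' @export
setClass("ThicknessMap",
    representation(
        grid = "matrix", validMask = "matrix", geometry = "ScanGeometry"
    )
)

setValidity("ThicknessMap", function(object) {
    g <- object@geometry
    dims <- as.integer(c(g@enfaceHeight, g@enfaceWidth))
    if (!identical(dim(object@grid), dims)) {
        return("thickness grid shape does not match geometry")
    }
    if (!identical(dim(object@validMask), dims) ||
        !is.logical(object@validMask)) {
        return("validMask must be a logical matrix matching geometry")
    }
    vals <- object@grid[object@validMask]
    if (length(vals) && (any(!is.finite(vals)) || any(vals < 0))) {
        return("valid thickness values must be finite and non-negative")
    }
    TRUE
})

#' @param grid numeric matrix of thickness values in micrometres.
#' @param validMask logical matrix marking measured pixels; defaults to
#'   all finite, non-missing entries of \code{grid}.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @return \code{ThicknessMap()} returns a \code{ThicknessMap}.
#' @rdname ThicknessMap-class
#' @export
ThicknessMap <- function(grid, validMask = NULL, geometry = ScanGeometry()) {
    grid <- as.matrix(grid)
    storage.mode(grid) <- "double"
    if (is.null(validMask)) {
        validMask <- is.finite(grid)
    }
    grid[!validMask] <- NA_real_
    new("ThicknessMap", grid = grid, validMask = validMask,
        geometry = geometry)
}

setMethod("show", "ThicknessMap", function(object) {
    vals <- object@grid[object@validMask]
    cat(sprintf(
        "ThicknessMap: %d x %d, %d measured pixel(s), range [%.1f, %.1f] um\n",
        nrow(object@grid), ncol(object@grid), length(vals),
        if (length(vals)) min(vals) else NA, if (length(vals)) max(vals) else NA
    ))
})

#' Discretized thickness severity classes
#'
#' An ordered set of disjoint boolean masks obtained by cutting a
#' thickness map into equal-width bands over a clinical range
#' (default 220-500 um, nine classes). Class 1 is the thickest band; the
#' class index increases as thickness decreases.
#'
#' @slot edges numeric vector of band boundaries in micrometres, strictly
#'   decreasing from the range top to the range bottom
#'   (\code{nClasses + 1} values).
#' @slot masks list of logical matrices, one per class, thickest first.
#' @slot geometry the \linkS4class{ScanGeometry}.
#'
#' @seealso \code{\link{discretizeThickness}}, \code{\link{classBounds}}
#' @export
setClass("ThicknessClasses",
    representation(
        edges = "numeric", masks = "list", geometry = "ScanGeometry"
    )
)

setValidity("ThicknessClasses", function(object) {
    n <- length(object@masks)
    if (length(object@edges) != n + 1L) {
        return("edges must have one more element than there are classes")
    }
    if (any(diff(object@edges) >= 0)) {
        return("edges must be strictly decreasing (thickest first)")
    }
    w <- -diff(object@edges)
    if (max(abs(w - w[1L])) > 1e-9 * w[1L]) {
        return("class bands must have equal widths")
    }
    dims <- as.integer(
        c(object@geometry@enfaceHeight, object@geometry@enfaceWidth)
    )
    for (m in object@masks) {
        if (!is.logical(m) || !identical(dim(m), dims)) {
            return("each class mask must be a logical matrix matching geometry")
        }
    }
    if (n >= 2L) {
        tot <- Reduce(`+`, lapply(object@masks, function(m) m * 1L))
        if (any(tot > 1L)) {
            return("class masks must be pairwise disjoint")
        }
    }
    TRUE
})

setMethod("show", "ThicknessClasses", function(object) {
    counts <- vapply(object@masks, sum, numeric(1))
    cat(sprintf(
        "ThicknessClasses: %d classes over [%.0f, %.0f] um (thickest first)\n",
        length(object@masks), min(object@edges), max(object@edges)
    ))
    cat("  pixels/class:", paste(counts, collapse = " "), "\n")
})

#' Observer study ratings
#'
#' A complete case-by-rater matrix of 5-point Likert scores (1 =
#' strongly disagree ... 5 = strongly agree) from a clinical
#' acceptability study, with the acceptance threshold used to
#' dichotomize ratings into accept/reject decisions.
#'
#' @slot ratings integer matrix, cases in rows, raters in columns,
#'   entries in \code{1:5}.
#' @slot acceptThreshold integer; a rating at or above it counts as an
#'   acceptance (default 4).
#'
#' @export
setClass("ObserverStudy",
    representation(ratings = "matrix", acceptThreshold = "integer"),
    prototype(acceptThreshold = 4L)
)

setValidity("ObserverStudy", function(object) {
    r <- object@ratings
    if (!all(r %in% 1:5)) {
        return("all ratings must be integers in {1,...,5}")
    }
    if (nrow(r) < 2L || ncol(r) < 2L) {
        return("need at least 2 cases and 2 raters")
    }
    if (!(object@acceptThreshold %in% 2:5)) {
        return("acceptThreshold must be in {2,...,5}")
    }
    TRUE
})

#' @param ratings integer matrix or data.frame of Likert scores, cases in
#'   rows, raters in columns.
#' @param acceptThreshold minimum rating that counts as acceptance.
#' @return \code{ObserverStudy()} returns an \code{ObserverStudy}.
#' @examples
#' set.seed(1)
#' m <- matrix(sample(3:5, 20, replace = TRUE), ncol = 2)
#' ObserverStudy(m)
#' @rdname ObserverStudy-class
#' @export
ObserverStudy <- function(ratings, acceptThreshold = 4L) {
    ratings <- as.matrix(ratings)
    storage.mode(ratings) <- "integer"
    if (is.null(colnames(ratings))) {
        colnames(ratings) <- paste0("rater", seq_len(ncol(ratings)))
    }
    new("ObserverStudy", ratings = ratings,
        acceptThreshold = as.integer(acceptThreshold))
}

setMethod("show", "ObserverStudy", function(object) {
    cat(sprintf(
        "ObserverStudy: %d cases x %d raters, accept threshold >= %d\n",
        nrow(object@ratings), ncol(object@ratings), object@acceptThreshold
    ))
})

#' ERM-thickness association result
#'
#' The weighted cumulative-IoU association score between an ERM mask and
#' the thickness severity classes, with its per-class components.
#'
#' @slot score the association score, \code{mean(weights * perClassIoU)}.
#' @slot perClassIoU IoU between the ERM mask and the cumulative union of
#'   classes 1..i, for each class i.
#' @slot weights the severity weights applied per class.
#'
#' @seealso \code{\link{associationScore}}
#' @export
setClass("AssociationResult",
    representation(
        score = "numeric", perClassIoU = "numeric", weights = "numeric"
    )
)

setValidity("AssociationResult", function(object) {
    if (length(object@perClassIoU) != length(object@weights)) {
        return("perClassIoU and weights must have equal length")
    }
    if (any(object@perClassIoU < 0) || any(object@perClassIoU > 1)) {
        return("per-class IoU values must lie in [0, 1]")
    }
    want <- mean(object@weights * object@perClassIoU)
    if (abs(object@score - want) > 1e-8) {
        return("score must equal mean(weights * perClassIoU)")
    }
    TRUE
})

setMethod("show", "AssociationResult", function(object) {
    cat(sprintf("AssociationResult: score %.4f (%d classes)\n",
        object@score, length(object@perClassIoU)))
    cat("  per-class IoU:",
        paste(sprintf("%.3f", object@perClassIoU), collapse = " "), "\n")
})

#' Pixel-to-micrometre calibration
#'
#' Linear calibration of the en face frame. The default of 20 um per
#' pixel follows devices where every 10 pixels span 200 um, so each
#' pixel covers 400 square micrometres.
#'
#' @slot umPerPixel micrometres per en face pixel edge.
#'
#' @seealso \code{\link{pixelArea}}
#' @export
setClass("Calibration", representation(umPerPixel = "numeric"),
    prototype(umPerPixel = 20))

setValidity("Calibration", function(object) {
    if (length(object@umPerPixel) != 1L || !is.finite(object@umPerPixel) ||
        object@umPerPixel <= 0) {
        return("umPerPixel must be a single positive number")
    }
    TRUE
})

#' @param umPerPixel micrometres per pixel edge.
#' @return \code{Calibration()} returns a \code{Calibration}.
#' @examples
#' pixelArea(Calibration(20))
#' @rdname Calibration-class
#' @export
Calibration <- function(umPerPixel = 20) {
    new("Calibration", umPerPixel = as.numeric(umPerPixel))
}

setMethod("show", "Calibration", function(object) {
    cat(sprintf("Calibration: %g um/pixel (%g um^2/pixel)\n",
        object@umPerPixel, object@umPerPixel^2))
})

#' Synthetic scenario specification
#'
#' Parameters for generating a fully synthetic eye: an ERM region in en
#' face coordinates (inverse-projected to per-B-scan detections), a
#' smooth thickened-retina blob, and a Likert rating model for observer
#' studies. All generation is deterministic given \code{seed}.
#'
#' @slot seed integer RNG seed.
#' @slot ermShape list describing the ERM region: \code{type}
#'   (\code{"rect"} or \code{"ellipse"}) plus either \code{x0, x1, y0,
#'   y1} (rect, en face pixels, half-open) or \code{cx, cy, rx, ry}
#'   (ellipse centre and radii).
#' @slot thicknessBlob list with \code{cx, cy, rx, ry} (pixels),
#'   \code{peak} and \code{background} thickness (um) and optional
#'   \code{noiseSd} (um).
#' @slot overlapTarget fraction of the ERM region that should overlap
#'   the in-range thickened retina; \code{NA} leaves the shape where it
#'   is, otherwise the ERM shape is translated along x to meet the
#'   target.
#' @slot ratingModel list with \code{latentMean}, \code{latentSd}
#'   (case-level quality), \code{raterShift} (per-rater bias vector) and
#'   \code{noiseSd} (per-rating noise).
#'
#' @export
setClass("ScenarioSpec",
    representation(
        seed = "integer", ermShape = "list", thicknessBlob = "list",
        overlapTarget = "numeric", ratingModel = "list"
    )
)

setValidity("ScenarioSpec", function(object) {
    b <- object@thicknessBlob
    if (!all(c("cx", "cy", "rx", "ry", "peak", "background") %in% names(b))) {
        return("thicknessBlob needs cx, cy, rx, ry, peak, background")
    }
    if (b$peak < 0 || b$peak > 600 || b$background < 0 || b$background > 600) {
        return("blob peak and background must lie in [0, 600] um")
    }
    if (!object@ermShape$type %in% c("rect", "ellipse")) {
        return("ermShape$type must be 'rect' or 'ellipse'")
    }
    if (!is.na(object@overlapTarget) &&
        (object@overlapTarget < 0 || object@overlapTarget > 1)) {
        return("overlapTarget must be in [0, 1] or NA")
    }
    TRUE
})

#' @param seed integer RNG seed.
#' @param ermShape,thicknessBlob,ratingModel see the class slots.
#' @param overlapTarget programmed ERM / thickened-retina overlap
#'   fraction, or \code{NA} to keep the shape as given.
#' @return \code{ScenarioSpec()} returns a \code{ScenarioSpec}.
#' @rdname ScenarioSpec-class
#' @export
ScenarioSpec <- function(seed = 1L,
                         ermShape = list(
                             type = "ellipse", cx = 248, cy = 248,
                             rx = 70, ry = 60
                         ),
                         thicknessBlob = list(
                             cx = 248, cy = 248, rx = 100, ry = 100,
                             peak = 480, background = 200, noiseSd = 0
                         ),
                         overlapTarget = NA_real_,
                         ratingModel = list(
                             latentMean = 4.48, latentSd = 0.8,
                             raterShift = c(0, 0.03), noiseSd = 0.2
                         )) {
    new("ScenarioSpec",
        seed = as.integer(seed), ermShape = ermShape,
        thicknessBlob = thicknessBlob,
        overlapTarget = as.numeric(overlapTarget), ratingModel = ratingModel
    )
}

setMethod("show", "ScenarioSpec", function(object) {
    cat(sprintf(
        "ScenarioSpec: seed %d, ERM %s, blob peak %g um over %g um background\n",
        object@seed, object@ermShape$type, object@thicknessBlob$peak,
        object@thicknessBlob$background
    ))
})
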