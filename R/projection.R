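# En face projection of per-B-scan detections.
#
# All public intervals are 0-based and half-open [start, end), so pixel
# counts are simply end - start. Conversion to R's 1-based matrix
# indexing happens only at the point of assignment.

# Snap tolerance for floor/ceiling after the linear coordinate map:
# inverse-mapped synthetic coordinates (x_e * 768/496) are inexact in
# binary and must land back on the integer they came from.
.SNAP <- 1e-9

#' Map a B-scan x-coordinate onto the en face axis
#'
#' Linearly rescales a lateral B-scan coordinate to the en face frame:
#' \code{x_enface = x_bscan / bscanWidth * enfaceExtent}. For horizontal
#' scans the target axis is the en face x-axis; for vertical scans the
#' same rescaling lands on the y-axis.
#'
#' @param x numeric vector of B-scan x-coordinates in pixels, in
#'   \code{[0, bscanWidth]}.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param axis \code{"x"} (horizontal scans) or \code{"y"} (vertical
#'   scans); selects which en face extent the coordinate is scaled to.
#' @return numeric vector of en face coordinates (real-valued; callers
#'   discretize).
#' @examples
#' normalizeCoordinate(c(0, 384, 768), ScanGeometry())
#' @export
normalizeCoordinate <- function(x, geometry = ScanGeometry(),
                                axis = c("x", "y")) {
    axis <- match.arg(axis)
    w <- geometry@bscanWidth
    bad <- which(x < 0 | x > w)
    if (length(bad)) {
        stop(sprintf(
            "B-scan coordinate %g outside [0, %d]", x[bad[1L]], w
        ))
    }
    extent <- if (axis == "x") geometry@enfaceWidth else geometry@enfaceHeight
    (x * extent) / w
}

#' Perpendicular band of a scan line on the en face frame
#'
#' Each of the \code{nScans} parallel scan lines owns a band of rows
#' (horizontal scans) or columns (vertical scans) spanning the full
#' inter-scan spacing \code{S = extent / nScans}. Band \code{k} is the
#' half-open interval \code{[floor(k * S), floor((k + 1) * S))}; the
#' bands tile the frame with no gaps or overlaps.
#'
#' @param scanIndex 0-based scan index.
#' @param orientation \code{"horizontal"} or \code{"vertical"}.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @return integer vector \code{c(start, end)}, a 0-based half-open
#'   interval of rows (horizontal) or columns (vertical).
#' @examples
#' scanBand(0, "horizontal") # rows [0, 19)
#' scanBand(24, "horizontal") # rows [476, 496)
#' @export
scanBand <- function(scanIndex, orientation = c("horizontal", "vertical"),
                     geometry = ScanGeometry()) {
    orientation <- match.arg(orientation)
    n <- geometry@nScans
    k <- as.integer(scanIndex)
    if (is.na(k) || k < 0L || k >= n) {
        stop(sprintf("scanIndex %s outside [0, %d)", scanIndex, n))
    }
    extent <- if (orientation == "horizontal") {
        geometry@enfaceHeight
    } else {
        geometry@enfaceWidth
    }
    # integer arithmetic: floor(k * extent / n) exactly
    c(
        start = (k * extent) %/% n,
        end = ((k + 1L) * extent) %/% n
    )
}

#' Project one detection onto the en face grid
#'
#' The along-scan extent \code{[x0, x1)} is rescaled through
#' \code{\link{normalizeCoordinate}} and discretized conservatively
#' (floor at the start, ceiling at the end) so no sub-pixel extent is
#' lost; the perpendicular extent is the scan's
#' \code{\link{scanBand}}. For horizontal scans the along-scan extent
#' spans columns; for vertical scans it spans rows.
#'
#' @param det a list or one-row data.frame with fields
#'   \code{orientation}, \code{scanIndex}, \code{x0}, \code{x1}.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @return list with integer elements \code{rows} and \code{cols}, each
#'   a 0-based half-open \code{c(start, end)} interval.
#' @examples
#' projectDetection(
#'     list(orientation = "horizontal", scanIndex = 0, x0 = 384, x1 = 768)
#' )
#' @export
projectDetection <- function(det, geometry = ScanGeometry()) {
    det <- as.list(det)
    if (det$x0 >= det$x1) {
        stop(sprintf(
            "degenerate detection: x0 (%g) must be < x1 (%g)", det$x0, det$x1
        ))
    }
    orientation <- match.arg(det$orientation, c("horizontal", "vertical"))
    axis <- if (orientation == "horizontal") "x" else "y"
    lo <- normalizeCoordinate(det$x0, geometry, axis = axis)
    hi <- normalizeCoordinate(det$x1, geometry, axis = axis)
    along <- c(
        start = as.integer(floor(lo + .SNAP)),
        end = as.integer(ceiling(hi - .SNAP))
    )
    band <- scanBand(det$scanIndex, orientation, geometry)
    if (orientation == "horizontal") {
        list(rows = band, cols = along)
    } else {
        list(rows = along, cols = band)
    }
}

#' Build the epiretinal projection image (EPI)
#'
#' Projects every detection at or above the confidence cutoff onto the
#' en face frame and merges the projected rectangles into a single
#' binary mask; the coverage matrix counts how many detections
#' contributed to each pixel.
#'
#' @param detections a \linkS4class{DetectionSet}.
#' @param minConfidence detections below this confidence are dropped
#'   before projection (default 0.25).
#' @return an \linkS4class{EPIMask}.
#' @examples
#' ds <- DetectionSet(
#'     orientation = "horizontal", scanIndex = 12L,
#'     x0 = 0, x1 = 768, confidence = 0.9
#' )
#' epi <- buildEPI(ds)
#' sum(maskGrid(epi))
#' @export
buildEPI <- function(detections, minConfidence = 0.25) {
    stopifnot(is(detections, "DetectionSet"))
    if (minConfidence < 0 || minConfidence > 1) {
        stop("minConfidence must lie in [0, 1]")
    }
    validObject(detections)
    g <- detections@geometry
    cov <- matrix(0L, nrow = g@enfaceHeight, ncol = g@enfaceWidth)
    d <- detections@detections
    d <- d[d$confidence >= minConfidence, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
        reg <- projectDetection(d[i, ], g)
        ri <- (reg$rows[["start"]] + 1L):reg$rows[["end"]]
        ci <- (reg$cols[["start"]] + 1L):reg$cols[["end"]]
        cov[ri, ci] <- cov[ri, ci] + 1L
    }
    new("EPIMask", grid = cov >= 1L, coverage = cov, geometry = g)
}
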