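# Conversion of EPI pixel counts to physical area and frame-relative
# ratio. Ratios are truncated, not rounded, to two decimals: that is the
# convention that reproduces the device's printed report values.

#' Physical area covered by one en face pixel
#'
#' @param cal a \linkS4class{Calibration}.
#' @return pixel area in square micrometres
#'   (\code{umPerPixel^2}; 400 for the default 20 um/pixel).
#' @examples
#' pixelArea(Calibration(20))
#' @export
pixelArea <- function(cal = Calibration()) {
    stopifnot(is(cal, "Calibration"))
    validObject(cal)
    cal@umPerPixel^2
}

#' Physical ERM area of an EPI mask
#'
#' Counts the pixels marked as ERM and multiplies by the pixel area.
#'
#' @param mask an \linkS4class{EPIMask} or a logical matrix.
#' @param cal a \linkS4class{Calibration}.
#' @return ERM area in square micrometres.
#' @examples
#' erm <- matrix(FALSE, 496, 496)
#' erm[1:100, 1:100] <- TRUE
#' ermArea(erm) # 10000 px * 400 um^2
#' @export
ermArea <- function(mask, cal = Calibration()) {
    grid <- if (is(mask, "EPIMask")) mask@grid else mask
    stopifnot(is.logical(grid))
    sum(grid) * pixelArea(cal)
}

# truncate to 2 decimals; the round() at 1e-6 absorbs representation
# error so a percentage that is mathematically k/100 never drops a cent
.truncate2 <- function(pct) {
    floor(round(pct * 100, 6)) / 100
}

#' ERM area ratio of the en face frame
#'
#' Expresses an ERM area as the percentage of the full en face frame it
#' covers, truncated (not rounded) to two decimal places.
#'
#' @param areaUm2 ERM area in square micrometres.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param cal a \linkS4class{Calibration}.
#' @param truncate logical; return the two-decimal truncated percentage
#'   (default) or the raw value.
#' @return percentage in \code{[0, 100]}.
#' @examples
#' ermRatio(14140800) # 14.36
#' @export
ermRatio <- function(areaUm2, geometry = ScanGeometry(), cal = Calibration(),
                     truncate = TRUE) {
    total <- as.numeric(geometry@enfaceWidth) * geometry@enfaceHeight *
        pixelArea(cal)
    if (any(areaUm2 < 0) || any(areaUm2 > total)) {
        stop(sprintf(
            "area must lie in [0, %g] um^2 for this frame", total
        ))
    }
    pct <- 100 * areaUm2 / total
    if (truncate) .truncate2(pct) else pct
}

#' Full area report for an EPI mask
#'
#' @param mask an \linkS4class{EPIMask}.
#' @param cal a \linkS4class{Calibration}.
#' @return list with \code{ermPixels}, \code{ermAreaUm2},
#'   \code{ermRatioPct} (truncated to 2 decimals), \code{ermRatioRaw}
#'   (full precision) and the calibration used.
#' @examples
#' epi <- buildEPI(DetectionSet())
#' areaReport(epi)
#' @export
areaReport <- function(mask, cal = Calibration()) {
    stopifnot(is(mask, "EPIMask"))
    g <- mask@geometry
    px <- sum(mask@grid)
    area <- px * pixelArea(cal)
    list(
        ermPixels = px,
        ermAreaUm2 = area,
        ermRatioPct = ermRatio(area, g, cal),
        ermRatioRaw = ermRatio(area, g, cal, truncate = FALSE),
        umPerPixel = cal@umPerPixel,
        pixelAreaUm2 = pixelArea(cal)
    )
}
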