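# ERM-thickness association: weighted mean over severity classes of the
# IoU between the ERM mask and the cumulative union of the thickest
# classes. Thicker retina (lower class index) carries more weight.

#' Intersection over union of two binary masks
#'
#' \code{|a & b| / |a | b|}, defined as 0 when both masks are empty so
#' "no area anywhere" reads as "no association" rather than NaN.
#'
#' @param a,b logical matrices of identical shape (or
#'   \linkS4class{EPIMask} objects).
#' @return a number in \code{[0, 1]}.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
#' maskIoU(a, b) # 1/3
#' @export
maskIoU <- function(a, b) {
    if (is(a, "EPIMask")) a <- a@grid
    if (is(b, "EPIMask")) b <- b@grid
    stopifnot(is.logical(a), is.logical(b))
    if (!identical(dim(a), dim(b))) {
        stop("mask shapes differ")
    }
    u <- sum(a | b)
    if (u == 0L) {
        return(0)
    }
    sum(a & b) / u
}

#' Severity weight of a thickness class
#'
#' The quadratic weighting \code{W_i = -0.01 i^2 - 0.07 i + 1.666},
#' strictly decreasing over classes 1..9 so the thickest retina counts
#' most. The coefficients are used exactly as stated; note their sum
#' over the nine classes is 8.994, so the association score is bounded
#' by 8.994 / 9 = 0.99933..., not by 1.
#'
#' @param i class index (vectorized), 1 to \code{nClasses}.
#' @param nClasses number of classes (range check only).
#' @return numeric weight(s).
#' @examples
#' classWeight(1) # 1.586
#' classWeight(9) # 0.226
#' @export
classWeight <- function(i, nClasses = 9L) {
    i <- as.integer(i)
    if (any(is.na(i)) || any(i < 1L) || any(i > nClasses)) {
        stop(sprintf("class index must lie in [1, %d]", nClasses))
    }
    -0.01 * i^2 - 0.07 * i + 1.666
}

#' Association score between ERM and thickened retina
#'
#' For each severity class i, the IoU between the binary ERM mask and
#' the cumulative union of classes 1..i is weighted by
#' \code{\link{classWeight}}; the score is the mean of the nine weighted
#' terms. High scores mean the ERM region coincides with the thickest
#' retina; detection coverage counts are ignored (the ERM operand is a
#' pixel set).
#'
#' @param erm an \linkS4class{EPIMask} or logical matrix.
#' @param classes a \linkS4class{ThicknessClasses}.
#' @return an \linkS4class{AssociationResult}.
#' @examples
#' tm <- ThicknessMap(matrix(480, 496, 496))
#' tc <- discretizeThickness(tm)
#' erm <- matrix(TRUE, 496, 496)
#' associationScore(erm, tc) # all cumulative IoU = 1 -> 0.99933...
#' @export
associationScore <- function(erm, classes) {
    if (is(erm, "EPIMask")) {
        if (!identical(
            c(erm@geometry@enfaceHeight, erm@geometry@enfaceWidth),
            c(classes@geometry@enfaceHeight, classes@geometry@enfaceWidth)
        )) {
            stop("ERM mask and thickness classes have different geometry")
        }
        erm <- erm@grid
    }
    stopifnot(is(classes, "ThicknessClasses"), is.logical(erm))
    n <- length(classes@masks)
    if (!identical(dim(erm), dim(classes@masks[[1L]]))) {
        stop("ERM mask shape does not match class masks")
    }
    cum <- matrix(FALSE, nrow(erm), ncol(erm))
    iou <- numeric(n)
    for (i in seq_len(n)) {
        cum <- cum | classes@masks[[i]]
        iou[i] <- maskIoU(erm, cum)
    }
    w <- classWeight(seq_len(n), nClasses = n)
    new("AssociationResult",
        score = mean(w * iou), perClassIoU = iou, weights = w)
}
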