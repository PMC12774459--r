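# Discretization of a retinal thickness map into equal-width severity
# bands. Clinically the 220-500 um range is the window of interest;
# class 1 is the thickest band (most severe), class indices increase as
# thickness decreases.

.DEFAULT_RANGE <- c(220, 500)
.DEFAULT_NCLASSES <- 9L

.bandEdges <- function(range, nClasses) {
    w <- (range[2L] - range[1L]) / nClasses
    range[2L] - (0:nClasses) * w # decreasing: top ... bottom
}

#' Thickness interval of one severity class
#'
#' Class \code{i} covers \code{[top - i*w, top - (i-1)*w)} where
#' \code{w = (top - bottom) / nClasses}; the interval is closed at its
#' lower bound and open at its upper bound, except that the range top
#' (500 um by default) is included in class 1.
#'
#' @param i class index, 1 (thickest) to \code{nClasses}.
#' @param range numeric \code{c(bottom, top)} in micrometres.
#' @param nClasses number of equal-width bands.
#' @return numeric \code{c(lower, upper)} in micrometres.
#' @examples
#' classBounds(1) # [468.89, 500]
#' classBounds(9) # [220, 251.11)
#' @export
classBounds <- function(i, range = .DEFAULT_RANGE,
                        nClasses = .DEFAULT_NCLASSES) {
    i <- as.integer(i)
    if (any(is.na(i)) || any(i < 1L) || any(i > nClasses)) {
        stop(sprintf("class index must lie in [1, %d]", nClasses))
    }
    edges <- .bandEdges(range, nClasses)
    c(lower = edges[i + 1L], upper = edges[i])
}

#' Discretize a thickness map into severity classes
#'
#' Every measured pixel with thickness inside the clinical range is
#' assigned to exactly one of \code{nClasses} equal-width bands,
#' thickest first; pixels below the range bottom or above the range top
#' stay unassigned. A pixel exactly on an internal band edge belongs to
#' the class whose lower bound that edge is, and the range top belongs
#' to class 1.
#'
#' @param tmap a \linkS4class{ThicknessMap}.
#' @param range numeric \code{c(bottom, top)} in micrometres.
#' @param nClasses number of bands.
#' @return a \linkS4class{ThicknessClasses}.
#' @examples
#' tm <- ThicknessMap(matrix(490, 496, 496))
#' tc <- discretizeThickness(tm)
#' sum(classMasks(tc)[[1]]) # every pixel in the thickest class
#' @export
discretizeThickness <- function(tmap, range = .DEFAULT_RANGE,
                                nClasses = .DEFAULT_NCLASSES) {
    stopifnot(is(tmap, "ThicknessMap"))
    validObject(tmap)
    edges <- .bandEdges(range, nClasses)
    inc <- rev(edges) # increasing, bottom ... top
    vals <- tmap@grid
    # j in 1..nClasses when vals in [inc[j], inc[j+1]); top closed
    j <- matrix(
        findInterval(vals, inc, rightmost.closed = TRUE),
        nrow = nrow(vals)
    )
    j[!tmap@validMask | is.na(vals)] <- 0L
    j[vals > range[2L] & tmap@validMask] <- 0L # above range, incl. > top
    masks <- lapply(seq_len(nClasses), function(i) {
        m <- j == (nClasses + 1L - i)
        m[is.na(m)] <- FALSE
        m
    })
    new("ThicknessClasses",
        edges = edges, masks = masks, geometry = tmap@geometry)
}

#' Cumulative union of the thickest classes
#'
#' Union of class masks 1..i, i.e. all pixels at least as thick as the
#' lower bound of class \code{i}; non-decreasing in \code{i}.
#'
#' @param classes a \linkS4class{ThicknessClasses}.
#' @param i class index.
#' @return logical matrix.
#' @examples
#' tm <- ThicknessMap(matrix(300, 496, 496))
#' tc <- discretizeThickness(tm)
#' sum(cumulativeUnion(tc, 9)) # everything in range
#' @export
cumulativeUnion <- function(classes, i) {
    stopifnot(is(classes, "ThicknessClasses"))
    i <- as.integer(i)
    if (is.na(i) || i < 1L || i > length(classes@masks)) {
        stop(sprintf("class index must lie in [1, %d]", length(classes@masks)))
    }
    Reduce(`|`, classes@masks[seq_len(i)])
}
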