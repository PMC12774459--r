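#' Accessors for the core containers
#'
#' \code{geometry} returns the \linkS4class{ScanGeometry} an object is
#' registered to; \code{maskGrid} the binary en face grid;
#' \code{coverage} the per-pixel detection count of an
#' \linkS4class{EPIMask}; \code{classMasks} the ordered list of severity
#' masks; \code{classEdges} the band boundaries in micrometres;
#' \code{ratings} the case-by-rater Likert matrix.
#'
#' @param x one of the package's S4 containers.
#' @return See the individual descriptions above.
#' @examples
#' epi <- buildEPI(DetectionSet())
#' dim(maskGrid(epi))
#' geometry(epi)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @rdname accessors
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname accessors
#' @export
setGeneric("classMasks", function(x) standardGeneric("classMasks"))

#' @rdname accessors
#' @export
setGeneric("classEdges", function(x) standardGeneric("classEdges"))

#' @rdname accessors
#' @export
setGeneric("ratings", function(x) standardGeneric("ratings"))

#' @rdname accessors
#' @export
setMethod("geometry", "DetectionSet", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("geometry", "EPIMask", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("geometry", "ThicknessMap", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("geometry", "ThicknessClasses", function(x) x@geometry)

#' @rdname accessors
#' @export
setMethod("maskGrid", "EPIMask", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("maskGrid", "ThicknessMap", function(x) x@validMask)

#' @rdname accessors
#' @export
setMethod("coverage", "EPIMask", function(x) x@coverage)

#' @rdname accessors
#' @export
setMethod("classMasks", "ThicknessClasses", function(x) x@masks)

#' @rdname accessors
#' @export
setMethod("classEdges", "ThicknessClasses", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("ratings", "ObserverStudy", function(x) x@ratings)

#' Thickness values of a map
#'
#' @param x a \linkS4class{ThicknessMap}.
#' @return numeric matrix of thickness in micrometres (\code{NA} where
#'   unmeasured).
#' @export
thicknessValues <- function(x) {
    stopifnot(is(x, "ThicknessMap"))
    x@grid
}
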