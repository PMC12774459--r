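# End-to-end pipeline: detections -> EPI -> area/ratio -> thickness
# discretization -> association score, with optional observer-study
# report, writing PNG/JSON/CSV artifacts.

#' Assemble a validated pipeline configuration
#'
#' All module preconditions are checked at assembly time so a bad
#' configuration fails before any stage runs.
#'
#' @param detectionsPath detection input (directory or manifest file).
#' @param dialect detection dialect, \code{"yolo_txt"} or
#'   \code{"json"}.
#' @param thicknessPath thickness map (CSV or TIFF), or \code{NULL} to
#'   skip the association stage.
#' @param ratingsPath observer ratings CSV, or \code{NULL} to skip the
#'   agreement stage.
#' @param outDir artifact directory, or \code{NULL} for no files.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param calibration a \linkS4class{Calibration}.
#' @param minConfidence detection confidence cutoff.
#' @param thicknessRange clinical range \code{c(bottom, top)} in
#'   micrometres.
#' @param nClasses number of severity bands.
#' @param acceptThreshold Likert acceptance threshold.
#' @return a list of class \code{"runConfig"}.
#' @export
runConfig <- function(detectionsPath, dialect = c("yolo_txt", "json"),
                      thicknessPath = NULL, ratingsPath = NULL,
                      outDir = NULL, geometry = ScanGeometry(),
                      calibration = Calibration(), minConfidence = 0.25,
                      thicknessRange = c(220, 500), nClasses = 9L,
                      acceptThreshold = 4L) {
    dialect <- match.arg(dialect)
    validObject(geometry)
    validObject(calibration)
    if (minConfidence < 0 || minConfidence > 1) {
        stop("minConfidence must lie in [0, 1]")
    }
    if (length(thicknessRange) != 2L ||
        thicknessRange[1L] >= thicknessRange[2L]) {
        stop("thicknessRange must be c(bottom, top) with bottom < top")
    }
    if (nClasses < 1L) {
        stop("nClasses must be at least 1")
    }
    if (!(acceptThreshold %in% 2:5)) {
        stop("acceptThreshold must be in {2,...,5}")
    }
    structure(
        list(
            detectionsPath = detectionsPath, dialect = dialect,
            thicknessPath = thicknessPath, ratingsPath = ratingsPath,
            outDir = outDir, geometry = geometry, calibration = calibration,
            minConfidence = minConfidence, thicknessRange = thicknessRange,
            nClasses = as.integer(nClasses),
            acceptThreshold = as.integer(acceptThreshold)
        ),
        class = "runConfig"
    )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Recognized keys mirror the \code{\link{runConfig}} arguments, with a
#' nested \code{geometry} block (\code{bscan_width}, \code{bscan_height},
#' \code{enface_width}, \code{enface_height}, \code{n_scans}) and
#' \code{um_per_pixel} for the calibration.
#'
#' @param path YAML (\code{.yml}/\code{.yaml}) or JSON file.
#' @return a \code{runConfig} list.
#' @export
readRunConfig <- function(path) {
    ext <- tolower(tools::file_ext(path))
    cfg <- if (ext %in% c("yml", "yaml")) {
        if (!requireNamespace("yaml", quietly = TRUE)) {
            stop("the 'yaml' package is needed for YAML configuration files")
        }
        yaml::read_yaml(path)
    } else {
        jsonlite::fromJSON(path)
    }
    g <- if (!is.null(cfg$geometry)) .geometryFromList(cfg$geometry) else
        ScanGeometry()
    cal <- Calibration(if (is.null(cfg$um_per_pixel)) 20 else cfg$um_per_pixel)
    runConfig(
        detectionsPath = cfg$detections_path,
        dialect = if (is.null(cfg$dialect)) "yolo_txt" else cfg$dialect,
        thicknessPath = cfg$thickness_path,
        ratingsPath = cfg$ratings_path,
        outDir = cfg$out_dir,
        geometry = g, calibration = cal,
        minConfidence = if (is.null(cfg$min_confidence)) 0.25 else
            cfg$min_confidence,
        thicknessRange = if (is.null(cfg$thickness_range)) c(220, 500) else
            unlist(cfg$thickness_range),
        nClasses = if (is.null(cfg$n_classes)) 9L else cfg$n_classes,
        acceptThreshold = if (is.null(cfg$accept_threshold)) 4L else
            cfg$accept_threshold
    )
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s",
            name, conditionMessage(e)), call. = FALSE)
    })
}

#' Run the full quantification pipeline
#'
#' Reads detections, builds the EPI, converts to physical area and
#' frame ratio, and -- when a thickness map is configured --
#' discretizes it and computes the association score; a ratings CSV
#' additionally yields the observer-agreement report. With
#' \code{outDir} set, the EPI PNG + sidecar and a JSON report are
#' written. The report notes the sum of the class weights actually
#' used (8.994 for the stated quadratic weighting, i.e. not 1).
#'
#' @param config a \code{runConfig} (or a path accepted by
#'   \code{\link{readRunConfig}}).
#' @return list with \code{epi}, \code{area}, and where configured
#'   \code{association}, \code{classes} and \code{agreement}.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        config <- readRunConfig(config)
    }
    stopifnot(inherits(config, "runConfig"))
    dets <- .stage("read_detections", readDetections(
        config$detectionsPath, config$dialect, config$geometry
    ))
    epi <- .stage("build_epi", buildEPI(dets, config$minConfidence))
    area <- .stage("quantify", areaReport(epi, config$calibration))
    out <- list(epi = epi, area = area)

    if (!is.null(config$thicknessPath)) {
        tmap <- .stage("read_thickness", readThicknessMap(
            config$thicknessPath, config$geometry
        ))
        classes <- .stage("discretize", discretizeThickness(
            tmap, config$thicknessRange, config$nClasses
        ))
        out$classes <- classes
        out$association <- .stage("associate", associationScore(epi, classes))
    }
    if (!is.null(config$ratingsPath)) {
        study <- .stage("read_ratings", readRatings(
            config$ratingsPath, config$acceptThreshold
        ))
        out$agreement <- .stage("agreement", agreementReport(study))
    }

    if (!is.null(config$outDir)) {
        dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
        .stage("write_artifacts", {
            writeEPI(epi, file.path(config$outDir, "epi.png"))
            report <- list(
                geometry = .geometryToList(config$geometry),
                calibration = list(
                    um_per_pixel = config$calibration@umPerPixel,
                    pixel_area_um2 = pixelArea(config$calibration)
                ),
                min_confidence = config$minConfidence,
                area = area
            )
            if (!is.null(out$association)) {
                w <- out$association@weights
                report$association <- list(
                    score = out$association@score,
                    per_class_iou = out$association@perClassIoU,
                    weights = w,
                    # the stated quadratic weights sum to 8.994, not 1
                    weight_sum = sum(w)
                )
            }
            if (!is.null(out$agreement)) {
                a <- out$agreement
                report$agreement <- list(
                    pearson_r = a$correlations$pearson,
                    spearman_rho = a$correlations$spearman,
                    weighted_kappa = a$weightedKappa,
                    icc21 = a$icc[c("value", "lower", "upper")],
                    bland_altman = a$blandAltman[
                        c("meanDiff", "sdDiff", "loaLow", "loaHigh")
                    ],
                    aas = a$acceptability$aas, ar = a$acceptability$ar,
                    nas = a$acceptability$nas,
                    binary_kappa = a$binaryKappa
                )
            }
            jsonlite::write_json(
                report, file.path(config$outDir, "report.json"),
                auto_unbox = TRUE, digits = NA
            )
        })
    }
    out
}
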