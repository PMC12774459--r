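# Readers and writers for the on-disk formats: YOLO-style detection
# text files, JSON detection manifests, thickness maps (CSV / 16-bit
# TIFF), EPI masks (PNG + JSON sidecar) and observer ratings (CSV).

.geometryToList <- function(g) {
    list(
        bscan_width = g@bscanWidth, bscan_height = g@bscanHeight,
        enface_width = g@enfaceWidth, enface_height = g@enfaceHeight,
        n_scans = g@nScans
    )
}

.geometryFromList <- function(x) {
    ScanGeometry(
        bscanWidth = x$bscan_width, bscanHeight = x$bscan_height,
        enfaceWidth = x$enface_width, enfaceHeight = x$enface_height,
        nScans = x$n_scans
    )
}

#' Read ERM detections from disk
#'
#' Two dialects are supported. \code{"yolo_txt"}: a directory with one
#' file per B-scan named \code{{orientation}_{index}.txt}, each line
#' \code{class x_center y_center width height [confidence]} with all
#' box fields normalized to \code{[0, 1]}; the lateral extent is
#' recovered as \code{(x_center +/- width/2) * bscanWidth} and only
#' lines of the ERM class are kept. \code{"json"}: a single manifest
#' file with a geometry block and one record per detection. Empty
#' files are valid (no ERM on that scan); malformed lines are reported
#' with file and line context.
#'
#' @param path directory (\code{yolo_txt}) or file (\code{json}).
#' @param dialect \code{"yolo_txt"} or \code{"json"}.
#' @param geometry a \linkS4class{ScanGeometry}; for \code{json} input
#'   the manifest's own geometry block wins.
#' @param classId ERM class id to keep in YOLO files (default 0).
#' @return a \linkS4class{DetectionSet}.
#' @export
readDetections <- function(path, dialect = c("yolo_txt", "json"),
                           geometry = ScanGeometry(), classId = 0L) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) {
        stop(sprintf("detection input '%s' does not exist", path))
    }
    if (dialect == "json") {
        return(.readDetectionsJson(path))
    }
    files <- list.files(path, pattern = "^(horizontal|vertical)_\\d+\\.txt$")
    rows <- list()
    for (f in files) {
        parts <- strsplit(sub("\\.txt$", "", f), "_")[[1L]]
        orientation <- parts[1L]
        scanIndex <- as.integer(parts[2L])
        lines <- readLines(file.path(path, f), warn = FALSE)
        for (ln in seq_along(lines)) {
            line <- trimws(lines[ln])
            if (!nzchar(line)) next
            tok <- suppressWarnings(as.numeric(strsplit(line, "\\s+")[[1L]]))
            if (length(tok) < 5L || length(tok) > 6L || anyNA(tok)) {
                stop(sprintf("%s:%d: malformed detection line '%s'",
                    f, ln, lines[ln]))
            }
            box <- tok[2:5]
            if (any(box < 0) || any(box > 1)) {
                stop(sprintf(
                    "%s:%d: box fields must be normalized to [0,1]", f, ln
                ))
            }
            if (tok[1L] != classId) next
            conf <- if (length(tok) == 6L) tok[6L] else 1
            w <- geometry@bscanWidth
            rows[[length(rows) + 1L]] <- data.frame(
                orientation = orientation, scanIndex = scanIndex,
                x0 = max(0, (tok[2L] - tok[4L] / 2) * w),
                x1 = min(w, (tok[2L] + tok[4L] / 2) * w),
                confidence = conf, stringsAsFactors = FALSE
            )
        }
    }
    d <- if (length(rows)) do.call(rbind, rows) else
        data.frame(
            orientation = character(), scanIndex = integer(),
            x0 = numeric(), x1 = numeric(), confidence = numeric()
        )
    new("DetectionSet", detections = d, geometry = geometry)
}

.readDetectionsJson <- function(path) {
    j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    g <- .geometryFromList(j$geometry)
    recs <- j$detections
    d <- if (is.data.frame(recs) && nrow(recs)) {
        data.frame(
            orientation = recs$orientation,
            scanIndex = as.integer(recs$scan_index),
            x0 = as.numeric(recs$x0_px), x1 = as.numeric(recs$x1_px),
            confidence = as.numeric(recs$confidence),
            stringsAsFactors = FALSE
        )
    } else {
        data.frame(
            orientation = character(), scanIndex = integer(),
            x0 = numeric(), x1 = numeric(), confidence = numeric()
        )
    }
    new("DetectionSet", detections = d, geometry = g)
}

#' Write ERM detections to disk
#'
#' Inverse of \code{\link{readDetections}}; for \code{"yolo_txt"} a
#' file is written for every scan (empty when the scan has no
#' detections), with the depth fields set to a full-height box since
#' only the lateral extent carries information here.
#'
#' @param detections a \linkS4class{DetectionSet}.
#' @param path output directory (\code{yolo_txt}) or file
#'   (\code{json}).
#' @param dialect \code{"yolo_txt"} or \code{"json"}.
#' @param classId class id written on YOLO lines.
#' @return invisibly, \code{path}.
#' @export
writeDetections <- function(detections, path,
                            dialect = c("yolo_txt", "json"), classId = 0L) {
    dialect <- match.arg(dialect)
    stopifnot(is(detections, "DetectionSet"))
    g <- detections@geometry
    d <- detections@detections
    if (dialect == "json") {
        out <- list(
            geometry = .geometryToList(g),
            detections = if (nrow(d)) {
                data.frame(
                    orientation = d$orientation, scan_index = d$scanIndex,
                    x0_px = d$x0, x1_px = d$x1, confidence = d$confidence
                )
            } else {
                list()
            }
        )
        jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
        return(invisible(path))
    }
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (orientation in c("horizontal", "vertical")) {
        for (k in seq_len(g@nScans) - 1L) {
            f <- file.path(path, sprintf("%s_%02d.txt", orientation, k))
            sel <- d$orientation == orientation & d$scanIndex == k
            lines <- character(0)
            if (any(sel)) {
                dd <- d[sel, , drop = FALSE]
                w <- g@bscanWidth
                lines <- sprintf(
                    "%d %.10f 0.5 %.10f 1.0 %.6f",
                    classId, (dd$x0 + dd$x1) / (2 * w), (dd$x1 - dd$x0) / w,
                    dd$confidence
                )
            }
            writeLines(lines, f)
        }
    }
    invisible(path)
}

#' Read a retinal thickness map
#'
#' CSV input is a plain numeric matrix (no header) in micrometres with
#' \code{NA}/\code{NaN} marking unmeasured pixels. TIFF input is a
#' single-channel 16-bit image whose integer values are micrometres;
#' value 0 is treated as the unmeasured sentinel.
#'
#' @param path file ending in \code{.csv} or \code{.tif}/\code{.tiff}.
#' @param geometry a \linkS4class{ScanGeometry}.
#' @return a \linkS4class{ThicknessMap}.
#' @export
readThicknessMap <- function(path, geometry = ScanGeometry()) {
    if (!file.exists(path)) {
        stop(sprintf("thickness map '%s' does not exist", path))
    }
    ext <- tolower(tools::file_ext(path))
    if (ext == "csv") {
        grid <- as.matrix(utils::read.csv(path, header = FALSE))
        dimnames(grid) <- NULL
        ThicknessMap(grid, geometry = geometry)
    } else if (ext %in% c("tif", "tiff")) {
        img <- tiff::readTIFF(path, as.is = TRUE)
        if (length(dim(img)) == 3L) {
            img <- img[, , 1L]
        }
        grid <- matrix(as.numeric(img), nrow = nrow(img))
        valid <- grid > 0
        grid[!valid] <- NA_real_
        ThicknessMap(grid, validMask = valid, geometry = geometry)
    } else {
        stop(sprintf("unsupported thickness-map format '.%s'", ext))
    }
}

#' Write a retinal thickness map
#'
#' CSV keeps full precision; TIFF stores integer micrometres in a
#' 16-bit single channel with unmeasured pixels as 0.
#'
#' @param tmap a \linkS4class{ThicknessMap}.
#' @param path output file ending in \code{.csv} or
#'   \code{.tif}/\code{.tiff}.
#' @return invisibly, \code{path}.
#' @export
writeThicknessMap <- function(tmap, path) {
    stopifnot(is(tmap, "ThicknessMap"))
    ext <- tolower(tools::file_ext(path))
    if (ext == "csv") {
        utils::write.table(tmap@grid, path,
            sep = ",", na = "NaN",
            row.names = FALSE, col.names = FALSE
        )
    } else if (ext %in% c("tif", "tiff")) {
        g <- round(tmap@grid)
        g[!tmap@validMask | is.na(g)] <- 0
        tiff::writeTIFF(g / 65535, path, bits.per.sample = 16L)
    } else {
        stop(sprintf("unsupported thickness-map format '.%s'", ext))
    }
    invisible(path)
}

#' Write an EPI mask as PNG plus JSON sidecar
#'
#' The PNG is a binary 8-bit mask (ERM white); the sidecar records the
#' geometry, the true-pixel count and a provenance summary of the
#' coverage counts.
#'
#' @param mask an \linkS4class{EPIMask}.
#' @param pngPath output PNG path.
#' @param jsonPath sidecar path; defaults to the PNG path with a
#'   \code{.json} extension.
#' @return invisibly, \code{pngPath}.
#' @export
writeEPI <- function(mask, pngPath,
                     jsonPath = sub("\\.png$", ".json", pngPath)) {
    stopifnot(is(mask, "EPIMask"))
    png::writePNG(mask@grid * 1, pngPath)
    side <- list(
        geometry = .geometryToList(mask@geometry),
        erm_pixels = sum(mask@grid),
        provenance = list(
            max_coverage = max(mask@coverage),
            total_contributions = sum(mask@coverage)
        )
    )
    jsonlite::write_json(side, jsonPath, auto_unbox = TRUE, digits = NA)
    invisible(pngPath)
}

#' Read an EPI mask written by \code{\link{writeEPI}}
#'
#' Coverage counts are not stored in the PNG, so the returned mask has
#' coverage 1 on every ERM pixel.
#'
#' @param pngPath PNG path.
#' @param jsonPath sidecar path (for the geometry); defaults next to
#'   the PNG.
#' @return an \linkS4class{EPIMask}.
#' @export
readEPI <- function(pngPath, jsonPath = sub("\\.png$", ".json", pngPath)) {
    img <- png::readPNG(pngPath)
    if (length(dim(img)) == 3L) {
        img <- img[, , 1L]
    }
    grid <- img >= 0.5
    g <- if (file.exists(jsonPath)) {
        .geometryFromList(jsonlite::fromJSON(jsonPath)$geometry)
    } else {
        ScanGeometry(enfaceWidth = ncol(grid), enfaceHeight = nrow(grid))
    }
    cov <- matrix(0L, nrow(grid), ncol(grid))
    cov[grid] <- 1L
    new("EPIMask", grid = grid, coverage = cov, geometry = g)
}

#' Read / write observer ratings as CSV
#'
#' The CSV has a \code{case_id} column followed by one integer column
#' per rater.
#'
#' @param path CSV path.
#' @param acceptThreshold acceptance threshold for the resulting study.
#' @return \code{readRatings} returns an \linkS4class{ObserverStudy}.
#' @export
readRatings <- function(path, acceptThreshold = 4L) {
    d <- utils::read.csv(path)
    if (!"case_id" %in% names(d)) {
        stop("ratings CSV must have a 'case_id' column")
    }
    m <- as.matrix(d[, setdiff(names(d), "case_id"), drop = FALSE])
    ObserverStudy(m, acceptThreshold = acceptThreshold)
}

#' @param study an \linkS4class{ObserverStudy}.
#' @rdname readRatings
#' @export
writeRatings <- function(study, path) {
    stopifnot(is(study, "ObserverStudy"))
    d <- data.frame(case_id = seq_len(nrow(study@ratings)))
    d <- cbind(d, as.data.frame(study@ratings))
    utils::write.csv(d, path, row.names = FALSE)
    invisible(path)
}
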