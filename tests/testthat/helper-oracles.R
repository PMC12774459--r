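# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately recompute everything per pixel / per cell
# rather than reusing the package's vectorized paths.

randomGeometry <- function(maxDim = 32L, maxScans = 4L) {
    ScanGeometry(
        bscanWidth = sample(8:64, 1),
        bscanHeight = 16L,
        enfaceWidth = sample(4:maxDim, 1),
        enfaceHeight = sample(4:maxDim, 1),
        nScans = sample(seq_len(maxScans), 1)
    )
}

# per-pixel membership test over all detection rectangles
bruteEPI <- function(ds, minConfidence = 0.25) {
    g <- geometry(ds)
    d <- as.data.frame(ds)
    d <- d[d$confidence >= minConfidence, , drop = FALSE]
    h <- g@enfaceHeight
    w <- g@enfaceWidth
    grid <- matrix(FALSE, h, w)
    cov <- matrix(0L, h, w)
    for (r0 in seq_len(h) - 1L) {
        for (c0 in seq_len(w) - 1L) {
            for (i in seq_len(nrow(d))) {
                ori <- d$orientation[i]
                n <- g@nScans
                extentPerp <- if (ori == "horizontal") h else w
                extentAlong <- if (ori == "horizontal") w else h
                b0 <- (d$scanIndex[i] * extentPerp) %/% n
                b1 <- ((d$scanIndex[i] + 1L) * extentPerp) %/% n
                a0 <- floor(d$x0[i] * extentAlong / g@bscanWidth + 1e-9)
                a1 <- ceiling(d$x1[i] * extentAlong / g@bscanWidth - 1e-9)
                perp <- if (ori == "horizontal") r0 else c0
                along <- if (ori == "horizontal") c0 else r0
                if (perp >= b0 && perp < b1 && along >= a0 && along < a1) {
                    grid[r0 + 1L, c0 + 1L] <- TRUE
                    cov[r0 + 1L, c0 + 1L] <- cov[r0 + 1L, c0 + 1L] + 1L
                }
            }
        }
    }
    list(grid = grid, coverage = cov)
}

# naive association: materialize every cumulative union and count pixels
bruteAssociation <- function(erm, masks) {
    n <- length(masks)
    total <- 0
    for (i in seq_len(n)) {
        cum <- matrix(FALSE, nrow(erm), ncol(erm))
        for (j in seq_len(i)) {
            cum <- cum | masks[[j]]
        }
        inter <- sum(erm & cum)
        uni <- sum(erm | cum)
        iou <- if (uni == 0) 0 else inter / uni
        wi <- -0.01 * i^2 - 0.07 * i + 1.666
        total <- total + wi * iou
    }
    total / n
}

randomMask <- function(h, w, p = 0.3) {
    matrix(stats::runif(h * w) < p, h, w)
}

# disjointify a list of random masks so they form valid class masks
disjointMasks <- function(h, w, n = 9L, p = 0.15) {
    taken <- matrix(FALSE, h, w)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        m <- randomMask(h, w, p) & !taken
        taken <- taken | m
        out[[i]] <- m
    }
    out
}

# wrap raw class masks into a ThicknessClasses without going through a map
makeClasses <- function(masks, geometry) {
    new("ThicknessClasses",
        edges = 500 - (0:length(masks)) * (280 / length(masks)),
        masks = masks, geometry = geometry
    )
}

smallGeometry <- function(h, w) {
    ScanGeometry(
        bscanWidth = 2L * w, bscanHeight = 8L,
        enfaceWidth = w, enfaceHeight = h, nScans = 1L
    )
}
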