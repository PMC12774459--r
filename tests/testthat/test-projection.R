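test_that("coordinate normalization rescales the B-scan axis linearly", {
    g <- ScanGeometry()
    expect_equal(normalizeCoordinate(768, g), 496)
    expect_equal(normalizeCoordinate(0, g), 0)
    expect_equal(normalizeCoordinate(384, g), 248)
    expect_error(normalizeCoordinate(-1, g), "outside")
    expect_error(normalizeCoordinate(769, g), "769")
})

test_that("scan bands follow the floor tiling and partition the frame", {
    g <- ScanGeometry()
    expect_equal(unname(scanBand(0, "horizontal", g)), c(0, 19))
    expect_equal(unname(scanBand(24, "horizontal", g)), c(476, 496))
    expect_equal(unname(scanBand(12, "horizontal", g)), c(238, 257))
    expect_error(scanBand(25, "horizontal", g), "outside")

    for (n in c(1L, 5L, 25L)) {
        gn <- ScanGeometry(nScans = n)
        covered <- integer(0)
        for (k in seq_len(n) - 1L) {
            b <- scanBand(k, "horizontal", gn)
            covered <- c(covered, seq(b[["start"]], b[["end"]] - 1L))
        }
        expect_equal(sort(covered), 0:(gn@enfaceHeight - 1L))
        expect_false(anyDuplicated(covered) > 0)
    }
})

test_that("detections project to band-aligned rectangles", {
    g <- ScanGeometry()
    r <- projectDetection(
        list(orientation = "horizontal", scanIndex = 12, x0 = 0, x1 = 768), g
    )
    expect_equal(unname(r$rows), c(238, 257))
    expect_equal(unname(r$cols), c(0, 496))

    r <- projectDetection(
        list(orientation = "vertical", scanIndex = 0, x0 = 0, x1 = 768), g
    )
    expect_equal(unname(r$rows), c(0, 496))
    expect_equal(unname(r$cols), c(0, 19))

    r <- projectDetection(
        list(orientation = "horizontal", scanIndex = 0, x0 = 384, x1 = 768), g
    )
    expect_equal(unname(r$cols), c(248, 496))
    expect_equal(unname(r$rows), c(0, 19))

    expect_error(
        projectDetection(
            list(orientation = "horizontal", scanIndex = 0, x0 = 10, x1 = 10), g
        ),
        "degenerate"
    )
})

test_that("a vertical detection is the transpose of its horizontal twin", {
    g <- ScanGeometry() # square en face frame
    for (k in c(0, 7, 24)) {
        h <- projectDetection(
            list(orientation = "horizontal", scanIndex = k, x0 = 100, x1 = 500), g
        )
        v <- projectDetection(
            list(orientation = "vertical", scanIndex = k, x0 = 100, x1 = 500), g
        )
        expect_equal(h$rows, v$cols)
        expect_equal(h$cols, v$rows)
    }
})

test_that("buildEPI merges detections into a union with coverage counts", {
    g <- ScanGeometry()
    expect_equal(sum(maskGrid(buildEPI(DetectionSet(geometry = g)))), 0)

    full <- DetectionSet(
        orientation = rep("horizontal", 25), scanIndex = 0:24,
        x0 = rep(0, 25), x1 = rep(768, 25), confidence = rep(1, 25),
        geometry = g
    )
    epi <- buildEPI(full)
    expect_equal(sum(maskGrid(epi)), 246016)
    expect_true(all(maskGrid(epi)))

    twice <- DetectionSet(
        orientation = rep("horizontal", 2), scanIndex = c(3L, 3L),
        x0 = c(100, 100), x1 = c(300, 300), confidence = c(0.9, 0.9),
        geometry = g
    )
    once <- DetectionSet(
        orientation = "horizontal", scanIndex = 3L,
        x0 = 100, x1 = 300, confidence = 0.9, geometry = g
    )
    e2 <- buildEPI(twice)
    e1 <- buildEPI(once)
    expect_equal(maskGrid(e2), maskGrid(e1))
    expect_equal(max(coverage(e2)), 2L)
    expect_equal(sum(coverage(e2)), 2L * sum(coverage(e1)))
})

test_that("low-confidence detections are dropped before projection", {
    ds <- DetectionSet(
        orientation = c("horizontal", "horizontal"), scanIndex = c(0L, 1L),
        x0 = c(0, 0), x1 = c(768, 768), confidence = c(0.1, 0.9)
    )
    epi <- buildEPI(ds, minConfidence = 0.25)
    b0 <- scanBand(0, "horizontal")
    expect_equal(sum(maskGrid(epi)[seq(b0[["start"]] + 1, b0[["end"]]), ]), 0)
    b1 <- scanBand(1, "horizontal")
    expect_true(all(maskGrid(epi)[seq(b1[["start"]] + 1, b1[["end"]]), ]))
})

test_that("adding detections never unsets pixels (union monotonicity)", {
    set.seed(11)
    g <- ScanGeometry()
    prev <- matrix(FALSE, 496, 496)
    d <- data.frame()
    for (i in 1:10) {
        ori <- sample(c("horizontal", "vertical"), 1)
        x0 <- runif(1, 0, 700)
        d <- rbind(d, data.frame(
            orientation = ori, scanIndex = sample(0:24, 1),
            x0 = x0, x1 = runif(1, x0 + 1, 768), confidence = 1
        ))
        ds <- DetectionSet(
            orientation = d$orientation, scanIndex = d$scanIndex,
            x0 = d$x0, x1 = d$x1, confidence = d$confidence, geometry = g
        )
        cur <- maskGrid(buildEPI(ds))
        expect_true(all(cur[prev]))
        expect_gte(sum(cur), sum(prev))
        prev <- cur
    }
})

test_that("buildEPI agrees with per-pixel brute force on random geometries", {
    set.seed(42)
    for (rep in 1:40) {
        g <- randomGeometry()
        nd <- sample(0:5, 1)
        ori <- sample(c("horizontal", "vertical"), nd, replace = TRUE)
        x0 <- runif(nd, 0, g@bscanWidth - 1)
        ds <- DetectionSet(
            orientation = ori,
            scanIndex = sample(seq_len(g@nScans) - 1L, nd, replace = TRUE),
            x0 = x0, x1 = pmin(g@bscanWidth, x0 + runif(nd, 0.5, g@bscanWidth)),
            confidence = runif(nd), geometry = g
        )
        want <- bruteEPI(ds)
        got <- buildEPI(ds)
        expect_identical(unname(maskGrid(got)), want$grid)
        expect_identical(unname(coverage(got)), want$coverage)
    }
})

test_that("invalid detections are rejected by the container", {
    expect_error(
        DetectionSet(
            orientation = "horizontal", scanIndex = 0L,
            x0 = 10, x1 = 800, confidence = 1
        ),
        "\\[0, 768\\]"
    )
    expect_error(
        DetectionSet(
            orientation = "diagonal", scanIndex = 0L,
            x0 = 0, x1 = 10, confidence = 1
        ),
        "orientation"
    )
    expect_error(
        DetectionSet(
            orientation = "horizontal", scanIndex = 30L,
            x0 = 0, x1 = 10, confidence = 1
        ),
        "scanIndex"
    )
})
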