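test_that("generation is deterministic given the spec", {
    spec <- ScenarioSpec(seed = 7, thicknessBlob = list(
        cx = 248, cy = 248, rx = 150, ry = 150, peak = 480,
        background = 260, noiseSd = 5
    ))
    d1 <- genDetections(spec)
    d2 <- genDetections(spec)
    expect_identical(as.data.frame(d1), as.data.frame(d2))
    expect_identical(
        thicknessValues(genThicknessMap(spec)),
        thicknessValues(genThicknessMap(spec))
    )
    expect_identical(ratings(genRatings(spec)), ratings(genRatings(spec)))
})

test_that("a full-frame ERM yields full-width detections on every scan", {
    spec <- ScenarioSpec(ermShape = list(
        type = "rect", x0 = 0, x1 = 496, y0 = 0, y1 = 496
    ))
    d <- as.data.frame(genDetections(spec))
    expect_equal(nrow(d), 50)
    expect_equal(sum(d$orientation == "horizontal"), 25)
    expect_equal(sum(d$orientation == "vertical"), 25)
    expect_true(all(d$x0 == 0 & d$x1 == 768))
})

test_that("an ERM confined to the first band hits one horizontal scan", {
    spec <- ScenarioSpec(ermShape = list(
        type = "rect", x0 = 100, x1 = 300, y0 = 0, y1 = 19
    ))
    d <- as.data.frame(genDetections(spec))
    h <- d[d$orientation == "horizontal", ]
    expect_equal(nrow(h), 1)
    expect_equal(h$scanIndex, 0L)
})

test_that("band-aligned rectangles survive the projection round-trip exactly", {
    # rows [0,19) is scan 0's band; cols [99,297) are vertical bands 5-14,
    # so the rectangle tiles exactly in both orientations
    spec <- ScenarioSpec(ermShape = list(
        type = "rect", x0 = 99, x1 = 297, y0 = 0, y1 = 19
    ))
    epi <- buildEPI(genDetections(spec))
    grid <- maskGrid(epi)
    want <- matrix(FALSE, 496, 496)
    want[1:19, 100:297] <- TRUE
    expect_identical(unname(grid), want)
    expect_equal(ermArea(epi), 198 * 19 * 400)
})

test_that("the projected EPI always covers the rasterized generating shape", {
    for (seed in 1:3) {
        set.seed(seed)
        x0 <- runif(1, 0, 300)
        y0 <- runif(1, 0, 300)
        shape <- list(
            type = "rect", x0 = x0, x1 = x0 + runif(1, 20, 150),
            y0 = y0, y1 = y0 + runif(1, 20, 150)
        )
        spec <- ScenarioSpec(seed = seed, ermShape = shape)
        grid <- maskGrid(buildEPI(genDetections(spec)))
        inner <- ermquant:::.shapeMask(shape, ScanGeometry())
        expect_true(all(grid[inner]))
    }
})

test_that("thickness blobs discretize as designed", {
    g <- ScanGeometry()
    blob <- function(peak, background) {
        ScenarioSpec(thicknessBlob = list(
            cx = 248, cy = 248, rx = 150, ry = 150,
            peak = peak, background = background, noiseSd = 0
        ))
    }
    tc <- discretizeThickness(genThicknessMap(blob(490, 200)))
    expect_gt(sum(classMasks(tc)[[1]]), 0) # class-1 core at the centre

    tc <- discretizeThickness(genThicknessMap(blob(200, 180)))
    expect_true(all(vapply(classMasks(tc), sum, numeric(1)) == 0))

    tc <- discretizeThickness(genThicknessMap(blob(230, 230)))
    expect_equal(sum(classMasks(tc)[[9]]), 496 * 496)
})

test_that("overlap targeting places the ERM where requested", {
    spec <- ScenarioSpec(overlapTarget = 0.5)
    d <- genDetections(spec)
    shape <- ermquant:::.shapeForOverlap(spec, ScanGeometry())
    rir <- ermquant:::.blobInRange(spec, ScanGeometry())
    m <- ermquant:::.shapeMask(shape, ScanGeometry())
    expect_equal(sum(m & rir) / sum(m), 0.5, tolerance = 0.01)
    expect_error(
        genDetections(ScenarioSpec(overlapTarget = 0.999999, ermShape = list(
            type = "rect", x0 = 0, x1 = 496, y0 = 0, y1 = 496
        ))),
        "not attainable"
    )
})

test_that("rating model drives the expected agreement regimes", {
    # strong shared latent signal, small rater noise -> high reliability
    iccs <- vapply(1:60, function(s) {
        spec <- ScenarioSpec(seed = s, ratingModel = list(
            latentMean = 3, latentSd = 1.2, raterShift = c(0, 0),
            noiseSd = 0.1
        ))
        icc21(genRatings(spec))$value
    }, numeric(1))
    expect_gt(mean(iccs), 0.9)

    # independent raters -> chance-level ordinal agreement
    kaps <- vapply(1:60, function(s) {
        spec <- ScenarioSpec(seed = s, ratingModel = list(
            latentMean = 3, latentSd = 0, raterShift = c(0, 0),
            noiseSd = 1.5
        ))
        quadraticWeightedKappa(genRatings(spec))
    }, numeric(1))
    expect_lt(abs(mean(kaps)), 0.06)

    # zero noise at the ceiling exercises the undefined-variance branch
    spec <- ScenarioSpec(ratingModel = list(
        latentMean = 5, latentSd = 0, raterShift = c(0, 0), noiseSd = 0
    ))
    s <- genRatings(spec)
    expect_true(all(ratings(s) == 5L))
    expect_warning(icc21(s), "undefined")
})

test_that("shapes outside the frame are refused", {
    expect_error(
        genDetections(ScenarioSpec(ermShape = list(
            type = "ellipse", cx = 480, cy = 248, rx = 50, ry = 50
        ))),
        "outside"
    )
})
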