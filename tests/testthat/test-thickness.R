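test_that("class bounds split 220-500 um into nine equal bands", {
    b1 <- classBounds(1)
    expect_equal(unname(b1), c(500 - 280 / 9, 500))
    b9 <- classBounds(9)
    expect_equal(unname(b9), c(220, 220 + 280 / 9))
    widths <- vapply(1:9, function(i) diff(classBounds(i)), numeric(1))
    expect_equal(unname(widths), rep(280 / 9, 9))
    expect_error(classBounds(0), "class index")
    expect_error(classBounds(10), "class index")
})

test_that("uniform maps land entirely in the expected class", {
    g <- ScanGeometry()
    mk <- function(v) discretizeThickness(ThicknessMap(matrix(v, 496, 496)))

    tc <- mk(490)
    expect_equal(sum(classMasks(tc)[[1]]), 496 * 496)
    for (i in 2:9) expect_equal(sum(classMasks(tc)[[i]]), 0)

    tc <- mk(230)
    expect_equal(sum(classMasks(tc)[[9]]), 496 * 496)
    for (i in 1:8) expect_equal(sum(classMasks(tc)[[i]]), 0)

    tc <- mk(210) # below the clinical range
    expect_true(all(vapply(classMasks(tc), sum, numeric(1)) == 0))

    tc <- mk(510) # above the clinical range
    expect_true(all(vapply(classMasks(tc), sum, numeric(1)) == 0))
})

test_that("boundary values follow the half-open convention", {
    g <- ScanGeometry()
    # one pixel per probed value, rest of the map far below range
    edges <- vapply(1:9, function(i) classBounds(i)[["lower"]], numeric(1))
    probes <- c(500, edges) # top of range plus every lower bound
    grid <- matrix(100, 496, 496)
    grid[1, seq_along(probes)] <- probes
    tc <- discretizeThickness(ThicknessMap(grid))
    # 500 belongs to class 1
    expect_true(classMasks(tc)[[1]][1, 1])
    # the lower bound of class i belongs to class i (not the thicker i-1)
    for (i in 1:9) {
        expect_true(classMasks(tc)[[i]][1, i + 1])
        if (i > 1) expect_false(classMasks(tc)[[i - 1]][1, i + 1])
    }
    # 220 is the lower bound of class 9
    expect_true(classMasks(tc)[[9]][1, 10])
})

test_that("the nine masks partition the in-range pixel set", {
    set.seed(5)
    for (rep in 1:5) {
        grid <- matrix(runif(496 * 496, 150, 550), 496, 496)
        grid[sample(length(grid), 500)] <- NA # unmeasured pixels
        tm <- ThicknessMap(grid)
        tc <- discretizeThickness(tm)
        stack <- Reduce(`+`, lapply(classMasks(tc), function(m) m * 1L))
        expect_true(all(stack <= 1L)) # disjoint
        inRange <- !is.na(grid) & grid >= 220 & grid <= 500
        expect_identical(stack == 1L, inRange) # exhaustive over the range
    }
})

test_that("cumulative unions are nested and end at the in-range set", {
    set.seed(6)
    grid <- matrix(runif(496 * 496, 180, 520), 496, 496)
    tm <- ThicknessMap(grid)
    tc <- discretizeThickness(tm)
    expect_identical(cumulativeUnion(tc, 1), classMasks(tc)[[1]])
    counts <- vapply(1:9, function(i) sum(cumulativeUnion(tc, i)), numeric(1))
    expect_true(all(diff(counts) >= 0))
    expect_equal(counts[9], sum(grid >= 220 & grid <= 500))
    expect_error(cumulativeUnion(tc, 10), "class index")
})

test_that("invalid and negative thickness values are rejected or excluded", {
    expect_error(
        validObject(new("ThicknessMap",
            grid = matrix(-5, 496, 496),
            validMask = matrix(TRUE, 496, 496), geometry = ScanGeometry()
        )),
        "non-negative"
    )
    grid <- matrix(300, 496, 496)
    valid <- matrix(TRUE, 496, 496)
    valid[1:10, ] <- FALSE
    tc <- discretizeThickness(ThicknessMap(grid, validMask = valid))
    expect_equal(sum(cumulativeUnion(tc, 9)), sum(valid))
})
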