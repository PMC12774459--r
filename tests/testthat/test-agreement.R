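study2 <- function(x, y, thr = 4L) ObserverStudy(cbind(x, y), thr)

test_that("correlations recover textbook rank/linear agreement", {
    s <- study2(1:5, 1:5)
    r <- ratingCorrelations(s)
    expect_equal(r$pearson, 1)
    expect_equal(r$spearman, 1)

    expect_equal(ratingCorrelations(study2(1:5, 5:1))$spearman, -1)
    expect_equal(ratingCorrelations(study2(1:5, c(1, 2, 3, 5, 4)))$spearman, 0.9)

    expect_warning(
        r0 <- ratingCorrelations(study2(rep(3, 5), 1:5)),
        "zero variance"
    )
    expect_true(is.na(r0$pearson))
})

test_that("quadratic weighted kappa matches hand-computed tables", {
    expect_equal(quadraticWeightedKappa(study2(c(1:5, 3), c(1:5, 3))), 1)

    # all pairs in the maximal-penalty cell (1 vs 5)
    expect_lte(quadraticWeightedKappa(study2(rep(1, 10), rep(5, 10))), 0)

    # symmetric two-category table: 20/5/5/20 on categories {1,2};
    # po_w = (40 + 10*15/16)/50, pe_w = 0.5 + 2*0.25*15/16 -> kappa = 0.6
    x <- c(rep(1, 20), rep(1, 5), rep(2, 5), rep(2, 20))
    y <- c(rep(1, 20), rep(2, 5), rep(1, 5), rep(2, 20))
    expect_equal(quadraticWeightedKappa(study2(x, y)), 0.6)

    # degenerate: both raters constant on the same category
    expect_equal(quadraticWeightedKappa(study2(rep(4, 5), rep(4, 5))), 1)
})

test_that("ICC(2,1) matches a two-way ANOVA oracle", {
    # identical columns, variance between cases -> perfect reliability
    base <- c(1, 2, 3, 4, 5, 5)
    expect_equal(icc21(study2(base, base))$value, 1)

    # constant but different columns -> nothing attributable to cases
    expect_lte(icc21(study2(rep(2, 6), rep(4, 6)))$value, 0)

    # toy matrix against mean squares from stats::aov
    m <- cbind(c(1, 2, 3, 4, 5, 5), c(2, 2, 4, 4, 5, 4))
    got <- icc21(ObserverStudy(m))
    long <- data.frame(
        y = as.vector(m),
        case = factor(rep(seq_len(nrow(m)), ncol(m))),
        rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
    )
    ms <- anova(stats::aov(y ~ case + rater, data = long))[["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    ns <- nrow(m); nr <- ncol(m)
    want <- (msr - mse) / (msr + (nr - 1) * mse + nr * (msc - mse) / ns)
    expect_equal(got$value, want)
    expect_equal(got$msr, msr)
    expect_equal(got$mse, mse)
    expect_lt(got$lower, got$value)
    expect_gt(got$upper, got$value)

    expect_warning(icc21(study2(rep(3, 4), rep(3, 4))), "undefined")
})

test_that("Bland-Altman bias and limits of agreement", {
    ba <- blandAltman(study2(rep(4, 10), rep(4, 10)))
    expect_equal(ba$meanDiff, 0)
    expect_equal(c(ba$loaLow, ba$loaHigh), c(0, 0))

    expect_equal(blandAltman(study2(c(1, 2), c(2, 1)))$meanDiff, 0)

    x <- rep(4, 30)
    y <- c(5, rep(4, 29)) # one disagreement of -1
    ba <- blandAltman(study2(x, y))
    expect_equal(ba$meanDiff, -1 / 30)
    expect_equal(ba$loaLow, ba$meanDiff - 1.96 * ba$sdDiff)
    expect_equal(ba$loaHigh, ba$meanDiff + 1.96 * ba$sdDiff)
})

test_that("acceptability indices: AAS, AR, NAS", {
    s <- study2(rep(5, 10), rep(5, 10))
    a <- acceptability(s)
    expect_equal(a$aas$pooled, 5)
    expect_equal(a$ar$pooled, 100)
    expect_equal(a$nas, 1)

    expect_equal(acceptability(study2(rep(1, 10), rep(1, 10)))$nas, -1)

    # 25/30 and 26/30 acceptances pool to 85% over all 60 ratings
    e1 <- c(rep(4, 25), rep(3, 5))
    e2 <- c(rep(4, 26), rep(3, 4))
    a <- acceptability(study2(e1, e2))
    expect_equal(unname(a$ar$perRater), c(2500 / 30, 2600 / 30))
    expect_equal(a$ar$pooled, 85)
    # neutral 3s count neither as accept nor reject
    expect_equal(a$nas, 51 / 60)

    # pooled AR is the ratings-weighted mean of per-rater rates
    expect_equal(a$ar$pooled, mean(a$ar$perRater))
})

test_that("binary accept/reject kappa matches the 2x2 closed form", {
    s <- study2(c(rep(5, 8), 2, 2), c(rep(4, 8), 1, 2))
    expect_equal(binaryAcceptKappa(s), 1)

    # a=20 both-accept, b=2, c=3, d=5 -> kappa = 188/338
    x <- c(rep(5, 20), rep(5, 2), rep(2, 3), rep(2, 5))
    y <- c(rep(5, 20), rep(2, 2), rep(5, 3), rep(2, 5))
    expect_equal(binaryAcceptKappa(study2(x, y)), 188 / 338)

    # degenerate marginals with perfect agreement
    expect_equal(binaryAcceptKappa(study2(rep(5, 6), rep(5, 6))), 1)
})

test_that("metrics are invariant to case reordering", {
    set.seed(3)
    m <- matrix(sample(1:5, 60, replace = TRUE, prob = c(1, 1, 2, 5, 6)), ncol = 2)
    s1 <- ObserverStudy(m)
    s2 <- ObserverStudy(m[sample(nrow(m)), ])
    r1 <- agreementReport(s1)
    r2 <- agreementReport(s2)
    expect_equal(r1$weightedKappa, r2$weightedKappa)
    expect_equal(r1$icc$value, r2$icc$value)
    expect_equal(r1$correlations$pearson, r2$correlations$pearson)
    expect_equal(r1$acceptability, r2$acceptability)
    expect_equal(r1$blandAltman$sdDiff, r2$blandAltman$sdDiff)
})

test_that("ratings outside the Likert range are rejected", {
    expect_error(ObserverStudy(cbind(c(1, 6), c(2, 3))), "ratings")
    expect_error(ObserverStudy(cbind(c(1, 2), c(0, 3))), "ratings")
    expect_error(ObserverStudy(matrix(3, 1, 2)), "at least 2")
})
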