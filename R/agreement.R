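# Observer-study statistics for clinical validation: correlation,
# chance-corrected agreement, reliability, bias and acceptability
# indices computed from a case x rater matrix of 5-point Likert scores.

.pairCols <- function(study) {
    r <- study@ratings
    if (ncol(r) != 2L) {
        stop("this metric is defined for exactly two raters")
    }
    list(x = as.numeric(r[, 1L]), y = as.numeric(r[, 2L]))
}

#' Pearson and Spearman correlation between two raters
#'
#' Product-moment and rank correlation of the two rating vectors; ties
#' get average ranks. A rater with zero variance makes the coefficient
#' undefined: the value is returned as \code{NA} with a warning rather
#' than a silent \code{NaN}.
#'
#' @param study an \linkS4class{ObserverStudy} with two raters.
#' @return list with \code{pearson} and \code{spearman}.
#' @examples
#' s <- ObserverStudy(cbind(1:5, c(1, 2, 3, 5, 4)))
#' ratingCorrelations(s)$spearman # 0.9
#' @export
ratingCorrelations <- function(study) {
    stopifnot(is(study, "ObserverStudy"))
    p <- .pairCols(study)
    if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) {
        warning("a rater has zero variance; correlations are undefined")
        return(list(pearson = NA_real_, spearman = NA_real_))
    }
    list(
        pearson = stats::cor(p$x, p$y),
        spearman = stats::cor(p$x, p$y, method = "spearman")
    )
}

#' Quadratic weighted Cohen's kappa
#'
#' Agreement on the ordinal 5-point scale with disagreement weights
#' \code{w_ij = 1 - (i - j)^2 / (k - 1)^2}, chance agreement from the
#' marginal products. When both raters use a single identical category
#' the statistic is degenerate and defined as 1.
#'
#' @param study an \linkS4class{ObserverStudy} with two raters.
#' @param categories the ordinal category values (default \code{1:5}).
#' @return the weighted kappa in \code{[-1, 1]}.
#' @examples
#' s <- ObserverStudy(cbind(c(1:5, 5), c(1:5, 5)))
#' quadraticWeightedKappa(s) # 1
#' @export
quadraticWeightedKappa <- function(study, categories = 1:5) {
    stopifnot(is(study, "ObserverStudy"))
    p <- .pairCols(study)
    k <- length(categories)
    tab <- table(
        factor(p$x, levels = categories),
        factor(p$y, levels = categories)
    )
    prop <- tab / sum(tab)
    idx <- seq_len(k)
    w <- 1 - outer(idx, idx, function(i, j) (i - j)^2) / (k - 1)^2
    po <- sum(w * prop)
    pe <- sum(w * outer(rowSums(prop), colSums(prop)))
    if (abs(1 - pe) < .Machine$double.eps^0.5) {
        # both raters confined to one category
        return(if (abs(1 - po) < .Machine$double.eps^0.5) 1 else NA_real_)
    }
    1 - (1 - po) / (1 - pe)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' Mean-squares decomposition of the full case x rater matrix (rows =
#' cases, columns = raters):
#' \code{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}.
#' The 95\% confidence interval uses the standard F-distribution method
#' with Satterthwaite degrees of freedom.
#'
#' @param study an \linkS4class{ObserverStudy} (any number >= 2 of
#'   raters).
#' @param conf confidence level (default 0.95).
#' @return list with \code{value}, \code{lower}, \code{upper} and the
#'   mean squares \code{msr}, \code{msc}, \code{mse}.
#' @examples
#' m <- cbind(c(1, 2, 3, 4, 5, 5), c(1, 2, 3, 4, 5, 4))
#' icc21(ObserverStudy(m))$value
#' @export
icc21 <- function(study, conf = 0.95) {
    stopifnot(is(study, "ObserverStudy"))
    x <- study@ratings
    ns <- nrow(x)
    nr <- ncol(x)
    gm <- mean(x)
    sst <- sum((x - gm)^2)
    ssr <- nr * sum((rowMeans(x) - gm)^2)
    ssc <- ns * sum((colMeans(x) - gm)^2)
    sse <- sst - ssr - ssc
    msr <- ssr / (ns - 1)
    msc <- ssc / (nr - 1)
    mse <- sse / ((ns - 1) * (nr - 1))
    denom <- msr + (nr - 1) * mse + nr * (msc - mse) / ns
    if (abs(denom) < .Machine$double.eps) {
        warning("no variance anywhere; ICC is undefined")
        return(list(
            value = NA_real_, lower = NA_real_, upper = NA_real_,
            msr = msr, msc = msc, mse = mse
        ))
    }
    icc <- (msr - mse) / denom
    alpha <- 1 - conf
    # F-based interval (two-way random, absolute agreement, single)
    a <- (nr * icc) / (ns * (1 - icc))
    b <- 1 + (nr * icc * (ns - 1)) / (ns * (1 - icc))
    v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (nr - 1) + (b * mse)^2 / ((ns - 1) * (nr - 1)))
    fl <- stats::qf(1 - alpha / 2, ns - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, ns - 1)
    lower <- ns * (msr - fl * mse) /
        (fl * (nr * msc + (nr * ns - nr - ns) * mse) + ns * msr)
    upper <- ns * (fu * msr - mse) /
        (nr * msc + (nr * ns - nr - ns) * mse + ns * fu * msr)
    list(
        value = icc, lower = lower, upper = upper,
        msr = msr, msc = msc, mse = mse
    )
}

#' Bland-Altman bias and limits of agreement
#'
#' Per-case differences rater 1 minus rater 2, their mean and standard
#' deviation, and limits of agreement mean +/- 1.96 sd.
#'
#' @param study an \linkS4class{ObserverStudy} with two raters.
#' @return list with \code{meanDiff}, \code{sdDiff}, \code{loaLow},
#'   \code{loaHigh} and the \code{differences} vector.
#' @examples
#' m <- cbind(rep(4, 30), c(rep(4, 29), 5))
#' blandAltman(ObserverStudy(m))$meanDiff # -1/30
#' @export
blandAltman <- function(study) {
    stopifnot(is(study, "ObserverStudy"))
    p <- .pairCols(study)
    d <- p$x - p$y
    m <- mean(d)
    s <- stats::sd(d)
    list(
        meanDiff = m, sdDiff = s,
        loaLow = m - 1.96 * s, loaHigh = m + 1.96 * s,
        differences = d
    )
}

#' Clinical acceptability indices
#'
#' AAS: mean Likert rating. AR: percentage of ratings at or above the
#' acceptance threshold. NAS: (acceptances - rejections) / N, where a
#' rejection is a rating of 2 or below and a neutral 3 counts in
#' neither. Per-rater values and values pooled over all ratings are
#' returned; the pooled AR is computed over the full set of ratings,
#' not by averaging per-rater percentages.
#'
#' @param study an \linkS4class{ObserverStudy}.
#' @return list with \code{aas}, \code{ar} (each with \code{perRater}
#'   and \code{pooled}) and \code{nas}.
#' @examples
#' m <- cbind(rep(5, 10), rep(4, 10))
#' acceptability(ObserverStudy(m))$ar$pooled # 100
#' @export
acceptability <- function(study) {
    stopifnot(is(study, "ObserverStudy"))
    r <- study@ratings
    thr <- study@acceptThreshold
    acc <- r >= thr
    rej <- r <= 2L
    list(
        aas = list(
            perRater = colMeans(r),
            pooled = mean(r)
        ),
        ar = list(
            perRater = 100 * colMeans(acc),
            pooled = 100 * mean(acc)
        ),
        nas = (sum(acc) - sum(rej)) / length(r)
    )
}

#' Cohen's kappa on binary accept/reject decisions
#'
#' Dichotomizes the ratings at the study's acceptance threshold and
#' computes unweighted Cohen's kappa between the two raters. When the
#' marginals are degenerate (both raters constant), the statistic is 1
#' if observed agreement is perfect.
#'
#' @param study an \linkS4class{ObserverStudy} with two raters.
#' @return kappa in \code{[-1, 1]}.
#' @examples
#' m <- cbind(c(rep(5, 8), 2, 2), c(rep(5, 8), 2, 2))
#' binaryAcceptKappa(ObserverStudy(m)) # 1
#' @export
binaryAcceptKappa <- function(study) {
    stopifnot(is(study, "ObserverStudy"))
    p <- .pairCols(study)
    thr <- study@acceptThreshold
    a <- factor(p$x >= thr, levels = c(FALSE, TRUE))
    b <- factor(p$y >= thr, levels = c(FALSE, TRUE))
    tab <- table(a, b) / length(a)
    po <- sum(diag(tab))
    pe <- sum(rowSums(tab) * colSums(tab))
    if (abs(1 - pe) < .Machine$double.eps^0.5) {
        return(if (abs(1 - po) < .Machine$double.eps^0.5) 1 else NA_real_)
    }
    (po - pe) / (1 - pe)
}

#' Complete observer-study agreement report
#'
#' Runs every agreement and acceptability metric on one study and
#' returns them in a single list; \code{print} gives a readable table.
#'
#' @param study an \linkS4class{ObserverStudy} with two raters.
#' @return list of class \code{"agreementReport"} with elements
#'   \code{correlations}, \code{weightedKappa}, \code{icc},
#'   \code{blandAltman}, \code{acceptability}, \code{binaryKappa} and
#'   \code{meta} (threshold, difference direction).
#' @examples
#' set.seed(7)
#' base <- pmin(5, pmax(1, round(rnorm(30, 4.4, 0.6))))
#' m <- cbind(base, pmin(5, pmax(1, base + sample(c(-1, 0, 0, 0, 1), 30,
#'     replace = TRUE
#' ))))
#' agreementReport(ObserverStudy(m))
#' @export
agreementReport <- function(study) {
    stopifnot(is(study, "ObserverStudy"))
    out <- list(
        correlations = ratingCorrelations(study),
        weightedKappa = quadraticWeightedKappa(study),
        icc = icc21(study),
        blandAltman = blandAltman(study),
        acceptability = acceptability(study),
        binaryKappa = binaryAcceptKappa(study),
        meta = list(
            acceptThreshold = study@acceptThreshold,
            differenceDirection = "rater1 - rater2",
            nCases = nrow(study@ratings),
            nRaters = ncol(study@ratings)
        )
    )
    class(out) <- "agreementReport"
    out
}

#' @param x an \code{agreementReport}.
#' @param ... ignored.
#' @rdname agreementReport
#' @export
print.agreementReport <- function(x, ...) {
    cat("Observer-study agreement report\n")
    cat(sprintf(
        "  %d cases x %d raters, accept threshold >= %d\n",
        x$meta$nCases, x$meta$nRaters, x$meta$acceptThreshold
    ))
    cat(sprintf("  Pearson r          %8.3f\n", x$correlations$pearson))
    cat(sprintf("  Spearman rho       %8.3f\n", x$correlations$spearman))
    cat(sprintf("  Weighted kappa     %8.3f\n", x$weightedKappa))
    cat(sprintf(
        "  ICC(2,1)           %8.3f (95%% CI %.2f-%.2f)\n",
        x$icc$value, x$icc$lower, x$icc$upper
    ))
    cat(sprintf(
        "  Mean diff (BA)     %8.3f +/- %.2f, LoA [%.3f, %.3f]\n",
        x$blandAltman$meanDiff, x$blandAltman$sdDiff,
        x$blandAltman$loaLow, x$blandAltman$loaHigh
    ))
    cat(sprintf(
        "  AAS                %8.2f (%s)\n", x$acceptability$aas$pooled,
        paste(sprintf("%.2f", x$acceptability$aas$perRater), collapse = ", ")
    ))
    cat(sprintf(
        "  AR                 %7.1f%% (%s)\n", x$acceptability$ar$pooled,
        paste(sprintf("%.1f%%", x$acceptability$ar$perRater), collapse = ", ")
    ))
    cat(sprintf("  NAS                %+8.2f\n", x$acceptability$nas))
    cat(sprintf("  Binary kappa       %8.3f\n", x$binaryKappa))
    invisible(x)
}
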