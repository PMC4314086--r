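#' Quadratic OLS fit of CV on mean abundance
#'
#' Ordinary least squares of `y` on `(1, x, x^2)` with the plain coefficient
#' of determination `r2 = 1 - SSE/SST`.  Used to quantify how much of the
#' noise variation is explained by the mean expression level in each sex.
#' Fits are on the raw (linear) scale; no weighting, free intercept.
#'
#' @param x per-transcript mean abundance (length >= 4, not all identical).
#' @param y per-transcript CV.
#' @return A [QuadraticFit-class].
#' @details A constant `y` gives `SST = 0`; `r2` is then defined as 0 with a
#'   warning.  A design that cannot support three coefficients (fewer than
#'   4 points, constant `x`, or exact collinearity) is a degenerate-fit
#'   error.
#' @examples
#' x <- 1:10
#' fitQuadratic(x, 2 - 0.3 * x + 0.01 * x^2)  # r2 = 1
#' @export
fitQuadratic <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 4L)
        stop("degenerate fit: need >= 4 points for a quadratic")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("x and y must be finite")
    if (length(unique(x)) < 3L)
        stop("degenerate fit: x support cannot identify a quadratic")
    fit <- stats::lm(y ~ x + I(x^2))
    b <- stats::coef(fit)
    if (anyNA(b)) stop("degenerate fit: collinear design")
    sst <- sum((y - mean(y))^2)
    if (sst == 0) {
        warning("constant y: SST = 0, r2 defined as 0")
        r2 <- 0
    } else {
        r2 <- 1 - sum(stats::residuals(fit)^2) / sst
    }
    new("QuadraticFit",
        coefficients = stats::setNames(as.numeric(b), c("b0", "b1", "b2")),
        r2 = max(0, min(1, r2)), nPoints = length(x))
}

#' Female/male ratio of mean--CV coupling strength
#'
#' For one strain or pooled genotype, fits the quadratic of per-transcript
#' CV on per-transcript replicate mean separately in females and males and
#' returns both coefficients of determination plus their ratio.  A ratio
#' well above 1 means the mean level explains much more of the noise in
#' females, i.e. male noise is driven more by mean-independent factors.
#'
#' @inheritParams pairedCVExpression
#' @return Named list with `r2Female`, `r2Male`, `ratio` and the two
#'   [QuadraticFit-class] objects (`fitFemale`, `fitMale`).  If `r2Male` is
#'   exactly 0 the ratio is `Inf`, flagging an undefined quotient.
#' @export
r2SexRatio <- function(ds, group, by = c("strain", "genotype")) {
    stopifnot(is(ds, "ExpressionDataset"))
    by <- match.arg(by)
    cd <- SummarizedExperiment::colData(ds)
    sel <- cd[[by]] == group
    if (!any(sel)) stop("no samples with ", by, " = '", group, "'")
    if (!all(c("female", "male") %in% cd$sex[sel]))
        stop("group '", group, "' lacks one sex; both are required")
    m <- SummarizedExperiment::assay(ds, "abundance")[, sel, drop = FALSE]
    sexFit <- function(sx) {
        sub <- m[, cd$sex[sel] == sx, drop = FALSE]
        if (ncol(sub) < 2L)
            stop("sex '", sx, "' needs >= 2 replicates")
        mu <- rowMeans(sub)
        keep <- mu > 0
        cv <- apply(sub[keep, , drop = FALSE], 1L, stats::sd) / mu[keep]
        fitQuadratic(mu[keep], cv)
    }
    ff <- sexFit("female")
    fm <- sexFit("male")
    ratio <- if (fm@r2 == 0) Inf else ff@r2 / fm@r2
    list(r2Female = ff@r2, r2Male = fm@r2, ratio = ratio,
         fitFemale = ff, fitMale = fm)
}
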