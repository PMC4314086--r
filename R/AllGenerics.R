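#' Accessor generics
#'
#' Small accessor family for the package's result objects: unit ids and the
#' two CV columns of a [PairedCV-class]; the observed statistic, simulated
#' null, percentiles and p-values of a [SignedRankResult-class] or
#' [DispersalTestResult-class].
#'
#' @param x an object of the documented classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))
#' @rdname accessors
#' @export
setGeneric("cvFemale", function(x) standardGeneric("cvFemale"))
#' @rdname accessors
#' @export
setGeneric("cvMale", function(x) standardGeneric("cvMale"))
#' @rdname accessors
#' @export
setGeneric("pairColors", function(x) standardGeneric("pairColors"))
#' @rdname accessors
#' @export
setGeneric("nDropped", function(x) standardGeneric("nDropped"))
#' @rdname accessors
#' @export
setGeneric("observedW", function(x) standardGeneric("observedW"))
#' @rdname accessors
#' @export
setGeneric("simulatedW", function(x) standardGeneric("simulatedW"))
#' @rdname accessors
#' @export
setGeneric("pUpper", function(x) standardGeneric("pUpper"))
#' @rdname accessors
#' @export
setGeneric("pLower", function(x) standardGeneric("pLower"))
#' @rdname accessors
#' @export
setGeneric("nullQuantiles", function(x) standardGeneric("nullQuantiles"))
#' @rdname accessors
#' @export
setGeneric("observedFraction", function(x) standardGeneric("observedFraction"))
#' @rdname accessors
#' @export
setGeneric("dispersalRecords", function(x) standardGeneric("dispersalRecords"))

#' @rdname accessors
#' @export
setMethod("unitIds", "PairedCV", function(x) x@unitId)
#' @rdname accessors
#' @export
setMethod("cvFemale", "PairedCV", function(x) x@cvF)
#' @rdname accessors
#' @export
setMethod("cvMale", "PairedCV", function(x) x@cvM)
#' @rdname accessors
#' @export
setMethod("pairColors", "PairedCV", function(x) x@color)
#' @rdname accessors
#' @export
setMethod("nDropped", "PairedCV", function(x) x@dropped)
#' @rdname accessors
#' @export
setMethod("length", "PairedCV", function(x) length(x@unitId))

#' Subset a PairedCV table
#'
#' @param x a [PairedCV-class].
#' @param i logical, integer or character index over units.
#' @param j,...,drop ignored.
#' @return A [PairedCV-class] with the selected units.
#' @export
setMethod("[", "PairedCV", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@unitId)
    PairedCV(x@unitId[i], x@cvF[i], x@cvM[i], x@color[i], x@dropped)
})

#' Coerce a PairedCV to data.frame
#'
#' @param x a [PairedCV-class].
#' @param ... ignored.
#' @return data.frame with columns `unit_id`, `cv_f`, `cv_m`, `color`.
#' @export
as.data.frame.PairedCV <- function(x, ...) {
    data.frame(unit_id = x@unitId, cv_f = x@cvF, cv_m = x@cvM,
               color = x@color, stringsAsFactors = FALSE)
}

#' @rdname accessors
#' @export
setMethod("observedW", "SignedRankResult", function(x) x@observedW)
#' @rdname accessors
#' @export
setMethod("simulatedW", "SignedRankResult", function(x) x@simulatedW)
#' @rdname accessors
#' @export
setMethod("pUpper", "SignedRankResult", function(x) x@pUpper)
#' @rdname accessors
#' @export
setMethod("pLower", "SignedRankResult", function(x) x@pLower)
#' @rdname accessors
#' @export
setMethod("nullQuantiles", "SignedRankResult",
          function(x) c(p5 = x@p5, p95 = x@p95))

#' @rdname accessors
#' @export
setMethod("observedFraction", "DispersalTestResult",
          function(x) x@observedFraction)
#' @rdname accessors
#' @export
setMethod("pUpper", "DispersalTestResult", function(x) x@pUpper)
#' @rdname accessors
#' @export
setMethod("pLower", "DispersalTestResult", function(x) x@pLower)
#' @rdname accessors
#' @export
setMethod("nullQuantiles", "DispersalTestResult",
          function(x) c(p5 = x@p5, p95 = x@p95))

#' @rdname accessors
#' @export
setMethod("dispersalRecords", "DispersalTable", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("nDropped", "DispersalTable", function(x) x@dropped)
#' @rdname accessors
#' @export
setMethod("length", "DispersalTable", function(x) nrow(x@records))

setMethod("show", "PairedCV", function(object) {
    cat("PairedCV with", length(object), "unit(s);",
        object@dropped, "dropped by replication filter\n")
    ncol <- sum(!is.na(object@color))
    if (ncol) cat(" ", ncol, "unit(s) carry a chromatin color\n")
    if (length(object)) {
        k <- min(5L, length(object))
        print(utils::head(as.data.frame(object), k))
        if (length(object) > k) cat("  ...\n")
    }
})

setMethod("show", "SignedRankResult", function(object) {
    cat("Monte Carlo-Wilcoxon matched-pairs signed-ranks test\n")
    cat("  label:", object@label, "  n pairs:", object@nPairs, "\n")
    cat(sprintf("  observed W: %.6g\n", object@observedW))
    cat(sprintf("  simulated W [5th/95th]: %.6g / %.6g  (n_sim = %d)\n",
                object@p5, object@p95, object@nSim))
    cat(sprintf("  P_upper/P_lower: %s/%s\n",
                formatMCPValue(object@pUpper, object@nSim),
                formatMCPValue(object@pLower, object@nSim)))
})

setMethod("show", "QuadraticFit", function(object) {
    b <- object@coefficients
    cat(sprintf("Quadratic fit: cv = %.4g + %.4g*mean + %.4g*mean^2\n",
                b[1], b[2], b[3]))
    cat(sprintf("  R^2 = %.4f over %d points\n", object@r2, object@nPoints))
})

setMethod("show", "DispersalTable", function(object) {
    df <- object@records
    cat("DispersalTable with", nrow(df), "species\n")
    tt <- table(df$taxon)
    cat("  taxa:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
    st <- table(df$chromosome_system)
    cat("  systems:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "DispersalTestResult", function(object) {
    cat("Heterogamety-biased dispersal permutation test\n")
    cat("  subset:", object@subset, "  n:", object@n, "\n")
    cat(sprintf("  observed fraction: %.2f\n", object@observedFraction))
    cat(sprintf("  simulated [5th/95th]: %.2f / %.2f  (n_sim = %d)\n",
                object@p5, object@p95, object@nSim))
    cat(sprintf("  P_upper/P_lower: %s/%s\n",
                formatMCPValue(object@pUpper, object@nSim),
                formatMCPValue(object@pLower, object@nSim)))
})
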