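#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionDataset: replicated female/male expression data
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' transcripts-by-samples abundance matrix (assay `"abundance"`) together with
#' the sample annotation the noise analyses require: `strain`, `genotype`,
#' `sex` (`"female"`/`"male"`) and `replicate` index.  All downstream
#' computations (per-sex coefficients of variation, genotype pooling,
#' mean--CV regressions) key off these four columns.
#'
#' @slot .Data inherited `SummarizedExperiment` representation.
#' @seealso [ExpressionDataset()], [pairedCVExpression()], [poolByGenotype()]
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    cd <- SummarizedExperiment::colData(object)
    need <- c("strain", "genotype", "sex", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if ("sex" %in% colnames(cd) &&
        !all(cd$sex %in% c("female", "male")))
        msg <- c(msg, "sex must be 'female' or 'male'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "transcript ids (rownames) must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, transcripts x samples; rownames are
#'   transcript ids, colnames sample ids.
#' @param strain,sex,replicate per-sample annotation vectors (length
#'   `ncol(values)`).
#' @param genotype per-sample genotype labels; defaults to `strain`.
#' @param rowRanges optional [GenomicRanges::GRanges] of gene spans, one per
#'   transcript, used by chromatin-color assignment.
#' @return An [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rexp(12, 1 / 100), 2, 6,
#'             dimnames = list(c("t1", "t2"), paste0("s", 1:6)))
#' ed <- ExpressionDataset(m, strain = rep("A", 6),
#'                         sex = rep(c("female", "male"), each = 3),
#'                         replicate = rep(1:3, 2))
#' ed
#' @export
ExpressionDataset <- function(values, strain, sex, replicate,
                              genotype = strain, rowRanges = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- paste0("t", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("sample", seq_len(ncol(values)))
    cd <- DataFrame(strain = as.character(strain),
                    genotype = as.character(genotype),
                    sex = as.character(sex),
                    replicate = as.integer(replicate),
                    row.names = colnames(values))
    args <- list(assays = list(abundance = values), colData = cd)
    if (!is.null(rowRanges)) {
        if (length(rowRanges) != nrow(values))
            stop("rowRanges must have one range per transcript")
        names(rowRanges) <- rownames(values)
        args$rowRanges <- rowRanges
    }
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("ExpressionDataset", se)
}

#' PairedCV: per-unit female and male coefficients of variation
#'
#' One row per analysis unit (transcript, or strain/trait cell), holding the
#' female CV and male CV computed over that unit's replicates, plus an
#' optional chromatin-color label used by the stratified test.  Units that
#' fail the replication filter (fewer than two replicates in either sex, or a
#' non-positive mean) never appear as rows; their count is kept in `dropped`.
#'
#' @slot unitId character, unique unit identifiers.
#' @slot cvF,cvM numeric, finite and non-negative; same length as `unitId`.
#' @slot color character, one of the five chromatin colors or `NA`.
#' @slot dropped integer, number of units removed by the replication filter.
#' @exportClass PairedCV
setClass("PairedCV",
         representation(unitId = "character", cvF = "numeric",
                        cvM = "numeric", color = "character",
                        dropped = "integer"))

setValidity("PairedCV", function(object) {
    n <- length(object@unitId)
    msg <- character()
    if (length(object@cvF) != n || length(object@cvM) != n ||
        length(object@color) != n)
        msg <- c(msg, "unitId, cvF, cvM, color must have equal length")
    if (anyDuplicated(object@unitId))
        msg <- c(msg, "unit ids must be unique")
    if (n && (!all(is.finite(object@cvF)) || !all(is.finite(object@cvM))))
        msg <- c(msg, "CVs must be finite")
    if (n && (any(object@cvF < 0) || any(object@cvM < 0)))
        msg <- c(msg, "CVs must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Construct a PairedCV table
#'
#' @param unitId character vector of unit ids.
#' @param cvF,cvM numeric vectors of female and male CVs.
#' @param color optional per-unit chromatin color (recycled `NA` otherwise).
#' @param dropped count of units removed upstream by replication filters.
#' @return A [PairedCV-class] object.
#' @export
PairedCV <- function(unitId, cvF, cvM, color = NA_character_, dropped = 0L) {
    n <- length(unitId)
    new("PairedCV", unitId = as.character(unitId), cvF = as.numeric(cvF),
        cvM = as.numeric(cvM), color = rep_len(as.character(color), n),
        dropped = as.integer(dropped))
}

#' SignedRankResult: observed W and its Monte Carlo null
#'
#' Holds the observed Wilcoxon sum of signed ranks W over the female-minus-
#' male CV differences, the vector of W values recomputed after each random
#' rearrangement of the pooled CVs, the 5th/95th percentiles of that null,
#' and the upper/lower permutation p-values (fractions of simulated W at or
#' above, and at or below, the observed one).
#'
#' @slot label analysis label (strain, genotype, trait or color).
#' @slot nPairs number of CV pairs entering the statistic.
#' @slot observedW observed signed-rank sum.
#' @slot simulatedW numeric vector of length `nSim`.
#' @slot p5,p95 percentiles of `simulatedW` (linear interpolation).
#' @slot pUpper,pLower permutation p-values in `[0, 1]`.
#' @slot nSim number of Monte Carlo rearrangements.
#' @slot seed RNG seed used for the rearrangements.
#' @exportClass SignedRankResult
setClass("SignedRankResult",
         representation(label = "character", nPairs = "integer",
                        observedW = "numeric", simulatedW = "numeric",
                        p5 = "numeric", p95 = "numeric",
                        pUpper = "numeric", pLower = "numeric",
                        nSim = "integer", seed = "integer"))

setValidity("SignedRankResult", function(object) {
    msg <- character()
    n <- object@nPairs
    if (abs(object@observedW) > n * (n + 1) / 2 + 1e-8)
        msg <- c(msg, "|observedW| exceeds n(n+1)/2")
    if (length(object@simulatedW) != object@nSim)
        msg <- c(msg, "simulatedW length must equal nSim")
    if (object@pUpper + object@pLower < 1 - 1e-12)
        msg <- c(msg, "pUpper + pLower must be >= 1 (ties count on both sides)")
    if (object@p5 > object@p95)
        msg <- c(msg, "p5 must not exceed p95")
    if (length(msg)) msg else TRUE
})

#' QuadraticFit: OLS quadratic of CV on mean abundance
#'
#' @slot coefficients named numeric `(b0, b1, b2)` for
#'   `cv = b0 + b1 * mean + b2 * mean^2`.
#' @slot r2 coefficient of determination in `[0, 1]`.
#' @slot nPoints number of transcripts fitted.
#' @exportClass QuadraticFit
setClass("QuadraticFit",
         representation(coefficients = "numeric", r2 = "numeric",
                        nPoints = "integer"))

setValidity("QuadraticFit", function(object) {
    msg <- character()
    if (length(object@coefficients) != 3)
        msg <- c(msg, "coefficients must be length 3")
    if (object@r2 < 0 || object@r2 > 1)
        msg <- c(msg, "r2 must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' DispersalTable: species with chromosome system and dispersal bias
#'
#' Each record names a species, its broad taxon, its chromosome system
#' (XY, XO, ZW or ZO) and which sex disperses most.  Two columns are derived
#' deterministically from the chromosome system: the heterogametic sex
#' (XY/XO -> male, ZW/ZO -> female) and whether the species carries a
#' sex-specific W or Y chromosome (XY/ZW -> TRUE, XO/ZO -> FALSE).
#'
#' @slot records data.frame with columns `species`, `taxon`,
#'   `chromosome_system`, `dispersing_sex`, `heterogametic_sex`, `has_WY`.
#' @slot dropped number of input records excluded at load (unknown or
#'   unbiased dispersal).
#' @exportClass DispersalTable
setClass("DispersalTable",
         representation(records = "data.frame", dropped = "integer"))

setValidity("DispersalTable", function(object) {
    df <- object@records
    msg <- character()
    need <- c("species", "taxon", "chromosome_system", "dispersing_sex",
              "heterogametic_sex", "has_WY")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        return(paste0("records lacks column(s): ",
                      paste(miss, collapse = ", ")))
    if (!all(df$chromosome_system %in% c("XY", "XO", "ZW", "ZO")))
        msg <- c(msg, "chromosome_system must be XY, XO, ZW or ZO")
    if (!all(df$dispersing_sex %in% c("female", "male")))
        msg <- c(msg, "dispersing_sex must be 'female' or 'male'")
    het <- heterogameticSexOf(df$chromosome_system)
    if (!identical(het, df$heterogametic_sex))
        msg <- c(msg, "heterogametic_sex inconsistent with chromosome_system")
    if (!identical(df$chromosome_system %in% c("XY", "ZW"), df$has_WY))
        msg <- c(msg, "has_WY inconsistent with chromosome_system")
    if (length(msg)) msg else TRUE
})

#' Heterogametic sex implied by a chromosome system
#'
#' @param system character vector of `"XY"`, `"XO"`, `"ZW"`, `"ZO"`.
#' @return `"male"` for XY/XO, `"female"` for ZW/ZO.
#' @export
heterogameticSexOf <- function(system) {
    out <- ifelse(system %in% c("XY", "XO"), "male",
           ifelse(system %in% c("ZW", "ZO"), "female", NA_character_))
    if (anyNA(out)) stop("unknown chromosome system tag")
    out
}

#' Construct a DispersalTable
#'
#' Records with `dispersing_sex` outside `female`/`male` (unknown or
#' unbiased dispersal) are excluded with a message; their count is kept in
#' the `dropped` slot.
#'
#' @param species,taxon,chromosome_system,dispersing_sex character vectors of
#'   equal length.
#' @return A [DispersalTable-class] object.
#' @export
DispersalTable <- function(species, taxon, chromosome_system, dispersing_sex) {
    df <- data.frame(species = as.character(species),
                     taxon = as.character(taxon),
                     chromosome_system = as.character(chromosome_system),
                     dispersing_sex = as.character(dispersing_sex),
                     stringsAsFactors = FALSE)
    keep <- df$dispersing_sex %in% c("female", "male")
    dropped <- sum(!keep)
    if (dropped)
        message(dropped, " record(s) without a biased dispersing sex excluded")
    df <- df[keep, , drop = FALSE]
    df$heterogametic_sex <- heterogameticSexOf(df$chromosome_system)
    df$has_WY <- df$chromosome_system %in% c("XY", "ZW")
    rownames(df) <- NULL
    new("DispersalTable", records = df, dropped = as.integer(dropped))
}

#' DispersalTestResult: observed heterogamety-biased fraction and its null
#'
#' @slot subset one of `"all"`, `"with_WY"`, `"without_WY"`.
#' @slot n subset size.
#' @slot observedFraction fraction of species whose heterogametic sex
#'   disperses most.
#' @slot simulatedFractions fractions recomputed after each tag permutation.
#' @slot p5,p95 percentiles of the simulated fractions.
#' @slot pUpper,pLower permutation p-values.
#' @slot nSim,seed Monte Carlo settings.
#' @exportClass DispersalTestResult
setClass("DispersalTestResult",
         representation(subset = "character", n = "integer",
                        observedFraction = "numeric",
                        simulatedFractions = "numeric",
                        p5 = "numeric", p95 = "numeric",
                        pUpper = "numeric", pLower = "numeric",
                        nSim = "integer", seed = "integer"))

setValidity("DispersalTestResult", function(object) {
    msg <- character()
    if (object@observedFraction < 0 || object@observedFraction > 1)
        msg <- c(msg, "observedFraction must lie in [0, 1]")
    if (length(object@simulatedFractions) != object@nSim)
        msg <- c(msg, "simulatedFractions length must equal nSim")
    if (length(msg)) msg else TRUE
})
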