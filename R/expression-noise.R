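#' Coefficient of variation of a replicate vector
#'
#' The package's noise measure: sample standard deviation (n-1 denominator)
#' divided by the mean.  Scale-invariant: `computeCV(c * x) == computeCV(x)`
#' for any `c > 0`.
#'
#' @param values numeric vector of at least two finite values with positive
#'   mean.
#' @return The CV (dimensionless).
#' @examples
#' computeCV(c(1, 3))   # sd = sqrt(2), mean = 2
#' @export
computeCV <- function(values) {
    if (length(values) < 2L)
        stop("insufficient replication: CV needs >= 2 values")
    if (!all(is.finite(values)))
        stop("CV input must be finite")
    m <- mean(values)
    if (m <= 0)
        stop("degenerate mean: CV needs a positive mean")
    stats::sd(values) / m
}

#' Pool strains sharing a genotype
#'
#' Relabels samples by genotype so that replicates of same-genotype strains
#' form one larger replicate group per sex (e.g. two strains of three
#' replicates per sex pool to six), increasing the power of the paired-CV
#' test.  Abundance values are untouched; replicate indices are renumbered
#' within each genotype/sex cell.
#'
#' @param ds an [ExpressionDataset-class].
#' @param genotypeMap named character, strain -> genotype label; every
#'   strain in `ds` must be mapped.
#' @return An [ExpressionDataset-class] whose `genotype` column carries the
#'   new labels.
#' @export
poolByGenotype <- function(ds, genotypeMap) {
    stopifnot(is(ds, "ExpressionDataset"))
    cd <- SummarizedExperiment::colData(ds)
    unmapped <- setdiff(unique(cd$strain), names(genotypeMap))
    if (length(unmapped))
        stop("strain(s) missing from genotypeMap: ",
             paste(unmapped, collapse = ", "))
    geno <- unname(genotypeMap[cd$strain])
    rep2 <- stats::ave(seq_along(geno), geno, cd$sex, FUN = seq_along)
    out <- ds
    SummarizedExperiment::colData(out)$genotype <- geno
    SummarizedExperiment::colData(out)$replicate <- as.integer(rep2)
    out
}

#' Paired female/male CVs per transcript
#'
#' For one strain or pooled genotype, computes each transcript's CV over the
#' female replicates and over the male replicates.  Transcripts whose mean
#' is non-positive in either sex (possible after microarray normalization)
#' are excluded; the count is reported with a message and kept in the
#' result's `dropped` slot.
#'
#' @param ds an [ExpressionDataset-class].
#' @param group strain or genotype label selecting the samples.
#' @param by `"strain"` or `"genotype"`: which annotation `group` refers to.
#' @return A [PairedCV-class] with one row per retained transcript.
#' @export
pairedCVExpression <- function(ds, group, by = c("strain", "genotype")) {
    stopifnot(is(ds, "ExpressionDataset"))
    by <- match.arg(by)
    cd <- SummarizedExperiment::colData(ds)
    sel <- cd[[by]] == group
    if (!any(sel)) stop("no samples with ", by, " = '", group, "'")
    sex <- cd$sex[sel]
    if (!all(c("female", "male") %in% sex))
        stop("group '", group, "' lacks one sex")
    if (sum(sex == "female") < 2L || sum(sex == "male") < 2L)
        stop("insufficient replication: need >= 2 replicates per sex")
    m <- SummarizedExperiment::assay(ds, "abundance")[, sel, drop = FALSE]
    fm <- m[, sex == "female", drop = FALSE]
    mm <- m[, sex == "male", drop = FALSE]
    muF <- rowMeans(fm)
    muM <- rowMeans(mm)
    keep <- muF > 0 & muM > 0
    if (any(!keep))
        message(sum(!keep), " transcript(s) with non-positive mean excluded")
    sdF <- apply(fm[keep, , drop = FALSE], 1L, stats::sd)
    sdM <- apply(mm[keep, , drop = FALSE], 1L, stats::sd)
    PairedCV(rownames(m)[keep], sdF / muF[keep], sdM / muM[keep],
             dropped = sum(!keep))
}

#' Paired female/male CVs from a grouped trait assay
#'
#' Implements the three pairing procedures for strain-panel stress assays:
#' \describe{
#'   \item{`per_individual_by_day`}{analysis unit = (strain, day); CV over
#'     individual measurements of that strain, sex and day.  Days are kept
#'     separate because conditions may drift between assay dates.}
#'   \item{`vial_means` / `group_means`}{analysis unit = strain; individual
#'     measurements are first averaged within each same-sex group (vial or
#'     set of single-individual vials), then the CV is taken over the group
#'     means.}
#' }
#' Units lacking either sex, or with fewer than two replicates (individuals
#' or groups) in either sex, are dropped; the count is reported with a
#' message and kept in the result's `dropped` slot.
#'
#' @param ds long-format trait data.frame with columns `strain`, `sex`,
#'   `group`, `value` (see [simulateTraits()]).
#' @param design one of `"per_individual_by_day"`, `"vial_means"`,
#'   `"group_means"`; defaults to the table's `"design"` attribute.
#' @return A [PairedCV-class], one row per retained analysis unit.
#' @export
pairedCVTraits <- function(ds, design = attr(ds, "design")) {
    stopifnot(is.data.frame(ds))
    if (is.null(design) || !design %in% .traitDesigns)
        stop("unknown trait design: ", if (is.null(design)) "<missing>"
             else design)
    if (!all(is.finite(ds$value))) stop("trait measurements must be finite")
    sexRepl <- function(sub, sx) {
        v <- sub$value[sub$sex == sx]
        g <- sub$group[sub$sex == sx]
        if (design == "per_individual_by_day") v
        else as.numeric(tapply(v, g, mean))
    }
    if (design == "per_individual_by_day") {
        units <- unique(ds[, c("strain", "group")])
        ids <- paste(units$strain, units$group, sep = ":")
        subs <- lapply(seq_len(nrow(units)), function(i)
            ds[ds$strain == units$strain[i] & ds$group == units$group[i], ])
    } else {
        ids <- unique(ds$strain)
        subs <- lapply(ids, function(st) ds[ds$strain == st, ])
    }
    cvF <- cvM <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
        f <- sexRepl(subs[[i]], "female")
        m <- sexRepl(subs[[i]], "male")
        if (length(f) >= 2L && length(m) >= 2L &&
            mean(f) > 0 && mean(m) > 0) {
            cvF[i] <- stats::sd(f) / mean(f)
            cvM[i] <- stats::sd(m) / mean(m)
        }
    }
    keep <- !is.na(cvF)
    if (any(!keep))
        message(sum(!keep),
                " unit(s) failing the replication filter dropped")
    PairedCV(ids[keep], cvF[keep], cvM[keep], dropped = sum(!keep))
}
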