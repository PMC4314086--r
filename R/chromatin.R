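#' Five-state chromatin colors
#'
#' The five chromatin components of the somatic fly genome used for
#' stratification: YELLOW (broadly expressed), BLACK and RED (repressive /
#' nuclear-periphery associated), BLUE and GREEN (classic heterochromatin).
#'
#' @export
chromatinColors <- function() c("YELLOW", "BLACK", "BLUE", "RED", "GREEN")

#' Read chromatin color tracts from BED
#'
#' Expects BED4 with the name column holding the color word
#' (case-insensitive).  Tracts on one chromosome must not overlap.
#'
#' @param file path to a BED file.
#' @return A [GenomicRanges::GRanges] with metadata column `color`.
#' @export
readColorTracts <- function(file) {
    gr <- rtracklayer::import(file, format = "BED")
    color <- toupper(as.character(gr$name))
    bad <- setdiff(unique(color), chromatinColors())
    if (length(bad))
        stop("unknown chromatin color(s) in ", file, ": ",
             paste(bad, collapse = ", "))
    gr$color <- color
    gr$name <- NULL
    cov <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
    if (sum(GenomicRanges::width(cov)) != sum(GenomicRanges::width(gr)))
        stop("color tracts overlap within a chromosome")
    gr
}

#' Read gene spans from BED or GFF3
#'
#' BED is read natively; for GFF3 only `gene`-typed features are kept and
#' the coordinate convention is converted on read.  Gene ids come from the
#' BED name column or the GFF3 `ID` attribute and must be unique.
#'
#' @param file path to a BED or GFF3 file (by extension: `.gff`, `.gff3`
#'   are GFF3, everything else BED).
#' @return A named [GenomicRanges::GRanges], one range per gene.
#' @export
readGeneSpans <- function(file) {
    isGFF <- grepl("\\.gff3?$", file, ignore.case = TRUE)
    if (isGFF) {
        gr <- rtracklayer::import(file, format = "GFF3")
        gr <- gr[gr$type == "gene"]
        ids <- as.character(gr$ID)
    } else {
        gr <- rtracklayer::import(file, format = "BED")
        ids <- as.character(gr$name)
    }
    if (anyNA(ids) || anyDuplicated(ids))
        stop("gene ids must be present and unique in ", file)
    names(gr) <- ids
    S4Vectors::mcols(gr) <- NULL
    gr
}

#' Assign each gene a chromatin color by full containment
#'
#' A gene gets color `c` if, and only if, exactly one tract contains its
#' entire span (boundary equality allowed) and that tract has color `c`.
#' Genes overlapping a tract boundary, contained in no tract, or contained
#' in more than one tract (possible only with overlapping inputs) are
#' `UNASSIGNED`.  Adjacent same-color tracts are not merged unless
#' `mergeSameColor = TRUE`, so a gene crossing the junction of two
#' same-color tracts stays unassigned by default.
#'
#' @param genes named [GenomicRanges::GRanges] of gene spans.
#' @param tracts [GenomicRanges::GRanges] with a `color` metadata column
#'   (see [readColorTracts()]).
#' @param mergeSameColor merge contiguous same-color tracts before testing
#'   containment.
#' @return Named character vector, gene id -> color or `"UNASSIGNED"`.
#' @export
assignColors <- function(genes, tracts, mergeSameColor = FALSE) {
    stopifnot(is(genes, "GRanges"), is(tracts, "GRanges"),
              !is.null(tracts$color), !is.null(names(genes)))
    if (mergeSameColor) {
        parts <- lapply(split(tracts, tracts$color), function(g) {
            r <- GenomicRanges::reduce(g)
            r$color <- rep(g$color[1], length(r))
            r
        })
        tracts <- unlist(GenomicRanges::GRangesList(parts),
                         use.names = FALSE)
    }
    hits <- GenomicRanges::findOverlaps(genes, tracts, type = "within",
                                        ignore.strand = TRUE)
    nHits <- tabulate(S4Vectors::queryHits(hits), nbins = length(genes))
    out <- rep("UNASSIGNED", length(genes))
    one <- which(nHits == 1L)
    first <- S4Vectors::subjectHits(hits)[match(one,
                                                S4Vectors::queryHits(hits))]
    out[one] <- tracts$color[first]
    stats::setNames(out, names(genes))
}

#' Attach chromatin colors to a PairedCV table
#'
#' @param pairs a [PairedCV-class] keyed by gene/transcript id.
#' @param assignment named color vector from [assignColors()]; units absent
#'   from it become `UNASSIGNED`.
#' @return A [PairedCV-class] with the `color` column filled.
#' @export
addColors <- function(pairs, assignment) {
    stopifnot(is(pairs, "PairedCV"))
    color <- unname(assignment[pairs@unitId])
    color[is.na(color)] <- "UNASSIGNED"
    PairedCV(pairs@unitId, pairs@cvF, pairs@cvM, color, pairs@dropped)
}

#' Chromatin-color stratified Monte Carlo-Wilcoxon test
#'
#' Computes one signed-rank test per chromatin color, with ranks assigned
#' within each color's pairs only.  The null is built from global
#' rearrangements: each of the `nSim` replicates draws one permutation of
#' all CV values pooled across every colored pair, refills the pairs, and
#' recomputes every color's W from that shared rearrangement, mirroring a
#' null that rearranges all CVs of the strain at once.  `UNASSIGNED` pairs
#' never enter any stratum (nor the pool).
#'
#' @param pairs a [PairedCV-class] whose `color` column is set (see
#'   [addColors()]).
#' @param nSim number of rearrangements (default 10,000).
#' @param seed mandatory RNG seed.
#' @return Named list of [SignedRankResult-class], one per color present.
#' @export
stratifiedTest <- function(pairs, nSim = 10000L, seed) {
    stopifnot(is(pairs, "PairedCV"))
    if (missing(seed)) stop("'seed' is mandatory")
    nSim <- stopIfNotCount(nSim, "nSim")
    keep <- !is.na(pairs@color) & pairs@color != "UNASSIGNED"
    if (!any(keep)) stop("no colored pairs to stratify")
    sub <- pairs[which(keep)]
    colors <- intersect(chromatinColors(), unique(sub@color))
    extra <- setdiff(unique(sub@color), chromatinColors())
    colors <- c(colors, extra)        # tolerate non-standard stratum labels
    idx <- lapply(colors, function(cl) which(sub@color == cl))
    names(idx) <- colors
    n <- length(sub)
    pool <- c(sub@cvF, sub@cvM)
    obs <- vapply(idx, function(i) .wilcoxW(sub@cvF[i] - sub@cvM[i]),
                  numeric(1))
    sims <- withSeed(seed, {
        out <- matrix(NA_real_, nSim, length(colors),
                      dimnames = list(NULL, colors))
        for (s in seq_len(nSim)) {
            p <- pool[sample.int(2L * n)]
            d <- p[seq_len(n)] - p[n + seq_len(n)]
            out[s, ] <- vapply(idx, function(i) .wilcoxW(d[i]), numeric(1))
        }
        out
    })
    res <- lapply(colors, function(cl)
        summarizeSignedRank(obs[[cl]], sims[, cl], nPairs = length(idx[[cl]]),
                            label = cl, seed = seed))
    stats::setNames(res, colors)
}
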