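#' Read and write the package's TSV interchange formats
#'
#' An [ExpressionDataset-class] round-trips as two TSVs: the abundance
#' matrix (`transcript_id` plus one column per sample) and the sample
#' metadata (`sample_id`, `strain`, `genotype`, `sex`, `replicate`).  Trait
#' data travel as a long-format TSV (`strain`, `sex`, `group`, `value`),
#' dispersal tables as TSV with `species`, `taxon`, `chromosome_system`,
#' `dispersing_sex`, and [PairedCV-class] tables as `unit_id`, `cv_f`,
#' `cv_m`, `color`.
#'
#' @param ds,x object to write.
#' @param matrixFile,metadataFile,file paths.
#' @name tsv-io
NULL

#' @rdname tsv-io
#' @return `writeExpressionDataset` invisibly returns the two paths.
#' @export
writeExpressionDataset <- function(ds, matrixFile, metadataFile) {
    stopifnot(is(ds, "ExpressionDataset"))
    m <- SummarizedExperiment::assay(ds, "abundance")
    out <- data.frame(transcript_id = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, matrixFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(ds))
    meta <- data.frame(sample_id = rownames(cd),
                       cd[, c("strain", "genotype", "sex", "replicate")],
                       stringsAsFactors = FALSE)
    utils::write.table(meta, metadataFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(matrixFile, metadataFile))
}

#' @rdname tsv-io
#' @return `readExpressionDataset` returns an [ExpressionDataset-class].
#'   Samples present in only one of the two files raise an error naming
#'   the offenders.
#' @export
readExpressionDataset <- function(matrixFile, metadataFile) {
    m <- utils::read.delim(matrixFile, check.names = FALSE,
                           stringsAsFactors = FALSE)
    meta <- utils::read.delim(metadataFile, stringsAsFactors = FALSE)
    vals <- as.matrix(m[, -1, drop = FALSE])
    rownames(vals) <- m$transcript_id
    extraM <- setdiff(colnames(vals), meta$sample_id)
    extraS <- setdiff(meta$sample_id, colnames(vals))
    if (length(extraM) || length(extraS))
        stop("matrix/metadata sample mismatch; only in matrix: [",
             paste(extraM, collapse = ", "), "]; only in metadata: [",
             paste(extraS, collapse = ", "), "]")
    meta <- meta[match(colnames(vals), meta$sample_id), ]
    ExpressionDataset(vals, strain = meta$strain, genotype = meta$genotype,
                      sex = meta$sex, replicate = meta$replicate)
}

#' @rdname tsv-io
#' @param design design tag stored alongside a trait table.
#' @export
writeTraitDataset <- function(ds, file, design = attr(ds, "design")) {
    stopifnot(is.data.frame(ds))
    utils::write.table(ds[, c("strain", "sex", "group", "value")], file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname tsv-io
#' @export
readTraitDataset <- function(file, design) {
    out <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("strain", "sex", "group", "value")
    miss <- setdiff(need, colnames(out))
    if (length(miss))
        stop("trait table lacks column(s): ", paste(miss, collapse = ", "))
    if (!missing(design)) attr(out, "design") <- design
    out
}

#' @rdname tsv-io
#' @export
writeDispersalTable <- function(x, file) {
    stopifnot(is(x, "DispersalTable"))
    utils::write.table(
        x@records[, c("species", "taxon", "chromosome_system",
                      "dispersing_sex")],
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname tsv-io
#' @export
readDispersalTable <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("species", "taxon", "chromosome_system", "dispersing_sex")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("dispersal table lacks column(s): ",
             paste(miss, collapse = ", "))
    DispersalTable(df$species, df$taxon, df$chromosome_system,
                   df$dispersing_sex)
}

#' @rdname tsv-io
#' @export
writePairedCV <- function(x, file) {
    stopifnot(is(x, "PairedCV"))
    utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(file)
}

#' @rdname tsv-io
#' @export
readPairedCV <- function(file) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE, na.strings = "")
    PairedCV(df$unit_id, df$cv_f, df$cv_m,
             if ("color" %in% colnames(df)) df$color else NA_character_)
}
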