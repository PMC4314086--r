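#' End-to-end pipeline runs
#'
#' File-in/file-out wrappers tying the stages into reproducible runs: each
#' reads the TSV/BED/GFF3 interchange formats, delegates to the module
#' functions, writes a result TSV mirroring the corresponding report table,
#' and writes a `*_manifest.tsv` recording the package version, every
#' parameter (seed and `nSim` always explicit) and the md5 checksum of each
#' input file.  A thin command-line wrapper over these functions ships in
#' `inst/scripts/noise-pipeline.R`.
#'
#' @name pipeline
NULL

writeManifest <- function(path, fields, inputs = character()) {
    for (f in inputs)
        fields[[paste0("md5_", basename(f))]] <- unname(tools::md5sum(f))
    fields$package_version <-
        as.character(utils::packageVersion("noiseDimorph"))
    df <- data.frame(key = names(fields),
                     value = vapply(fields, function(x)
                         paste(format(x, digits = 15), collapse = ","),
                         character(1)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

readManifest <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    stats::setNames(df$value, df$key)
}

#' @rdname pipeline
#' @param exprConfig,traitConfig,dispersalConfig optional configs; each
#'   non-NULL config has its dataset generated and written.
#' @param outDir output directory (created if needed).
#' @return `runSimulate` invisibly returns the written file paths.
#' @export
runSimulate <- function(exprConfig = NULL, traitConfig = NULL,
                        dispersalConfig = NULL, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    fields <- list()
    if (!is.null(exprConfig)) {
        ed <- simulateExpression(exprConfig)
        mf <- file.path(outDir, "expression_matrix.tsv")
        sf <- file.path(outDir, "expression_samples.tsv")
        writeExpressionDataset(ed, mf, sf)
        files <- c(files, mf, sf)
        fields$expr_seed <- exprConfig@seed
        fields$expr_n_transcripts <- exprConfig@nTranscripts
        fields$expr_n_strains <- exprConfig@nStrains
        fields$expr_replicates_per_sex <- exprConfig@replicatesPerSex
        fields$expr_noise_inflation_gamma <- exprConfig@noiseInflationGamma
    }
    if (!is.null(traitConfig)) {
        td <- simulateTraits(traitConfig)
        tf <- file.path(outDir, "traits.tsv")
        writeTraitDataset(td, tf)
        files <- c(files, tf)
        fields$trait_seed <- traitConfig@seed
        fields$trait_design <- traitConfig@traitDesign
        fields$trait_sex_cv_pair <- traitConfig@sexCVPair
    }
    if (!is.null(dispersalConfig)) {
        dt <- simulateDispersal(dispersalConfig)
        df <- file.path(outDir, "dispersal.tsv")
        writeDispersalTable(dt, df)
        files <- c(files, df)
        fields$dispersal_seed <- dispersalConfig@seed
        fields$dispersal_p_het_biased <- dispersalConfig@pHetBiased
    }
    if (!length(files)) stop("no config given")
    writeManifest(file.path(outDir, "simulate_manifest.tsv"), fields, files)
    invisible(files)
}

#' @rdname pipeline
#' @param matrixFile,metadataFile expression TSV pair (see
#'   [writeExpressionDataset()]).
#' @param genotypeMap optional named strain -> genotype map; when given,
#'   genotypes pooling more than one strain are tested too, after the
#'   per-strain rows.
#' @param nSim,seed Monte Carlo settings; per-analysis seeds are derived as
#'   `seed + row index`.
#' @return `runNoiseTest` invisibly returns the result data.frame.
#' @export
runNoiseTest <- function(matrixFile, metadataFile, genotypeMap = NULL,
                         nSim = 10000L, seed, outDir) {
    if (missing(seed)) stop("'seed' is mandatory")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ds <- readExpressionDataset(matrixFile, metadataFile)
    if (!is.null(genotypeMap)) ds <- poolByGenotype(ds, genotypeMap)
    cd <- SummarizedExperiment::colData(ds)
    strains <- unique(cd$strain)
    pooled <- names(which(vapply(split(cd$strain, cd$genotype),
                                 function(s) length(unique(s)) > 1L,
                                 logical(1))))
    jobs <- rbind(data.frame(label = strains, by = "strain"),
                  if (length(pooled))
                      data.frame(label = pooled, by = "genotype"))
    results <- vector("list", nrow(jobs))
    nrep <- integer(nrow(jobs))
    for (i in seq_len(nrow(jobs))) {
        pcv <- pairedCVExpression(ds, jobs$label[i], by = jobs$by[i])
        results[[i]] <- signedRankTest(pcv, nSim = nSim, seed = seed + i,
                                       label = jobs$label[i])
        nrep[i] <- sum(cd[[jobs$by[i]]] == jobs$label[i] &
                       cd$sex == "female")
    }
    out <- renderSignedRankTable(results, nrep)
    utils::write.table(out, file.path(outDir, "noise_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(file.path(outDir, "noise_test_manifest.tsv"),
                  list(seed = seed, n_sim = nSim),
                  c(matrixFile, metadataFile))
    invisible(out)
}

#' @rdname pipeline
#' @param traitFile long-format trait TSV.
#' @param design trait design tag (see [pairedCVTraits()]).
#' @param label row label for the report table.
#' @return `runTraitTest` invisibly returns the result data.frame.
#' @export
runTraitTest <- function(traitFile, design, nSim = 10000L, seed, outDir,
                         label = design) {
    if (missing(seed)) stop("'seed' is mandatory")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    td <- readTraitDataset(traitFile, design = design)
    pcv <- pairedCVTraits(td, design)
    res <- signedRankTest(pcv, nSim = nSim, seed = seed, label = label)
    counts <- table(td$strain, td$sex)
    out <- renderSignedRankTable(list(res),
                                 paste0(min(counts), "-", max(counts)))
    utils::write.table(out, file.path(outDir, "trait_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(file.path(outDir, "trait_test_manifest.tsv"),
                  list(seed = seed, n_sim = nSim, design = design),
                  traitFile)
    invisible(out)
}

#' @rdname pipeline
#' @return `runMeanCV` invisibly returns the result data.frame with one row
#'   per strain (and pooled genotype): the two coefficients of
#'   determination and their female/male ratio.
#' @export
runMeanCV <- function(matrixFile, metadataFile, genotypeMap = NULL,
                      outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ds <- readExpressionDataset(matrixFile, metadataFile)
    if (!is.null(genotypeMap)) ds <- poolByGenotype(ds, genotypeMap)
    cd <- SummarizedExperiment::colData(ds)
    strains <- unique(cd$strain)
    pooled <- names(which(vapply(split(cd$strain, cd$genotype),
                                 function(s) length(unique(s)) > 1L,
                                 logical(1))))
    jobs <- rbind(data.frame(label = strains, by = "strain"),
                  if (length(pooled))
                      data.frame(label = pooled, by = "genotype"))
    out <- do.call(rbind, lapply(seq_len(nrow(jobs)), function(i) {
        r <- r2SexRatio(ds, jobs$label[i], by = jobs$by[i])
        data.frame(label = jobs$label[i], r2_female = r$r2Female,
                   r2_male = r$r2Male, ratio = r$ratio,
                   stringsAsFactors = FALSE)
    }))
    utils::write.table(out, file.path(outDir, "mean_cv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(file.path(outDir, "mean_cv_manifest.tsv"), list(),
                  c(matrixFile, metadataFile))
    invisible(out)
}

#' @rdname pipeline
#' @param tractsFile BED4 of color tracts; `genesFile` BED6/GFF3 of gene
#'   spans keyed by transcript id.
#' @param genesFile see `tractsFile`.
#' @param group,by strain or genotype analysed (as in
#'   [pairedCVExpression()]).
#' @return `runStratify` invisibly returns the per-color result data.frame.
#' @export
runStratify <- function(matrixFile, metadataFile, tractsFile, genesFile,
                        group, by = "strain", genotypeMap = NULL,
                        nSim = 10000L, seed, outDir) {
    if (missing(seed)) stop("'seed' is mandatory")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ds <- readExpressionDataset(matrixFile, metadataFile)
    if (!is.null(genotypeMap)) ds <- poolByGenotype(ds, genotypeMap)
    pcv <- pairedCVExpression(ds, group, by = by)
    asn <- assignColors(readGeneSpans(genesFile),
                        readColorTracts(tractsFile))
    pcv <- addColors(pcv, asn)
    res <- stratifiedTest(pcv, nSim = nSim, seed = seed)
    out <- renderSignedRankTable(res,
        sum(SummarizedExperiment::colData(ds)[[by]] == group &
            SummarizedExperiment::colData(ds)$sex == "female"))
    out <- cbind(strain = group, out)
    utils::write.table(out, file.path(outDir, "stratified_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(file.path(outDir, "stratified_test_manifest.tsv"),
                  list(seed = seed, n_sim = nSim, group = group, by = by),
                  c(matrixFile, metadataFile, tractsFile, genesFile))
    invisible(out)
}

#' @rdname pipeline
#' @param dispersalFile species dispersal TSV; `NULL` uses the packaged
#'   36-species table.
#' @return `runDispersal` invisibly returns the three-subset result
#'   data.frame.
#' @export
runDispersal <- function(dispersalFile = NULL, nSim = 10000L, seed,
                         outDir) {
    if (missing(seed)) stop("'seed' is mandatory")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    tab <- if (is.null(dispersalFile)) loadDispersalFixture()
           else readDispersalTable(dispersalFile)
    res <- lapply(seq_along(.dispersalSubsets), function(i)
        tagPermutationTest(tab, .dispersalSubsets[i], nSim = nSim,
                           seed = seed + i))
    out <- renderDispersalTable(res)
    utils::write.table(out, file.path(outDir, "dispersal_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(file.path(outDir, "dispersal_test_manifest.tsv"),
                  list(seed = seed, n_sim = nSim),
                  if (is.null(dispersalFile)) character()
                  else dispersalFile)
    invisible(out)
}
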