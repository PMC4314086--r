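#' Configuration for the synthetic expression generator
#'
#' Describes a replicated two-sex expression experiment in the style of a
#' strain panel assayed with three biological replicates per strain and sex.
#' Per-transcript mean abundances are drawn log-normally; per-transcript
#' female CVs are drawn from a gamma distribution; male CVs are the female
#' CVs inflated by the factor `noiseInflationGamma` (gamma = 1 means no
#' dimorphism).  Replicate values are the transcript mean times `1 + eps`
#' with `eps ~ N(0, cv^2)`, redrawn while non-positive so abundances stay
#' strictly positive.
#'
#' @slot nTranscripts,nStrains,replicatesPerSex experiment dimensions;
#'   `replicatesPerSex >= 2` because a CV needs at least two values.
#' @slot genotypeMap named character, strain -> genotype label.
#' @slot meanLogLocation,meanLogScale log-normal parameters of transcript
#'   mean abundance (arbitrary expression units).
#' @slot baseCVShape,baseCVScale gamma parameters of the female CV draw.
#' @slot noiseInflationGamma multiplicative male-CV factor, > 0.
#' @slot cvFemaleFun,cvMaleFun optional functions mapping transcript mean to
#'   CV, overriding the gamma draw (and gamma inflation, respectively); used
#'   to impose a mean--noise coupling.
#' @slot seed mandatory RNG seed.
#' @exportClass SimExprConfig
setClass("SimExprConfig",
         representation(nTranscripts = "integer", nStrains = "integer",
                        genotypeMap = "character",
                        replicatesPerSex = "integer",
                        meanLogLocation = "numeric", meanLogScale = "numeric",
                        baseCVShape = "numeric", baseCVScale = "numeric",
                        noiseInflationGamma = "numeric",
                        cvFemaleFun = "ANY", cvMaleFun = "ANY",
                        seed = "integer"))

setValidity("SimExprConfig", function(object) {
    msg <- character()
    if (object@replicatesPerSex < 2L)
        msg <- c(msg, "replicatesPerSex must be >= 2 (a CV needs >= 2 values)")
    if (!is.finite(object@noiseInflationGamma) ||
        object@noiseInflationGamma <= 0)
        msg <- c(msg, "noiseInflationGamma must be > 0")
    if (object@meanLogScale <= 0 || object@baseCVShape <= 0 ||
        object@baseCVScale <= 0)
        msg <- c(msg, "scale/shape parameters must be > 0")
    if (length(msg)) msg else TRUE
})

setMethod("$", "SimExprConfig", function(x, name) slot(x, name))

#' @rdname SimExprConfig-class
#' @param nTranscripts,nStrains,replicatesPerSex,genotypeMap,meanLogLocation,meanLogScale,baseCVShape,baseCVScale,noiseInflationGamma,cvFemaleFun,cvMaleFun,seed see slots.
#' @return A validated `SimExprConfig`.
#' @examples
#' cfg <- SimExprConfig(nTranscripts = 100, seed = 1)
#' ed <- simulateExpression(cfg)
#' @export
SimExprConfig <- function(nTranscripts = 1000L, nStrains = 6L,
                          genotypeMap = NULL, replicatesPerSex = 3L,
                          meanLogLocation = log(100), meanLogScale = 1,
                          baseCVShape = 4, baseCVScale = 0.05,
                          noiseInflationGamma = 1.5,
                          cvFemaleFun = NULL, cvMaleFun = NULL,
                          seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    stopIfNotCount(nTranscripts, "nTranscripts")
    stopIfNotCount(nStrains, "nStrains")
    if (!is.numeric(replicatesPerSex) || replicatesPerSex < 2L)
        stop("invalid config: replicatesPerSex must be >= 2")
    if (!is.numeric(noiseInflationGamma) || noiseInflationGamma <= 0)
        stop("invalid config: noiseInflationGamma must be > 0")
    strains <- sprintf("strain%02d", seq_len(nStrains))
    if (is.null(genotypeMap)) {
        genotypeMap <- stats::setNames(strains, strains)
    } else if (is.null(names(genotypeMap))) {
        stop("genotypeMap must be a named character vector (strain -> genotype)")
    }
    new("SimExprConfig", nTranscripts = as.integer(nTranscripts),
        nStrains = as.integer(nStrains), genotypeMap = genotypeMap,
        replicatesPerSex = as.integer(replicatesPerSex),
        meanLogLocation = meanLogLocation, meanLogScale = meanLogScale,
        baseCVShape = baseCVShape, baseCVScale = baseCVScale,
        noiseInflationGamma = noiseInflationGamma,
        cvFemaleFun = cvFemaleFun, cvMaleFun = cvMaleFun,
        seed = as.integer(seed))
}

#' Simulate a replicated two-sex expression dataset
#'
#' @param config a [SimExprConfig-class].
#' @return An [ExpressionDataset-class] of strictly positive abundances with
#'   per-sample `strain`, `genotype`, `sex` and `replicate` annotation.  The
#'   true per-transcript means and sex CVs are attached as rowData columns
#'   `true_mean`, `true_cv_f`, `true_cv_m` for parameter-recovery checks.
#' @details Identical configs (including the seed) give bit-identical
#'   datasets.  The same transcript mean and sex CVs apply to every strain,
#'   so the only systematic female/male difference is the CV inflation.
#' @export
simulateExpression <- function(config) {
    stopifnot(is(config, "SimExprConfig"))
    validObject(config)
    withSeed(config@seed, {
        nt <- config@nTranscripts
        strains <- names(config@genotypeMap)[seq_len(config@nStrains)]
        reps <- config@replicatesPerSex
        mu <- stats::rlnorm(nt, config@meanLogLocation, config@meanLogScale)
        cvF <- if (is.null(config@cvFemaleFun))
            stats::rgamma(nt, shape = config@baseCVShape,
                          scale = config@baseCVScale)
        else config@cvFemaleFun(mu)
        cvM <- if (is.null(config@cvMaleFun))
            config@noiseInflationGamma * cvF
        else config@cvMaleFun(mu)
        if (any(cvF < 0) || any(cvM < 0))
            stop("CV functions must return non-negative values")
        sex <- rep(rep(c("female", "male"), each = reps),
                   times = length(strains))
        strain <- rep(strains, each = 2L * reps)
        replicate <- rep(seq_len(reps), times = 2L * length(strains))
        ns <- length(sex)
        sdMat <- outer(mu, ifelse(sex == "female", 1, 0)) * cvF +
                 outer(mu, ifelse(sex == "male", 1, 0)) * cvM
        vals <- matrix(stats::rnorm(nt * ns, mean = rep(mu, times = ns),
                                    sd = sdMat), nt, ns)
        bad <- which(vals <= 0)
        while (length(bad)) {       # truncate at zero by redrawing
            vals[bad] <- stats::rnorm(length(bad),
                                      mean = rep(mu, times = ns)[bad],
                                      sd = sdMat[bad])
            bad <- bad[vals[bad] <= 0]
        }
        dimnames(vals) <- list(sprintf("t%05d", seq_len(nt)),
                               paste(strain, sex, replicate, sep = "_"))
        ed <- ExpressionDataset(vals, strain = strain, sex = sex,
                                replicate = replicate,
                                genotype = unname(config@genotypeMap[strain]))
        SummarizedExperiment::rowData(ed)$true_mean <- mu
        SummarizedExperiment::rowData(ed)$true_cv_f <- cvF
        SummarizedExperiment::rowData(ed)$true_cv_m <- cvM
        ed
    })
}

#' Configuration for the synthetic trait-assay generator
#'
#' Mirrors the three replication structures of strain-panel stress assays:
#' `per_individual_by_day` (individuals measured per strain, sex and assay
#' day, days analysed separately, as in startle response),
#' `vial_means` (several same-sex vials per strain, vial averages as
#' replicates, as in starvation resistance) and `group_means` (groups of
#' single-individual vials averaged per group, as in chill coma recovery).
#'
#' @slot traitDesign one of `"per_individual_by_day"`, `"vial_means"`,
#'   `"group_means"`.
#' @slot nStrains,groupsPerCell,individualsPerGroup positive counts; for
#'   `per_individual_by_day`, `groupsPerCell` is the number of assay days.
#' @slot sexCVPair named numeric `(female, male)` target CVs at the
#'   replicate level (dimensionless).
#' @slot withinGroupCV individual-level CV inside a vial/group for the two
#'   averaged designs.
#' @slot seed mandatory RNG seed.
#' @exportClass SimTraitConfig
setClass("SimTraitConfig",
         representation(traitDesign = "character", nStrains = "integer",
                        groupsPerCell = "integer",
                        individualsPerGroup = "integer",
                        sexCVPair = "numeric", withinGroupCV = "numeric",
                        seed = "integer"))

.traitDesigns <- c("per_individual_by_day", "vial_means", "group_means")

setValidity("SimTraitConfig", function(object) {
    msg <- character()
    if (!object@traitDesign %in% .traitDesigns)
        msg <- c(msg, paste("traitDesign must be one of:",
                            paste(.traitDesigns, collapse = ", ")))
    if (any(c(object@nStrains, object@groupsPerCell,
              object@individualsPerGroup) < 1L))
        msg <- c(msg, "counts must be positive")
    if (length(object@sexCVPair) != 2L || any(object@sexCVPair < 0))
        msg <- c(msg, "sexCVPair must be two non-negative CVs")
    if (length(msg)) msg else TRUE
})

#' @rdname SimTraitConfig-class
#' @param traitDesign,nStrains,groupsPerCell,individualsPerGroup,sexCVPair,withinGroupCV,seed see slots.
#' @return A validated `SimTraitConfig`.
#' @export
SimTraitConfig <- function(traitDesign = "per_individual_by_day",
                           nStrains = 20L, groupsPerCell = 2L,
                           individualsPerGroup = 10L,
                           sexCVPair = c(female = 0.2, male = 0.3),
                           withinGroupCV = 0.05, seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    if (!traitDesign %in% .traitDesigns)
        stop("unknown trait design: ", traitDesign)
    new("SimTraitConfig", traitDesign = traitDesign,
        nStrains = stopIfNotCount(nStrains, "nStrains"),
        groupsPerCell = stopIfNotCount(groupsPerCell, "groupsPerCell"),
        individualsPerGroup = stopIfNotCount(individualsPerGroup,
                                             "individualsPerGroup"),
        sexCVPair = stats::setNames(as.numeric(sexCVPair),
                                    c("female", "male")),
        withinGroupCV = withinGroupCV, seed = as.integer(seed))
}

#' Simulate a grouped trait assay
#'
#' @param config a [SimTraitConfig-class].
#' @return A long-format data.frame with columns `strain`, `sex`, `group`
#'   (vial or assay-day id) and `value` (trait units), carrying the design
#'   tag as attribute `"design"`.
#' @details For `per_individual_by_day` the target sex CV applies at the
#'   individual level within a strain/sex/day cell.  For the two averaged
#'   designs it applies at the group-mean level: group means are the
#'   strain/sex mean times `1 + eps` with `eps ~ N(0, cv^2)`, and individual
#'   measurements scatter around their group mean with `withinGroupCV`.
#'   All draws are truncated at zero by redrawing.
#' @export
simulateTraits <- function(config) {
    stopifnot(is(config, "SimTraitConfig"))
    validObject(config)
    withSeed(config@seed, {
        strains <- sprintf("strain%02d", seq_len(config@nStrains))
        strainMean <- stats::setNames(
            stats::rlnorm(length(strains), log(100), 0.3), strains)
        rows <- list()
        for (st in strains) for (sx in c("female", "male")) {
            cv <- config@sexCVPair[[sx]]
            for (g in seq_len(config@groupsPerCell)) {
                gid <- if (config@traitDesign == "per_individual_by_day")
                    sprintf("day%d", g) else sprintf("group%d", g)
                if (config@traitDesign == "per_individual_by_day") {
                    vals <- truncPosNorm(config@individualsPerGroup,
                                         strainMean[[st]],
                                         strainMean[[st]] * cv)
                } else {
                    gm <- truncPosNorm(1L, strainMean[[st]],
                                       strainMean[[st]] * cv)
                    vals <- truncPosNorm(config@individualsPerGroup, gm,
                                         gm * config@withinGroupCV)
                }
                rows[[length(rows) + 1L]] <-
                    data.frame(strain = st, sex = sx, group = gid,
                               value = vals, stringsAsFactors = FALSE)
            }
        }
        out <- do.call(rbind, rows)
        rownames(out) <- NULL
        attr(out, "design") <- config@traitDesign
        out
    })
}

truncPosNorm <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
}

#' Configuration for the synthetic dispersal-table generator
#'
#' @slot nSpecies number of species.
#' @slot pHetBiased probability in `[0, 1]` that a species' heterogametic
#'   sex is the one dispersing most.
#' @slot systemComposition named counts over `XY`, `XO`, `ZW`, `ZO` summing
#'   to `nSpecies`.
#' @slot seed mandatory RNG seed.
#' @exportClass SimDispersalConfig
setClass("SimDispersalConfig",
         representation(nSpecies = "integer", pHetBiased = "numeric",
                        systemComposition = "integer", seed = "integer"))

setValidity("SimDispersalConfig", function(object) {
    msg <- character()
    if (object@pHetBiased < 0 || object@pHetBiased > 1)
        msg <- c(msg, "pHetBiased must lie in [0, 1]")
    if (!setequal(names(object@systemComposition),
                  c("XY", "XO", "ZW", "ZO")))
        msg <- c(msg, "systemComposition needs names XY, XO, ZW, ZO")
    else if (sum(object@systemComposition) != object@nSpecies)
        msg <- c(msg, "systemComposition must sum to nSpecies")
    if (length(msg)) msg else TRUE
})

#' @rdname SimDispersalConfig-class
#' @param nSpecies,pHetBiased,systemComposition,seed see slots.
#' @return A validated `SimDispersalConfig`.
#' @export
SimDispersalConfig <- function(nSpecies = 36L, pHetBiased = 0.8,
                               systemComposition = c(XY = 17L, XO = 3L,
                                                     ZW = 14L, ZO = 2L),
                               seed) {
    if (missing(seed)) stop("'seed' is mandatory")
    nSpecies <- stopIfNotCount(nSpecies, "nSpecies")
    comp <- as.integer(systemComposition)
    names(comp) <- names(systemComposition)
    if (sum(comp) != nSpecies)
        stop("systemComposition must sum to nSpecies (got ",
             sum(comp), " vs ", nSpecies, ")")
    new("SimDispersalConfig", nSpecies = nSpecies,
        pHetBiased = pHetBiased, systemComposition = comp,
        seed = as.integer(seed))
}

#' Simulate a species dispersal table
#'
#' Each species receives a chromosome-system tag from the stated composition
#' and a dispersing-most sex that equals its heterogametic sex with
#' probability `pHetBiased`, and the opposite sex otherwise.
#'
#' @param config a [SimDispersalConfig-class].
#' @return A [DispersalTable-class].
#' @export
simulateDispersal <- function(config) {
    stopifnot(is(config, "SimDispersalConfig"))
    validObject(config)
    withSeed(config@seed, {
        tags <- sample(rep(names(config@systemComposition),
                           times = config@systemComposition))
        het <- heterogameticSexOf(tags)
        biased <- stats::runif(config@nSpecies) < config@pHetBiased
        disp <- ifelse(biased, het,
                       ifelse(het == "male", "female", "male"))
        DispersalTable(species = sprintf("species%03d",
                                         seq_len(config@nSpecies)),
                       taxon = "simulated", chromosome_system = tags,
                       dispersing_sex = disp)
    })
}

#' Load the packaged 36-species dispersal table
#'
#' Returns the packaged metazoan sex-biased dispersal table: 36 species (11
#' birds, 11 insects, 14 mammals) with known chromosome systems, of which 5
#' commonly or completely lack sex-specific W/Y chromosomes.  The file is a
#' synthetic reconstruction: the original species-level supplement is not
#' redistributed here, so a table was rebuilt to match every published
#' composition fact (taxon counts, chromosome-system mix, observed
#' heterogamety-biased dispersal fractions 0.81/0.90/0.20 and their
#' permutation-null percentiles); species names are plausible exemplars.
#'
#' @return A [DispersalTable-class] with 36 records.
#' @examples
#' tab <- loadDispersalFixture()
#' hetBiasedFraction(tab, "all")
#' @export
loadDispersalFixture <- function() {
    path <- system.file("extdata", "dispersal_metazoa_synthetic.tsv",
                        package = "noiseDimorph")
    if (!nzchar(path) || !file.exists(path))
        stop("packaged dispersal table not found")
    readDispersalTable(path)
}
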