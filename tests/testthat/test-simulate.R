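test_that("simulated expression is reproducible, positive and annotated", {
    cfg <- SimExprConfig(nTranscripts = 50, nStrains = 2, seed = 11)
    ed1 <- simulateExpression(cfg)
    ed2 <- simulateExpression(cfg)
    expect_identical(assay(ed1, "abundance"), assay(ed2, "abundance"))
    expect_true(all(assay(ed1, "abundance") > 0))
    cd <- colData(ed1)
    expect_setequal(unique(cd$sex), c("female", "male"))
    expect_equal(sum(cd$strain == "strain01" & cd$sex == "male"), 3)
    expect_equal(dim(ed1), c(50L, 2L * 2L * 3L))
    # a different seed moves the data
    ed3 <- simulateExpression(SimExprConfig(nTranscripts = 50,
                                            nStrains = 2, seed = 12))
    expect_false(identical(assay(ed1, "abundance"),
                           assay(ed3, "abundance")))
})

test_that("invalid generator configs are rejected at construction", {
    expect_error(SimExprConfig(replicatesPerSex = 1, seed = 1),
                 "replicatesPerSex")
    expect_error(SimExprConfig(noiseInflationGamma = 0, seed = 1),
                 "noiseInflationGamma")
    expect_error(SimExprConfig(noiseInflationGamma = -1, seed = 1),
                 "noiseInflationGamma")
    expect_error(SimExprConfig(nTranscripts = 10), "seed")
    expect_error(SimTraitConfig(traitDesign = "bogus", seed = 1),
                 "unknown trait design")
    expect_error(SimDispersalConfig(nSpecies = 10,
                                    systemComposition = c(XY = 4, XO = 1,
                                                          ZW = 3, ZO = 1),
                                    seed = 1),
                 "sum to nSpecies")
})

test_that("generator recovers its own noise parameters at deep replication", {
    gamma <- 2
    cfg <- SimExprConfig(nTranscripts = 300, nStrains = 1,
                         replicatesPerSex = 200,
                         noiseInflationGamma = gamma, seed = 21)
    ed <- simulateExpression(cfg)
    pcv <- pairedCVExpression(ed, "strain01")
    trueF <- rowData(ed)$true_cv_f
    # empirical female CV tracks the drawn CV per transcript
    expect_lt(median(abs(cvFemale(pcv) / trueF - 1)), 0.1)
    # male/female CV ratio recovers gamma
    expect_lt(abs(median(cvMale(pcv) / cvFemale(pcv)) - gamma),
              0.1 * gamma)
})

test_that("trait generator reproduces the three pairing structures", {
    cfg <- SimTraitConfig(traitDesign = "per_individual_by_day",
                          nStrains = 10, groupsPerCell = 2,
                          individualsPerGroup = 8, seed = 3)
    td <- simulateTraits(cfg)
    expect_identical(attr(td, "design"), "per_individual_by_day")
    pcv <- pairedCVTraits(td)
    expect_equal(length(pcv), 20)    # strains x days analysis units

    cfgV <- SimTraitConfig(traitDesign = "vial_means", nStrains = 4,
                           groupsPerCell = 3, individualsPerGroup = 5,
                           seed = 4)
    tdV <- simulateTraits(cfgV)
    expect_equal(length(pairedCVTraits(tdV)), 4)  # unit = strain

    # one vial per strain-sex cannot support a CV: every unit drops,
    # and the downstream statistic then refuses the empty table
    cfg1 <- SimTraitConfig(traitDesign = "vial_means", nStrains = 3,
                           groupsPerCell = 1, individualsPerGroup = 5,
                           seed = 5)
    expect_message(pcv1 <- pairedCVTraits(simulateTraits(cfg1)),
                   "replication filter")
    expect_equal(length(pcv1), 0)
    expect_equal(nDropped(pcv1), 3L)
    expect_error(wilcoxonW(pcv1), "empty")
})

test_that("dispersal generator honours composition and bias probability", {
    cfg <- SimDispersalConfig(nSpecies = 20, pHetBiased = 1,
                              systemComposition = c(XY = 5, XO = 5,
                                                    ZW = 5, ZO = 5),
                              seed = 6)
    tab <- simulateDispersal(cfg)
    expect_equal(hetBiasedFraction(tab, "all"), 1.0)
    expect_equal(sort(table(dispersalRecords(tab)$chromosome_system)),
                 sort(table(rep(c("XY", "XO", "ZW", "ZO"), 5))),
                 ignore_attr = TRUE)

    big <- simulateDispersal(SimDispersalConfig(
        nSpecies = 10000, pHetBiased = 0.5,
        systemComposition = c(XY = 2500, XO = 2500, ZW = 2500, ZO = 2500),
        seed = 7))
    expect_lt(abs(hetBiasedFraction(big, "all") - 0.5), 0.02)

    noWY <- simulateDispersal(SimDispersalConfig(
        nSpecies = 12, pHetBiased = 0.5,
        systemComposition = c(XY = 0, XO = 6, ZW = 0, ZO = 6), seed = 8))
    expect_false(any(dispersalRecords(noWY)$has_WY))
})

test_that("equal-sex-CV trait assays stay non-significant at the nominal rate", {
    nRuns <- 100
    rej <- vapply(seq_len(nRuns), function(i) {
        cfg <- SimTraitConfig(traitDesign = "per_individual_by_day",
                              nStrains = 15, groupsPerCell = 2,
                              individualsPerGroup = 10,
                              sexCVPair = c(female = 0.2, male = 0.2),
                              seed = 400 + i)
        pcv <- pairedCVTraits(simulateTraits(cfg))
        r <- signedRankTest(pcv, nSim = 400, seed = 900 + i)
        min(pUpper(r), pLower(r)) <= 0.025
    }, logical(1))
    se <- sqrt(0.05 * 0.95 / nRuns)
    expect_lt(abs(mean(rej) - 0.05), 3 * se + 0.01)
})
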