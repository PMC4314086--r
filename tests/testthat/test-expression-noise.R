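test_that("computeCV matches the n-1 definition and its edge cases", {
    expect_equal(computeCV(c(2, 2, 2)), 0)
    expect_equal(computeCV(c(1, 3)), sqrt(2) / 2, tolerance = 1e-6)
    expect_equal(round(computeCV(c(1, 3)), 5), 0.70711)
    expect_error(computeCV(5), "insufficient replication")
    expect_error(computeCV(c(-2, 1)), "degenerate mean")
    expect_error(computeCV(c(1, NA)), "finite")
})

test_that("computeCV is scale invariant", {
    set.seed(42)
    for (i in 1:25) {
        x <- rlnorm(sample(2:12, 1))
        c0 <- computeCV(x)
        for (k in c(0.01, 3, 1e4))
            expect_equal(computeCV(k * x), c0, tolerance = 1e-12)
    }
})

test_that("genotype pooling merges replicate groups without touching values", {
    cfg <- SimExprConfig(nTranscripts = 40, nStrains = 3, seed = 13)
    ed <- simulateExpression(cfg)
    map <- c(strain01 = "G1", strain02 = "G1", strain03 = "G2")
    pooled <- poolByGenotype(ed, map)
    expect_identical(assay(pooled, "abundance"), assay(ed, "abundance"))
    cd <- colData(pooled)
    expect_equal(sum(cd$genotype == "G1" & cd$sex == "female"), 6)
    expect_equal(sum(cd$genotype == "G2" & cd$sex == "male"), 3)
    # three strains pooled -> 9 replicates per sex
    map9 <- c(strain01 = "G", strain02 = "G", strain03 = "G")
    cd9 <- colData(poolByGenotype(ed, map9))
    expect_equal(sum(cd9$genotype == "G" & cd9$sex == "female"), 9)
    expect_error(poolByGenotype(ed, c(strain01 = "G1")), "strain02")
})

test_that("paired expression CVs commute with identity pooling", {
    cfg <- SimExprConfig(nTranscripts = 30, nStrains = 2, seed = 14)
    ed <- simulateExpression(cfg)
    idMap <- c(strain01 = "strain01", strain02 = "strain02")
    a <- pairedCVExpression(ed, "strain01", by = "strain")
    b <- pairedCVExpression(poolByGenotype(ed, idMap), "strain01",
                            by = "genotype")
    expect_equal(cvFemale(a), cvFemale(b))
    expect_equal(cvMale(a), cvMale(b))
})

test_that("paired expression CVs are symmetric, sized and sex-checked", {
    vals <- matrix(rlnorm(60, log(50)), 10, 6)
    vals[, 4:6] <- vals[, 1:3]    # male replicates copy female ones
    ed <- makeTinyDataset(vals, reps = 3)
    pcv <- pairedCVExpression(ed, "A")
    expect_equal(cvFemale(pcv), cvMale(pcv))
    expect_equal(length(pcv), 10)
    expect_identical(unitIds(pcv), rownames(ed))

    onlyF <- ExpressionDataset(matrix(rlnorm(9), 3, 3),
                               strain = rep("A", 3),
                               sex = rep("female", 3), replicate = 1:3)
    expect_error(pairedCVExpression(onlyF, "A"), "lacks one sex")
    expect_error(pairedCVExpression(ed, "nope"), "no samples")
})

test_that("CV ratio recovers the generator's inflation at 50 replicates", {
    # modest base CVs keep the male draw far from the positivity
    # truncation, so the realized inflation matches the nominal factor
    cfg <- SimExprConfig(nTranscripts = 400, nStrains = 1,
                         replicatesPerSex = 50, noiseInflationGamma = 3,
                         baseCVScale = 0.025, seed = 15)
    pcv <- pairedCVExpression(simulateExpression(cfg), "strain01")
    expect_lt(abs(median(cvMale(pcv) / cvFemale(pcv)) - 3), 0.3)
})

test_that("transcripts with non-positive means are filtered and counted", {
    vals <- matrix(rlnorm(36, log(100)), 6, 6)
    vals[2, 1:3] <- c(-5, -4, 2)   # negative female mean after normalization
    ed <- makeTinyDataset(vals, reps = 3)
    expect_message(pcv <- pairedCVExpression(ed, "A"), "non-positive mean")
    expect_equal(length(pcv), 5)
    expect_equal(nDropped(pcv), 1L)
    expect_false("t2" %in% unitIds(pcv))
})

test_that("trait pairing follows the per-design unit and filter rules", {
    # 2 strains x 2 days, 5 individuals per cell -> 4 paired units
    td <- expand.grid(strain = c("s1", "s2"), sex = c("female", "male"),
                      group = c("day1", "day2"), i = 1:5,
                      stringsAsFactors = FALSE)
    td$value <- rlnorm(nrow(td), log(20), 0.2)
    pcv <- pairedCVTraits(td[, c("strain", "sex", "group", "value")],
                          design = "per_individual_by_day")
    expect_equal(length(pcv), 4)
    expect_setequal(unitIds(pcv), c("s1:day1", "s1:day2",
                                    "s2:day1", "s2:day2"))

    # group_means on a hand-built 2-group input: CV of the group means
    hb <- data.frame(strain = "s1",
                     sex = rep(c("female", "male"), each = 4),
                     group = rep(c("g1", "g2"), each = 2, times = 2),
                     value = c(10, 14, 20, 26, 9, 11, 30, 34))
    pg <- pairedCVTraits(hb, design = "group_means")
    expect_equal(cvFemale(pg), computeCV(c(mean(c(10, 14)),
                                           mean(c(20, 26)))))
    expect_equal(cvMale(pg), computeCV(c(mean(c(9, 11)),
                                         mean(c(30, 34)))))

    # a strain with one male vial is dropped with a logged count
    oneVial <- rbind(hb, data.frame(strain = "s2",
                                    sex = rep(c("female", "male"),
                                              c(4, 2)),
                                    group = c("g1", "g1", "g2", "g2",
                                              "g1", "g1"),
                                    value = c(10, 12, 14, 16, 20, 22)))
    expect_message(p2 <- pairedCVTraits(oneVial, design = "vial_means"),
                   "1 unit")
    expect_setequal(unitIds(p2), "s1")
    expect_equal(nDropped(p2), 1L)
    expect_error(pairedCVTraits(hb, design = "bogus"), "unknown")
})
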