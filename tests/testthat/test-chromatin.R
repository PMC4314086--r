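tractTable <- function(...) {
    df <- data.frame(..., stringsAsFactors = FALSE)
    names(df) <- c("chrom", "start", "end", "color")[seq_along(df)]
    df
}

test_that("color assignment requires full single-tract containment", {
    tracts <- grFromTable(data.frame(
        chrom = c("2L", "2L", "2L"), start = c(51, 301, 601),
        end = c(300, 500, 800),
        color = c("YELLOW", "BLACK", "YELLOW")), colorCol = "color")
    genes <- grFromTable(data.frame(
        chrom = "2L",
        start = c(101, 251, 51, 550, 120),
        end = c(200, 400, 300, 560, 130),
        gene_id = c("inside", "spanning", "exact", "outside", "inner2")))
    asn <- assignColors(genes, tracts)
    expect_identical(asn[["inside"]], "YELLOW")
    expect_identical(asn[["spanning"]], "UNASSIGNED")  # crosses a boundary
    expect_identical(asn[["exact"]], "YELLOW")          # equality allowed
    expect_identical(asn[["outside"]], "UNASSIGNED")
    expect_identical(asn[["inner2"]], "YELLOW")
})

test_that("chromosome identity is respected", {
    tracts <- grFromTable(data.frame(chrom = "2L", start = 1, end = 1000,
                                     color = "RED"), colorCol = "color")
    genes <- grFromTable(data.frame(chrom = c("2L", "3R"),
                                    start = c(10, 10), end = c(20, 20),
                                    gene_id = c("g1", "g2")))
    asn <- assignColors(genes, tracts)
    expect_identical(unname(asn), c("RED", "UNASSIGNED"))
})

test_that("same-color junctions stay unassigned unless tracts are merged", {
    tracts <- grFromTable(data.frame(
        chrom = "X", start = c(1, 501), end = c(500, 900),
        color = c("BLUE", "BLUE")), colorCol = "color")
    gene <- grFromTable(data.frame(chrom = "X", start = 400, end = 600,
                                   gene_id = "g"))
    expect_identical(unname(assignColors(gene, tracts)), "UNASSIGNED")
    expect_identical(unname(assignColors(gene, tracts,
                                         mergeSameColor = TRUE)), "BLUE")
})

test_that("assignment matches an exhaustive small-coordinate brute force", {
    # all gene placements over a tiny coordinate grid against two tracts
    tracts <- data.frame(chrom = "c", start = c(3, 8), end = c(7, 12),
                         color = c("RED", "GREEN"),
                         stringsAsFactors = FALSE)
    combos <- expand.grid(start = 1:13, end = 1:13)
    combos <- combos[combos$start <= combos$end, ]
    genes <- data.frame(chrom = "c", start = combos$start,
                        end = combos$end,
                        gene_id = sprintf("g%03d", seq_len(nrow(combos))),
                        stringsAsFactors = FALSE)
    got <- assignColors(grFromTable(genes),
                        grFromTable(tracts, colorCol = "color"))
    expect_identical(got, naiveAssignColors(genes, tracts))
})

test_that("assignment matches the double-loop oracle on random instances", {
    set.seed(23)
    for (i in 1:25) {
        nT <- sample(1:6, 1)
        starts <- sort(sample(seq(1, 500, by = 10), nT))
        widths <- sample(5:60, nT, replace = TRUE)
        ends <- pmin(starts + widths,
                     c(starts[-1] - 1, 600))  # keep tracts non-overlapping
        tracts <- data.frame(chrom = "c", start = starts, end = ends,
                             color = sample(chromatinColors(), nT,
                                            replace = TRUE),
                             stringsAsFactors = FALSE)
        nG <- sample(1:20, 1)
        gs <- sample(1:590, nG, replace = TRUE)
        genes <- data.frame(chrom = "c", start = gs,
                            end = gs + sample(0:80, nG, replace = TRUE),
                            gene_id = paste0("g", seq_len(nG)),
                            stringsAsFactors = FALSE)
        expect_identical(
            assignColors(grFromTable(genes),
                         grFromTable(tracts, colorCol = "color")),
            naiveAssignColors(genes, tracts))
    }
})

test_that("BED and GFF3 gene spans load onto identical coordinates", {
    bed <- tempfile(fileext = ".bed")
    # BED is 0-based half-open: [100, 200) is bases 101..200 inclusive
    writeLines(c("2L\t100\t200\tgeneA\t0\t+",
                 "2L\t300\t450\tgeneB\t0\t-"), bed)
    gff <- tempfile(fileext = ".gff3")
    writeLines(c("##gff-version 3",
                 "2L\tsrc\tgene\t101\t200\t.\t+\t.\tID=geneA",
                 "2L\tsrc\tgene\t301\t450\t.\t-\t.\tID=geneB",
                 "2L\tsrc\texon\t301\t350\t.\t-\t.\tID=exon1"), gff)
    gb <- readGeneSpans(bed)
    gg <- readGeneSpans(gff)
    expect_equal(length(gg), 2)     # exon feature ignored
    expect_equal(GenomicRanges::start(gb), GenomicRanges::start(gg))
    expect_equal(GenomicRanges::end(gb), GenomicRanges::end(gg))
    expect_identical(names(gb), names(gg))
})

test_that("color tract BED reading validates colors and overlap", {
    bed <- tempfile(fileext = ".bed")
    writeLines(c("2L\t0\t100\tyellow", "2L\t100\t250\tBLACK"), bed)
    tr <- readColorTracts(bed)
    expect_identical(tr$color, c("YELLOW", "BLACK"))

    bad <- tempfile(fileext = ".bed")
    writeLines("2L\t0\t100\tmauve", bad)
    expect_error(readColorTracts(bad), "unknown chromatin color")

    ovl <- tempfile(fileext = ".bed")
    writeLines(c("2L\t0\t100\tRED", "2L\t50\t150\tBLUE"), ovl)
    expect_error(readColorTracts(ovl), "overlap")
})

test_that("a single-color stratified test reduces to the plain test", {
    set.seed(29)
    n <- 80
    p <- PairedCV(paste0("u", 1:n), rlnorm(n, 0, 0.2), rlnorm(n, 0, 0.2),
                  color = "YELLOW")
    st <- stratifiedTest(p, nSim = 500, seed = 61)
    expect_named(st, "YELLOW")
    plain <- signedRankTest(p, nSim = 500, seed = 61)
    expect_equal(observedW(st$YELLOW), observedW(plain))
    expect_identical(simulatedW(st$YELLOW), simulatedW(plain))
    expect_equal(pLower(st$YELLOW), pLower(plain))
})

test_that("per-stratum W uses within-color ranks and skips UNASSIGNED", {
    nA <- 7; nB <- 5
    p <- PairedCV(c(paste0("a", 1:nA), paste0("b", 1:nB), "u1"),
                  c(1 + (1:nA) / 10, rep(0.1, nB), 0.5),
                  c(rep(0.1, nA), 1 + (1:nB) / 10, 0.9),
                  color = c(rep("RED", nA), rep("GREEN", nB),
                            "UNASSIGNED"))
    st <- stratifiedTest(p, nSim = 50, seed = 71)
    expect_setequal(names(st), c("RED", "GREEN"))
    expect_equal(observedW(st$RED), nA * (nA + 1) / 2)
    expect_equal(observedW(st$GREEN), -nB * (nB + 1) / 2)
    expect_equal(st$RED@nPairs + st$GREEN@nPairs, length(p) - 1L)
    # strata share each global rearrangement: same seed, coupled nulls
    st2 <- stratifiedTest(p, nSim = 50, seed = 71)
    expect_identical(simulatedW(st2$RED), simulatedW(st$RED))
})

test_that("colors attach to pairs by unit id", {
    p <- PairedCV(c("g1", "g2", "g3"), c(.1, .2, .3), c(.2, .2, .2))
    asn <- c(g1 = "YELLOW", g3 = "BLUE")
    pc <- addColors(p, asn)
    expect_identical(pairColors(pc), c("YELLOW", "UNASSIGNED", "BLUE"))
})
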