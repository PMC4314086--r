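# Independent oracles and small fixture builders used across the suite.

# closed-form null SD of W for n tie-free pairs (sign-randomization law)
sigmaW <- function(n) sqrt(n * (n + 1) * (2 * n + 1) / 6)

# all permutations of 1..n as a matrix (n! rows); plain recursion
permutationsOf <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- permutationsOf(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        rest <- seq_len(n)[-k]
        cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    }))
}

# signed-rank sum computed directly from the definition
naiveW <- function(cvF, cvM) {
    d <- cvF - cvM
    sum(sign(d) * rank(abs(d)))
}

# brute-force normal-equations quadratic fit
normalEquationsFit <- function(x, y) {
    X <- cbind(1, x, x^2)
    b <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% b
    list(b = as.numeric(b), r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# O(genes x tracts) containment oracle on plain coordinate tables
# (1-based closed intervals, as GRanges stores them)
naiveAssignColors <- function(genes, tracts) {
    out <- rep("UNASSIGNED", nrow(genes))
    for (i in seq_len(nrow(genes))) {
        hits <- character()
        for (j in seq_len(nrow(tracts))) {
            if (genes$chrom[i] == tracts$chrom[j] &&
                tracts$start[j] <= genes$start[i] &&
                genes$end[i] <= tracts$end[j])
                hits <- c(hits, tracts$color[j])
        }
        if (length(hits) == 1L) out[i] <- hits
    }
    stats::setNames(out, genes$gene_id)
}

grFromTable <- function(df, colorCol = NULL) {
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    if (!is.null(colorCol)) gr$color <- df[[colorCol]]
    if (!is.null(df$gene_id)) names(gr) <- df$gene_id
    gr
}

# hand-built expression dataset: values[t, sample] laid out as
# female replicates then male replicates for a single strain
makeTinyDataset <- function(values, reps, strain = "A") {
    ExpressionDataset(values,
                      strain = rep(strain, 2 * reps),
                      sex = rep(c("female", "male"), each = reps),
                      replicate = rep(seq_len(reps), 2))
}

# exact upper p-value of the tag permutation test by full enumeration
enumTagPUpper <- function(tags, disp, subset = "all") {
    het <- function(t) ifelse(t %in% c("XY", "XO"), "male", "female")
    sel <- function(t) switch(subset, all = rep(TRUE, length(t)),
                              with_WY = t %in% c("XY", "ZW"),
                              without_WY = t %in% c("XO", "ZO"))
    obs <- mean((disp == het(tags))[sel(tags)])
    perms <- permutationsOf(length(tags))
    fr <- apply(perms, 1L, function(p) {
        t2 <- tags[p]
        mean((disp == het(t2))[sel(t2)])
    })
    mean(fr >= obs)
}
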