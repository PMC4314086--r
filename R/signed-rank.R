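#' Wilcoxon sum of signed ranks over paired CVs
#'
#' The core sex-bias statistic.  For each unit the male CV is subtracted
#' from the female CV; the absolute differences are ranked ascending (1..n,
#' midranks on ties) and each rank takes the sign of its difference.  W is
#' the sum of the signed ranks, so `W < 0` indicates generally noisier male
#' expression.  Zero differences keep their rank with sign 0 and contribute
#' nothing; no unit is dropped.  W is sensitive both to how many units are
#' biased and to how strongly, without any significance threshold per unit.
#'
#' @param pairs a [PairedCV-class] with at least one unit.
#' @return The observed W (signed rank units); `|W| <= n(n+1)/2`.
#' @examples
#' p <- PairedCV(c("a", "b", "c"), c(0.5, 0.3, 0.9), c(0.2, 0.4, 0.9))
#' wilcoxonW(p)  # d = (+0.3, -0.1, 0); ranks (3, 2, 1); W = +3 - 2 + 0 = 1
#' @export
wilcoxonW <- function(pairs) {
    stopifnot(is(pairs, "PairedCV"))
    if (length(pairs) == 0L) stop("empty PairedCV table")
    .wilcoxW(pairs@cvF - pairs@cvM)
}

.wilcoxW <- function(d) sum(sign(d) * rank(abs(d)))

#' Monte Carlo null distribution of W by global rearrangement
#'
#' Builds the permutation null the test compares against: all `2n` CV
#' values (both sexes, every unit) are pooled, uniformly permuted, and
#' refilled into the n female slots and n male slots in order; W is then
#' recomputed.  Repeating this `nSim` times yields the distribution W takes
#' for data with the same values but no female/male structure.  For
#' tie-free data this global rearrangement is equivalent in law to flipping
#' each pair's sign independently, so `Var(W) = n(n+1)(2n+1)/6`.
#'
#' @param pairs a [PairedCV-class].
#' @param nSim number of rearrangements (default 10,000).
#' @param seed mandatory RNG seed.
#' @return Numeric vector of `nSim` simulated W values.
#' @export
mcNullW <- function(pairs, nSim = 10000L, seed) {
    stopifnot(is(pairs, "PairedCV"))
    if (missing(seed)) stop("'seed' is mandatory")
    nSim <- stopIfNotCount(nSim, "nSim")
    n <- length(pairs)
    if (n == 0L) stop("empty PairedCV table")
    pool <- c(pairs@cvF, pairs@cvM)
    withSeed(seed, {
        vapply(seq_len(nSim), function(i) {
            p <- pool[sample.int(2L * n)]
            .wilcoxW(p[seq_len(n)] - p[n + seq_len(n)])
        }, numeric(1))
    })
}

#' Summarize an observed W against its Monte Carlo null
#'
#' `pUpper` is the fraction of simulated W greater than or equal to the
#' observed one, `pLower` the fraction less than or equal (ties count on
#' both sides, so `pUpper + pLower >= 1`).  The 5th/95th percentiles of the
#' simulated W use linear interpolation.  P-values are stored as plain
#' fractions; only the text renderers print a zero count as `"<1/n_sim"`.
#'
#' @param observedW observed statistic from [wilcoxonW()].
#' @param simulatedW non-empty numeric vector from [mcNullW()].
#' @param nPairs number of pairs behind `observedW`.
#' @param label analysis label carried into the result.
#' @param seed seed used for `simulatedW` (recorded, not used).
#' @return A [SignedRankResult-class].
#' @export
summarizeSignedRank <- function(observedW, simulatedW, nPairs,
                                label = "", seed = NA_integer_) {
    if (!length(simulatedW)) stop("simulatedW must be non-empty")
    q <- stats::quantile(simulatedW, c(0.05, 0.95), names = FALSE, type = 7)
    new("SignedRankResult", label = label, nPairs = as.integer(nPairs),
        observedW = observedW, simulatedW = as.numeric(simulatedW),
        p5 = q[1], p95 = q[2],
        pUpper = mean(simulatedW >= observedW),
        pLower = mean(simulatedW <= observedW),
        nSim = length(simulatedW), seed = as.integer(seed))
}

#' Monte Carlo-Wilcoxon matched-pairs signed-ranks test
#'
#' Convenience wrapper running [wilcoxonW()], [mcNullW()] and
#' [summarizeSignedRank()] in one call.
#'
#' @inheritParams mcNullW
#' @inheritParams summarizeSignedRank
#' @return A [SignedRankResult-class].
#' @examples
#' cfg <- SimExprConfig(nTranscripts = 200, nStrains = 1,
#'                      noiseInflationGamma = 2, seed = 7)
#' pcv <- pairedCVExpression(simulateExpression(cfg), "strain01")
#' signedRankTest(pcv, nSim = 200, seed = 11)
#' @export
signedRankTest <- function(pairs, nSim = 10000L, seed, label = "") {
    obs <- wilcoxonW(pairs)
    sims <- mcNullW(pairs, nSim = nSim, seed = seed)
    summarizeSignedRank(obs, sims, nPairs = length(pairs), label = label,
                        seed = seed)
}

#' Render signed-rank results as a report table
#'
#' One row per result with the columns of the main result tables: label,
#' replication, pair count, observed W, null 5th/95th percentiles, and the
#' two p-values rendered with [formatMCPValue()] (a zero count prints as
#' `"<1/n_sim"`).
#'
#' @param results list of [SignedRankResult-class] objects.
#' @param nReplicates optional per-result replication annotation.
#' @return data.frame ready for TSV export.
#' @export
renderSignedRankTable <- function(results, nReplicates = NA) {
    if (is(results, "SignedRankResult")) results <- list(results)
    nReplicates <- rep_len(nReplicates, length(results))
    do.call(rbind, lapply(seq_along(results), function(i) {
        r <- results[[i]]
        data.frame(label = r@label, n_replicates = nReplicates[i],
                   n_datapairs = r@nPairs, observed_w = r@observedW,
                   p5 = r@p5, p95 = r@p95,
                   p_upper = formatMCPValue(r@pUpper, r@nSim),
                   p_lower = formatMCPValue(r@pLower, r@nSim),
                   stringsAsFactors = FALSE)
    }))
}
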