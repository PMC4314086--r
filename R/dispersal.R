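.dispersalSubsets <- c("all", "with_WY", "without_WY")

.subsetRows <- function(df, subset) {
    switch(subset,
           all = rep(TRUE, nrow(df)),
           with_WY = df$has_WY,
           without_WY = !df$has_WY,
           stop("unknown subset: ", subset))
}

#' Fraction of species with heterogamety-biased dispersal
#'
#' The fraction of species, within a subset, whose dispersing-most sex
#' equals the heterogametic sex implied by their chromosome system.
#'
#' @param table a [DispersalTable-class].
#' @param subset `"all"`, `"with_WY"` (XY/ZW species) or `"without_WY"`
#'   (XO/ZO species).
#' @return Fraction in `[0, 1]` (full precision; report renderers round to
#'   two decimals).
#' @examples
#' hetBiasedFraction(loadDispersalFixture(), "all")
#' @export
hetBiasedFraction <- function(table, subset = "all") {
    stopifnot(is(table, "DispersalTable"))
    df <- table@records
    sel <- .subsetRows(df, match.arg(subset, .dispersalSubsets))
    if (!any(sel)) stop("empty subset: ", subset)
    mean(df$dispersing_sex[sel] == df$heterogametic_sex[sel])
}

#' Permutation test for heterogamety-biased dispersal
#'
#' Builds the null by uniformly permuting the chromosome-system tags across
#' all species (dispersal directions stay put), re-deriving each species'
#' heterogametic sex and W/Y status from its permuted tag, and recomputing
#' the subset's heterogamety-biased fraction.  Tags are always permuted over
#' the full table, even when testing a W/Y subset: subset membership is
#' itself tag-derived, so it is re-formed from the permuted tags each
#' replicate.
#'
#' @inheritParams hetBiasedFraction
#' @param nSim number of tag permutations (default 10,000).
#' @param seed mandatory RNG seed.
#' @return A [DispersalTestResult-class].
#' @export
tagPermutationTest <- function(table, subset = "all", nSim = 10000L, seed) {
    stopifnot(is(table, "DispersalTable"))
    if (missing(seed)) stop("'seed' is mandatory")
    nSim <- stopIfNotCount(nSim, "nSim")
    subset <- match.arg(subset, .dispersalSubsets)
    df <- table@records
    obs <- hetBiasedFraction(table, subset)
    nObs <- sum(.subsetRows(df, subset))
    disp <- df$dispersing_sex
    tags <- df$chromosome_system
    sims <- withSeed(seed, {
        vapply(seq_len(nSim), function(i) {
            t2 <- tags[sample.int(length(tags))]
            het <- ifelse(t2 %in% c("XY", "XO"), "male", "female")
            sel <- switch(subset, all = TRUE,
                          with_WY = t2 %in% c("XY", "ZW"),
                          without_WY = t2 %in% c("XO", "ZO"))
            b <- (disp == het)[sel]
            if (length(b)) mean(b) else NA_real_
        }, numeric(1))
    })
    sims <- sims[!is.na(sims)]   # permutations emptying the subset drop out
    q <- stats::quantile(sims, c(0.05, 0.95), names = FALSE, type = 7)
    new("DispersalTestResult", subset = subset, n = as.integer(nObs),
        observedFraction = obs, simulatedFractions = sims,
        p5 = q[1], p95 = q[2],
        pUpper = mean(sims >= obs), pLower = mean(sims <= obs),
        nSim = length(sims), seed = as.integer(seed))
}

#' Render dispersal test results as a report table
#'
#' Mirrors the dispersal result table: observed fraction and simulated
#' percentiles to two decimals, p-values via [formatMCPValue()].
#'
#' @param results list of [DispersalTestResult-class] objects.
#' @return data.frame ready for TSV export.
#' @export
renderDispersalTable <- function(results) {
    if (is(results, "DispersalTestResult")) results <- list(results)
    do.call(rbind, lapply(results, function(r)
        data.frame(subset = r@subset, n = r@n,
                   observed_fraction = sprintf("%.2f", r@observedFraction),
                   p5 = sprintf("%.2f", r@p5), p95 = sprintf("%.2f", r@p95),
                   p_upper = formatMCPValue(r@pUpper, r@nSim),
                   p_lower = formatMCPValue(r@pLower, r@nSim),
                   stringsAsFactors = FALSE)))
}
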