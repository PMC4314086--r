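#' Evaluate an expression under an explicit RNG seed
#'
#' All Monte Carlo machinery in the package takes a mandatory seed; this
#' helper seeds the RNG for the duration of `code` and restores the caller's
#' RNG state afterwards, so no function leaves global side effects.
#'
#' @param seed a single finite integer-valued number.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("'seed' must be a single finite number")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

#' Render a Monte Carlo p-value the way the result tables print it
#'
#' A permutation p-value of exactly zero means no simulated statistic reached
#' the observed one, so the text rendering is the resolution bound
#' `"<1/n_sim"` (e.g. `"<0.0001"` at 10,000 rearrangements).  Everything else
#' is printed with four decimals.  Only this renderer rounds; stored
#' p-values stay full precision.
#'
#' @param p numeric p-value in `[0, 1]`.
#' @param nSim number of Monte Carlo replicates behind `p`.
#' @return character rendering.
#' @export
formatMCPValue <- function(p, nSim) {
    ifelse(p == 0, paste0("<", formatC(1 / nSim, format = "f",
                                       digits = ceiling(log10(nSim)))),
           sprintf("%.4f", p))
}

stopIfNotCount <- function(x, name, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < min || x != round(x))
        stop(sprintf("'%s' must be a single integer >= %d", name, min))
    invisible(as.integer(x))
}
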