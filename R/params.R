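#' Analysis parameters
#'
#' Bundles every tunable of the pipeline with its default. Defaults follow
#' the method's published settings: 1,000 random experiments for the
#' pathway-burden null, FDR cutoff 0.05, common sub-pathway coverage
#' threshold 90% with at least five genes, subtype coverage-difference
#' threshold 0.25, and a raw Fisher p cutoff of 0.05 at the sub-pathway
#' emission gate.
#'
#' @param nReps number of random experiments for the permutation null
#'   (default 1000).
#' @param fdr BH-adjusted significance cutoff for pathway screens
#'   (default 0.05).
#' @param coverageThreshold minimum cohort coverage of an emitted common
#'   sub-pathway, in (0, 1] (default 0.90).
#' @param minGenes minimum gene count of an emitted common sub-pathway
#'   (default 5).
#' @param diffThreshold minimum subtype coverage difference of an emitted
#'   subtype-specific sub-pathway (default 0.25).
#' @param alpha raw Fisher p cutoff at the subtype sub-pathway emission gate
#'   (default 0.05).
#' @param seed integer seed for the permutation null; `NULL` leaves the RNG
#'   state untouched.
#' @param excludeClasses MAF Variant_Classification values to drop when
#'   reading variants (default: none).
#' @param nonGainBudget maximum number of retained genes that do not
#'   increase the coverage difference in subtype mode (default 1).
#' @param addOne if `TRUE`, use the add-one permutation p estimator
#'   (sum+1)/(n+1) instead of the plain exceedance fraction; default `FALSE`.
#' @return a named list of class `PathMGParams`.
#' @examples
#' pathMGParams(coverageThreshold = 0.85)
#' @export
pathMGParams <- function(nReps = 1000L, fdr = 0.05, coverageThreshold = 0.90,
                         minGenes = 5L, diffThreshold = 0.25, alpha = 0.05,
                         seed = NULL, excludeClasses = character(),
                         nonGainBudget = 1L, addOne = FALSE) {
    nReps <- as.integer(nReps)
    minGenes <- as.integer(minGenes)
    nonGainBudget <- as.integer(nonGainBudget)
    stopifnot(length(nReps) == 1L, nReps >= 1L,
              length(fdr) == 1L, fdr > 0, fdr <= 1,
              length(coverageThreshold) == 1L,
              coverageThreshold > 0, coverageThreshold <= 1,
              length(minGenes) == 1L, minGenes >= 1L,
              length(diffThreshold) == 1L,
              diffThreshold > 0, diffThreshold < 1,
              length(alpha) == 1L, alpha > 0, alpha <= 1,
              nonGainBudget >= 0L,
              is.logical(addOne), length(addOne) == 1L)
    if (!is.null(seed)) seed <- as.integer(seed)
    structure(list(nReps = nReps, fdr = fdr,
                   coverageThreshold = coverageThreshold,
                   minGenes = minGenes, diffThreshold = diffThreshold,
                   alpha = alpha, seed = seed,
                   excludeClasses = as.character(excludeClasses),
                   nonGainBudget = nonGainBudget, addOne = addOne),
              class = c("PathMGParams", "list"))
}

#' @export
print.PathMGParams <- function(x, ...) {
    cat("PathMG parameters:\n")
    for (nm in names(x)) {
        v <- x[[nm]]
        cat(sprintf("  %-18s %s\n", nm,
                    if (is.null(v)) "NULL" else paste(v, collapse = ",")))
    }
    invisible(x)
}
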