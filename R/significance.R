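## Significantly mutated pathways under a degree-preserving random null:
## each random experiment redraws, for every sample, the same number of
## mutated genes it really has, uniformly without replacement from the
## background gene universe. A pathway's permutation p is the fraction of
## experiments in which the random mutated-sample count strictly exceeds the
## observed one.

#' Number of samples in which a gene set is mutated
#'
#' A sample counts as mutated in the set iff at least one member gene
#' carries a mutation in it. Genes absent from the profile contribute
#' nothing.
#'
#' @param profile a [MutationProfile-class].
#' @param genes character vector (or [GeneList-class]) of gene symbols.
#' @return integer count in `[0, nSamples(profile)]`.
#' @export
pathwayMutatedSamples <- function(profile, genes) {
    genes <- .asGenes(genes)
    if (!length(genes)) {
        warning("empty gene set; returning 0")
        return(0L)
    }
    genes <- intersect(genes, geneNames(profile))
    if (!length(genes)) return(0L)
    sum(Matrix::colSums(mutationMatrix(profile)[genes, , drop = FALSE]) > 0)
}

#' Exceedance p-value from injected null counts
#'
#' Computes `p = (# replicates with R > M) / n`, the plain permutation
#' estimator used for pathway burden: ties count as non-exceedance. With
#' `addOne = TRUE` the positively biased but never-zero estimator
#' `(sum + 1)/(n + 1)` is used instead.
#'
#' @param nullCounts integer vector of per-replicate null statistics R.
#' @param observed observed statistic M.
#' @param addOne use the add-one estimator (default `FALSE`).
#' @return list with `p`, `exceedCount` and `nReps`.
#' @export
exceedancePValue <- function(nullCounts, observed, addOne = FALSE) {
    n <- length(nullCounts)
    if (n < 1L) stop("at least one null replicate is required")
    ex <- sum(nullCounts > observed)
    p <- if (addOne) (ex + 1) / (n + 1) else ex / n
    list(p = p, exceedCount = as.integer(ex), nReps = as.integer(n))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH FDR adjustment (delegates to [stats::p.adjust()]), with input
#' validation.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted values in input order.
#' @export
bhAdjust <- function(pvalues) {
    if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(pvalues, method = "BH")
}

## internal: resolve a background universe, folding in mutated genes that
## the supplied list is missing (they must be drawable or per-sample counts
## could exceed the universe).
.resolveBackground <- function(profile, background) {
    bg <- .asGenes(background)
    if (!length(bg)) stop("background gene list is empty")
    mutated <- geneNames(profile)[Matrix::rowSums(mutationMatrix(profile)) > 0]
    extra <- setdiff(mutated, bg)
    if (length(extra)) {
        warning(length(extra),
                " mutated gene(s) absent from the background were added to it")
        bg <- c(bg, extra)
    }
    bg
}

## internal: one random experiment. Returns (sample index, gene index) pairs
## over the background universe, preserving per-sample mutated-gene counts.
.drawNullPairs <- function(counts, B) {
    gi <- unlist(lapply(counts, function(k) sample.int(B, k)),
                 use.names = FALSE)
    si <- rep.int(seq_along(counts), counts)
    list(gi = gi, si = si)
}

#' Simulate one null mutation profile
#'
#' Produces a random cohort over the background gene universe in which every
#' sample keeps exactly its observed number of mutated genes, drawn
#' uniformly without replacement and independently across samples.
#'
#' @param profile the observed [MutationProfile-class].
#' @param background background gene universe ([GeneList-class] or
#'   character); mutated genes missing from it are folded in with a warning.
#' @param seed optional integer seed.
#' @return a [MutationProfile-class] over the background genes with the same
#'   sample roster.
#' @export
simulateNullProfile <- function(profile, background, seed = NULL) {
    bg <- .resolveBackground(profile, background)
    counts <- sampleMutationCounts(profile)
    if (max(counts) > length(bg))
        stop("a sample has more mutated genes than the background holds")
    if (!is.null(seed)) set.seed(seed)
    d <- .drawNullPairs(counts, length(bg))
    .newProfile(gi = d$gi, si = d$si, genes = bg,
                samples = sampleNames(profile))
}

#' Permutation p-values for pathway mutation burden
#'
#' For every pathway, counts the samples mutated in it (M), then runs
#' `nReps` random experiments; in each, every sample redraws its observed
#' number of mutated genes uniformly from the background and the random
#' mutated-sample count R is compared against M. `p = #(R > M)/nReps`, with
#' all pathways evaluated against the same simulated cohorts, and q from BH
#' adjustment. Deterministic given `seed`.
#'
#' @param profile a [MutationProfile-class].
#' @param pathways non-empty list of [Pathway-class] objects.
#' @param background background universe ([GeneList-class] or character).
#' @param nReps number of random experiments (default 1000).
#' @param seed optional integer seed.
#' @param addOne use the add-one p estimator (see [exceedancePValue()]).
#' @return data.frame with one row per pathway: `pathway_id`, `name`,
#'   `n_genes`, `M`, `N`, `exceed_count`, `n_reps`, `p`, `q`.
#' @export
permutationPvalues <- function(profile, pathways, background, nReps = 1000L,
                               seed = NULL, addOne = FALSE) {
    if (!length(pathways)) stop("pathways must be non-empty")
    nReps <- as.integer(nReps)
    if (nReps < 1L) stop("nReps must be >= 1")
    bg <- .resolveBackground(profile, background)
    B <- length(bg)
    counts <- sampleMutationCounts(profile)
    if (max(counts) > B)
        stop("a sample has more mutated genes than the background holds")
    N <- nSamples(profile)

    M <- vapply(pathways, function(p)
        pathwayMutatedSamples(profile, pathwayGenes(p)), 0L)

    # pathway membership over the background universe (genes outside the
    # background are never drawn, so they drop out of the null)
    P <- length(pathways)
    mi <- unlist(lapply(seq_len(P), function(j) {
        idx <- match(intersect(pathwayGenes(pathways[[j]]), bg), bg)
        idx
    }), use.names = FALSE)
    mj <- rep.int(seq_len(P), vapply(seq_len(P), function(j)
        length(intersect(pathwayGenes(pathways[[j]]), bg)), 0L))
    mem <- Matrix::sparseMatrix(i = mi, j = mj, x = 1, dims = c(B, P))

    if (!is.null(seed)) set.seed(seed)
    exceed <- integer(P)
    for (r in seq_len(nReps)) {
        d <- .drawNullPairs(counts, B)
        S <- Matrix::sparseMatrix(i = d$si, j = d$gi, x = 1, dims = c(N, B),
                                  use.last.ij = TRUE)
        R <- Matrix::colSums((S %*% mem) > 0)
        exceed <- exceed + (R > M)
    }
    p <- if (addOne) (exceed + 1) / (nReps + 1) else exceed / nReps
    data.frame(pathway_id = vapply(pathways, pathwayId, ""),
               name = vapply(pathways, pathwayName, ""),
               n_genes = vapply(pathways, function(x)
                   length(pathwayGenes(x)), 0L),
               M = as.integer(M), N = N,
               exceed_count = as.integer(exceed), n_reps = nReps,
               p = p, q = bhAdjust(p), stringsAsFactors = FALSE)
}

#' Filter significant pathways
#'
#' @param results data.frame from [permutationPvalues()] (or any table with
#'   `q` and `pathway_id` columns).
#' @param fdr BH-adjusted cutoff (default 0.05).
#' @return rows with `q < fdr`, sorted by `q` then `pathway_id`.
#' @export
significantPathways <- function(results, fdr = 0.05) {
    keep <- results[results$q < fdr, , drop = FALSE]
    keep[order(keep$q, keep$pathway_id), , drop = FALSE]
}
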