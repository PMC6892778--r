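## Synthetic cohorts and pathway collections with known planted structure.
## The generator emulates the statistical shape of a somatic-mutation cohort
## -- overdispersed per-sample mutated-gene counts (negative binomial, to
## mimic hypermutator tails), uniform background gene usage -- and can plant
## (a) a connected gene set whose union of mutations covers an exact target
## fraction of samples and (b) a connected gene set with a prescribed
## coverage difference between two subtypes. Everything is deterministic
## per seed, and the planted quantities are exactly auditable on the
## emitted matrices.

#' Describe a synthetic benchmarking scenario
#'
#' @param nSamples cohort size (default 200, the scale at which the planted
#'   recovery benchmarks are run).
#' @param nBackgroundGenes size of the background gene universe
#'   (default 1000).
#' @param pathwaySizes integer vector: one pathway per element, of that many
#'   genes (default ten pathways of 15 genes).
#' @param edgeDensity probability of an edge between two member genes of a
#'   pathway (Erdos-Renyi; default 0.2).
#' @param mutationMean,mutationDispersion negative-binomial mean and size
#'   parameters of the per-sample mutated-gene count (defaults 20 and 2;
#'   size 2 gives the heavy upper tail seen in hypermutated samples).
#' @param seed integer RNG seed.
#' @return a named list of class `SyntheticScenario`.
#' @export
syntheticScenario <- function(nSamples = 200L, nBackgroundGenes = 1000L,
                              pathwaySizes = rep(15L, 10L),
                              edgeDensity = 0.2, mutationMean = 20,
                              mutationDispersion = 2, seed = 1L) {
    stopifnot(nSamples >= 1L, nBackgroundGenes >= 1L,
              all(pathwaySizes >= 1L), edgeDensity >= 0, edgeDensity <= 1,
              mutationMean > 0, mutationDispersion > 0)
    structure(list(nSamples = as.integer(nSamples),
                   nBackgroundGenes = as.integer(nBackgroundGenes),
                   pathwaySizes = as.integer(pathwaySizes),
                   edgeDensity = edgeDensity,
                   mutationMean = mutationMean,
                   mutationDispersion = mutationDispersion,
                   seed = as.integer(seed)),
              class = c("SyntheticScenario", "list"))
}

#' Generate a random pathway collection and background universe
#'
#' Gene symbols are `G0001`, `G0002`, ...; each pathway draws its members
#' from the background without replacement and wires them with independent
#' Erdos-Renyi edges at the scenario's density, so a pathway may decompose
#' into several connected components or isolated genes.
#'
#' @param scenario a [syntheticScenario()] list.
#' @return list with `pathways` (list of [Pathway-class]) and `background`
#'   (a [GeneList-class]).
#' @export
generatePathwayDB <- function(scenario) {
    set.seed(scenario$seed)
    bg <- sprintf("G%04d", seq_len(scenario$nBackgroundGenes))
    pws <- vector("list", length(scenario$pathwaySizes))
    for (i in seq_along(scenario$pathwaySizes)) {
        s <- scenario$pathwaySizes[i]
        genes <- sample(bg, s)
        g <- igraph::sample_gnp(s, scenario$edgeDensity)
        e <- igraph::as_edgelist(g)
        em <- if (nrow(e)) cbind(genes[e[, 1L]], genes[e[, 2L]]) else NULL
        pws[[i]] <- Pathway(sprintf("PW%03d", i), genes = genes, edges = em,
                            name = sprintf("synthetic pathway %d", i))
    }
    list(pathways = pws, background = GeneList(bg, label = "background"))
}

#' Simulate a background-noise mutation cohort
#'
#' Per-sample mutated-gene counts are drawn from a negative binomial
#' (truncated to the universe size) and genes uniformly without replacement
#' from the background: exactly the null model of the pathway-burden test.
#'
#' @param scenario a [syntheticScenario()] list.
#' @param background optional [GeneList-class]/character universe; defaults
#'   to the scenario's `G...` roster.
#' @param seed optional seed overriding the scenario's.
#' @return a [MutationProfile-class] (background genes x samples).
#' @export
simulateCohort <- function(scenario, background = NULL, seed = NULL) {
    bg <- if (is.null(background))
        sprintf("G%04d", seq_len(scenario$nBackgroundGenes))
    else .asGenes(background)
    set.seed(if (is.null(seed)) scenario$seed else as.integer(seed))
    counts <- pmin(stats::rnbinom(scenario$nSamples,
                                  size = scenario$mutationDispersion,
                                  mu = scenario$mutationMean),
                   length(bg))
    d <- .drawNullPairs(counts, length(bg))
    .newProfile(gi = d$gi, si = d$si, genes = bg,
                samples = sprintf("S%04d", seq_len(scenario$nSamples)))
}

## internal: clear the planted genes' rows and re-assign mutations so that
## exactly k samples carry >= 1 mutation in the set. Round-robin assignment
## over the non-redundant genes gives every one of them a positive marginal
## gain; redundant genes instead receive mutations only in already-covered
## samples (exercising the zero-gain rescue logic).
.plantCoverage <- function(profile, genes, k, redundant = character()) {
    m <- as.matrix(mutationMatrix(profile))
    missingGenes <- setdiff(genes, rownames(m))
    if (length(missingGenes)) {
        m <- rbind(m, matrix(0, length(missingGenes), ncol(m),
                             dimnames = list(missingGenes, colnames(m))))
    }
    m[genes, ] <- 0
    covered <- sample.int(ncol(m), k)
    rr <- setdiff(genes, redundant)
    if (!length(rr)) stop("at least one non-redundant planted gene is needed")
    for (j in seq_along(covered))
        m[rr[(j - 1L) %% length(rr) + 1L], covered[j]] <- 1
    for (g in redundant) {
        take <- covered[seq_len(min(3L, length(covered)))]
        m[g, take] <- 1
    }
    MutationProfile(m)
}

#' Plant a common-coverage signal into a cohort
#'
#' Rewrites the planted genes' rows so that exactly `ceiling(c * N)` samples
#' carry at least one mutation in the planted set; covered samples are
#' assigned round-robin over the planted genes so each gene covers its own
#' share of samples. All other rows (background noise) are left untouched.
#'
#' @param profile the noise [MutationProfile-class] to modify.
#' @param genes the planted gene set (connected in its host pathway).
#' @param targetCoverage target fraction `c` in (0, 1].
#' @param redundant optional subset of `genes` to make coverage-redundant
#'   (mutated only in already-covered samples), for exercising the
#'   zero-gain rescue path of the greedy search.
#' @param seed optional integer seed.
#' @return a new [MutationProfile-class].
#' @export
plantCommonSignal <- function(profile, genes, targetCoverage,
                              redundant = character(), seed = NULL) {
    N <- nSamples(profile)
    if (targetCoverage * N < 1) stop("targetCoverage * N is below one sample")
    k <- ceiling(targetCoverage * N)
    if (k > N) stop("targetCoverage must be at most 1")
    if (!is.null(seed)) set.seed(seed)
    .plantCoverage(profile, genes, k, redundant = redundant)
}

#' Plant a subtype-differential signal into two cohorts
#'
#' Sets the planted-set coverage to `base + max(d, 0)` in subtype A and
#' `base + max(-d, 0)` in subtype B (rounded to whole samples), so the
#' realized coverage difference equals the target `d` to within one sample
#' of the smaller subtype.
#'
#' @param profileA,profileB per-subtype noise [MutationProfile-class]
#'   objects.
#' @param genes the planted gene set (connected in its host pathway).
#' @param targetDiff target coverage difference `d` in (-1, 1); positive
#'   plants an A-specific signal, negative a B-specific one.
#' @param baseCoverage planted coverage of the lower subtype (default 0.3).
#' @param seed optional integer seed.
#' @return list with modified `A` and `B` profiles and the realized
#'   `diff`.
#' @export
plantSubtypeSignal <- function(profileA, profileB, genes, targetDiff,
                               baseCoverage = 0.3, seed = NULL) {
    cA <- baseCoverage + max(targetDiff, 0)
    cB <- baseCoverage + max(-targetDiff, 0)
    if (cA > 1 || cB > 1 || baseCoverage < 0)
        stop("infeasible target difference at this base coverage")
    nA <- nSamples(profileA); nB <- nSamples(profileB)
    kA <- round(cA * nA); kB <- round(cB * nB)
    if (kA < 1L && kB < 1L) stop("planted coverage is below one sample")
    if (!is.null(seed)) set.seed(seed)
    A <- .plantCoverage(profileA, genes, kA)
    B <- .plantCoverage(profileB, genes, kB)
    list(A = A, B = B, diff = kA / nA - kB / nB)
}
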