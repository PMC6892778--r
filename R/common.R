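## Greedy extraction of connected sub-pathways by patient coverage.
##
## The growth loop operates on one connected component of a pathway's
## interaction graph. Starting from the most frequently mutated gene, each
## pass ranks the unvisited direct neighbours of the current seeds by their
## marginal coverage gain (Pf) computed against the sub-pathway state at the
## start of the pass, then adds them in descending order. A gene whose
## realized gain at insertion time is positive joins the sub-pathway (set GI)
## and becomes a new seed; a gene with no realized gain (set GN) is retained
## only if at least one of its own unvisited neighbours, tried in descending
## gain order, yields a positive gain -- those neighbours become new seeds --
## otherwise it is removed and never revisited. Ties in frequency or gain
## break lexicographically on the gene symbol so runs are deterministic.

#' Connected components of a pathway graph
#'
#' @param pathway a [Pathway-class].
#' @return list of character vectors partitioning the pathway's genes into
#'   maximal connected sets; isolated genes are singleton components.
#'   Components are ordered by first appearance of a member in the
#'   pathway's gene vector.
#' @export
pathwayComponents <- function(pathway) {
    g <- pathwayGraph(pathway)
    comp <- igraph::components(g)
    membership <- comp$membership[pathwayGenes(pathway)]
    split(pathwayGenes(pathway),
          factor(membership, levels = unique(membership)))
}

#' Cohort coverage of a gene set
#'
#' Fraction of samples carrying at least one mutation in any member gene.
#'
#' @inheritParams pathwayMutatedSamples
#' @return fraction in `[0, 1]`.
#' @export
mutationCoverage <- function(profile, genes) {
    if (nSamples(profile) == 0L) stop("profile has no samples")
    if (!length(.asGenes(genes))) return(0)
    pathwayMutatedSamples(profile, genes) / nSamples(profile)
}

#' Marginal coverage gain of a candidate gene (Pf)
#'
#' @param profile a [MutationProfile-class].
#' @param current gene set already in the sub-pathway.
#' @param candidate single gene not yet in `current`.
#' @return non-negative fraction: coverage of `current + candidate` minus
#'   coverage of `current`.
#' @export
marginalGain <- function(profile, current, candidate) {
    current <- .asGenes(current)
    if (candidate %in% current) stop("candidate is already in the set")
    mutationCoverage(profile, c(current, candidate)) -
        (if (length(current)) mutationCoverage(profile, current) else 0)
}

## ---------------------------------------------------------------------------
## Shared greedy engine.
##
## state: an environment the gain/commit closures read and write; snapshot /
## restore make the tentative insertion of a non-gain gene reversible (in
## subtype mode a negative-gain gene does change the covered sets).
##
## gainFun(g): realized gain of adding g to the current state
## commitFun(g): update state as if g were added
## snapshotFun()/restoreFun(s): save / roll back state
## ---------------------------------------------------------------------------
.greedyGrow <- function(adj, candidates, seedGene, gainFun, commitFun,
                        snapshotFun, restoreFun, nonGainBudget = Inf) {
    traceGene <- character(); traceGain <- numeric(); traceClass <- character()
    note <- function(g, gain, cls) {
        traceGene[[length(traceGene) + 1L]] <<- g
        traceGain[[length(traceGain) + 1L]] <<- gain
        traceClass[[length(traceClass) + 1L]] <<- cls
        length(traceGene)
    }
    sub <- character()
    visited <- character()
    seedGain <- gainFun(seedGene)
    commitFun(seedGene)
    sub <- seedGene
    visited <- seedGene
    note(seedGene, seedGain, "seed")
    seeds <- seedGene
    budget <- nonGainBudget

    while (length(seeds)) {
        frontier <- setdiff(unique(unlist(adj[seeds], use.names = FALSE)),
                            visited)
        frontier <- intersect(frontier, candidates)
        if (!length(frontier)) break
        passGain <- vapply(frontier, gainFun, numeric(1L))
        ord <- frontier[order(-passGain, frontier)]
        newSeeds <- character()
        for (g in ord) {
            if (g %in% visited) next
            gain <- gainFun(g)
            if (gain > 0) {
                commitFun(g)
                sub <- c(sub, g); visited <- c(visited, g)
                newSeeds <- c(newSeeds, g)
                note(g, gain, "GI")
            } else {
                visited <- c(visited, g)
                if (budget <= 0) {
                    note(g, gain, "GN-rejected")
                    next
                }
                snap <- snapshotFun()
                commitFun(g)
                idxG <- note(g, gain, "GN-retained")  # provisional
                nbrs <- setdiff(intersect(adj[[g]], candidates), visited)
                rescued <- character()
                if (length(nbrs)) {
                    ng <- vapply(nbrs, gainFun, numeric(1L))
                    for (h in nbrs[order(-ng, nbrs)]) {
                        hg <- gainFun(h)
                        if (hg > 0) {
                            commitFun(h)
                            visited <- c(visited, h)
                            rescued <- c(rescued, h)
                            note(h, hg, "GI")
                        }
                    }
                }
                if (length(rescued)) {
                    sub <- c(sub, g, rescued)
                    newSeeds <- c(newSeeds, rescued)
                    budget <- budget - 1
                } else {
                    restoreFun(snap)
                    traceClass[[idxG]] <- "GN-rejected"
                }
            }
        }
        seeds <- newSeeds
    }
    list(genes = sub,
         trace = data.frame(gene = traceGene, gain = traceGain,
                            class = traceClass, stringsAsFactors = FALSE))
}

## adjacency list of a pathway restricted to one component
.componentAdjacency <- function(pathway, component) {
    adj <- lapply(setNames(nm = component), function(g) character())
    e <- pathwayEdges(pathway)
    if (nrow(e)) {
        keep <- e[, 1L] %in% component & e[, 2L] %in% component
        e <- e[keep, , drop = FALSE]
        for (k in seq_len(nrow(e))) {
            adj[[e[k, 1L]]] <- c(adj[[e[k, 1L]]], e[k, 2L])
            adj[[e[k, 2L]]] <- c(adj[[e[k, 2L]]], e[k, 1L])
        }
    }
    adj
}

## per-gene mutated sample indices restricted to profile
.geneHits <- function(profile, genes) {
    m <- mutationMatrix(profile)
    hits <- lapply(setNames(nm = genes), function(g) integer())
    present <- intersect(genes, geneNames(profile))
    if (length(present)) {
        sm <- m[present, , drop = FALSE]
        tm <- as(sm, "TsparseMatrix")
        hi <- split(tm@j + 1L, factor(tm@i + 1L,
                                      levels = seq_along(present)))
        for (k in seq_along(present)) hits[[present[k]]] <- hi[[k]]
    }
    hits
}

#' Grow a common sub-pathway in one connected component
#'
#' Implements the greedy coverage growth (see the package vignette): seed at
#' the component gene with the highest cohort mutation frequency, expand
#' through direct interaction neighbours in descending marginal-gain order,
#' retaining zero-gain genes only when they bridge to a gain-positive
#' neighbour. The result is emitted only if its coverage reaches
#' `params$coverageThreshold` and it has at least `params$minGenes` genes.
#'
#' @param component character vector of genes (one connected component).
#' @param pathway the source [Pathway-class].
#' @param profile the cohort [MutationProfile-class].
#' @param params a [pathMGParams()] list.
#' @param componentIndex integer index recorded in the result.
#' @return list with `subPathway` (a [SubPathway-class], or `NULL` when the
#'   emission gate fails) and `trace` (the full greedy log, including
#'   rejected genes).
#' @export
growCommonSubPathway <- function(component, pathway, profile, params,
                                 componentIndex = 1L) {
    stopifnot(length(component) >= 1L)
    freq <- setNames(numeric(length(component)), component)
    present <- intersect(component, geneNames(profile))
    if (length(present))
        freq[present] <- mutationFrequency(profile)[present]
    seed <- component[order(-freq, component)][1L]

    N <- nSamples(profile)
    hits <- .geneHits(profile, component)
    covered <- logical(N)
    gainFun <- function(g) sum(!covered[hits[[g]]]) / N
    commitFun <- function(g) covered[hits[[g]]] <<- TRUE
    snapshotFun <- function() covered
    restoreFun <- function(s) covered <<- s

    res <- .greedyGrow(.componentAdjacency(pathway, component), component,
                       seed, gainFun, commitFun, snapshotFun, restoreFun,
                       nonGainBudget = Inf)
    cov <- mutationCoverage(profile, res$genes)  # from-scratch audit
    sp <- NULL
    if (cov >= params$coverageThreshold && length(res$genes) >= params$minGenes)
        sp <- new("SubPathway", pathwayId = pathwayId(pathway),
                  pathwayName = pathwayName(pathway),
                  componentIndex = as.integer(componentIndex),
                  genes = res$genes, coverage = cov, trace = res$trace)
    list(subPathway = sp, trace = res$trace)
}

#' Find all common sub-pathways
#'
#' Runs [growCommonSubPathway()] on every connected component of every
#' supplied pathway (normally the significantly mutated ones), deduplicates
#' identical (pathway, gene set) results and sorts by coverage descending.
#'
#' @param profile the cohort [MutationProfile-class].
#' @param pathways list of [Pathway-class] objects.
#' @param params a [pathMGParams()] list.
#' @return list of [SubPathway-class] objects (possibly empty).
#' @export
findCommonSubPathways <- function(profile, pathways,
                                  params = pathMGParams()) {
    out <- list()
    for (pw in pathways) {
        comps <- pathwayComponents(pw)
        for (ci in seq_along(comps)) {
            r <- growCommonSubPathway(comps[[ci]], pw, profile, params,
                                      componentIndex = ci)
            if (!is.null(r$subPathway))
                out[[length(out) + 1L]] <- r$subPathway
        }
    }
    if (!length(out)) return(out)
    key <- vapply(out, function(s)
        paste(s@pathwayId, paste(sort(s@genes), collapse = ";")), "")
    out <- out[!duplicated(key)]
    out[order(-vapply(out, function(s) s@coverage, 0),
              vapply(out, function(s) s@pathwayId, ""))]
}
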