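## Subtype-specific mutated pathways and sub-pathways. Pathways are first
## screened with a two-sided Fisher exact test on the 2x2 table of
## pathway-mutated status vs subtype (BH-adjusted); within each screened
## pathway, sub-pathways are grown greedily to maximise the coverage
## difference between the two subtypes, separately for each direction using
## only that direction's genes (v > 0 for A, v < 0 for B). Unlike common
## mode, at most one retained gene per sub-pathway may fail to increase the
## coverage difference.

#' Fisher screen for subtype-specific pathways
#'
#' For every pathway, builds the 2x2 table of (mutated, not mutated) x
#' (subtype A, subtype B) sample counts from [pathwayMutatedSamples()] and
#' applies a two-sided Fisher exact test; p-values are BH-adjusted and rows
#' with `q < fdr` are returned.
#'
#' @param profileA,profileB per-subtype [MutationProfile-class] objects
#'   (both non-empty).
#' @param pathways list of [Pathway-class] objects.
#' @param fdr BH-adjusted cutoff (default 0.05); use `fdr > 1` to keep all
#'   rows.
#' @return data.frame: `pathway_id`, `name`, `M_A`, `N_A`, `M_B`, `N_B`,
#'   `p`, `q`, filtered to `q < fdr` and sorted by `q` then `pathway_id`.
#' @export
fisherPathwayScreen <- function(profileA, profileB, pathways, fdr = 0.05) {
    nA <- nSamples(profileA); nB <- nSamples(profileB)
    if (nA == 0L || nB == 0L) stop("both subtypes need at least one sample")
    mA <- vapply(pathways, function(p)
        pathwayMutatedSamples(profileA, pathwayGenes(p)), 0L)
    mB <- vapply(pathways, function(p)
        pathwayMutatedSamples(profileB, pathwayGenes(p)), 0L)
    p <- vapply(seq_along(pathways), function(i)
        stats::fisher.test(matrix(c(mA[i], nA - mA[i], mB[i], nB - mB[i]),
                                  nrow = 2L))$p.value, 0)
    d <- data.frame(pathway_id = vapply(pathways, pathwayId, ""),
                    name = vapply(pathways, pathwayName, ""),
                    M_A = as.integer(mA), N_A = nA,
                    M_B = as.integer(mB), N_B = nB,
                    p = p, q = bhAdjust(p), stringsAsFactors = FALSE)
    d <- d[d$q < fdr, , drop = FALSE]
    d[order(d$q, d$pathway_id), , drop = FALSE]
}

#' Partition component genes by subtype mutation-frequency difference
#'
#' For every gene, computes its mutation frequency within each subtype
#' (`f_a`, `f_b`) and the difference `v = f_a - f_b`. Genes with `v > 0`
#' form the subtype-A-specific set `Ga`, genes with `v < 0` the
#' subtype-B-specific set `Gb`; genes with `v = 0` belong to neither.
#'
#' @param profileA,profileB per-subtype [MutationProfile-class] objects.
#' @param genes character vector of genes (e.g. one component).
#' @return list with named numeric vectors `fa`, `fb`, `v` and character
#'   vectors `Ga`, `Gb`.
#' @export
partitionGenes <- function(profileA, profileB, genes) {
    genes <- .asGenes(genes)
    freqIn <- function(profile) {
        f <- setNames(numeric(length(genes)), genes)
        present <- intersect(genes, geneNames(profile))
        if (length(present))
            f[present] <- mutationFrequency(profile)[present]
        f
    }
    fa <- freqIn(profileA); fb <- freqIn(profileB)
    v <- fa - fb
    list(fa = fa, fb = fb, v = v,
         Ga = genes[v > 0], Gb = genes[v < 0])
}

#' Marginal coverage-difference gain of a candidate gene (Pv)
#'
#' Change in `coverage_A - coverage_B` when `candidate` is added to
#' `current`; may be negative.
#'
#' @param profileA,profileB per-subtype [MutationProfile-class] objects.
#' @param current gene set already in the sub-pathway.
#' @param candidate single gene not in `current`.
#' @return numeric gain.
#' @export
marginalDiffGain <- function(profileA, profileB, current, candidate) {
    current <- .asGenes(current)
    if (candidate %in% current) stop("candidate is already in the set")
    covDiff <- function(genes) {
        if (!length(genes)) return(0)
        mutationCoverage(profileA, genes) - mutationCoverage(profileB, genes)
    }
    covDiff(c(current, candidate)) - covDiff(current)
}

## two-sided Fisher p on sub-pathway mutated status vs subtype
.subPathwayFisher <- function(profileA, profileB, genes) {
    mA <- pathwayMutatedSamples(profileA, genes)
    mB <- pathwayMutatedSamples(profileB, genes)
    stats::fisher.test(matrix(c(mA, nSamples(profileA) - mA,
                                mB, nSamples(profileB) - mB),
                              nrow = 2L))$p.value
}

#' Grow a subtype-specific sub-pathway in one connected component
#'
#' Direction `"A"` grows among the genes with `v > 0`, seeded at the gene
#' with the largest `|v|`, adding direct neighbours (restricted to the same
#' direction set) in descending order of their coverage-difference gain Pv;
#' gain-positive genes become new seeds. At most `params$nonGainBudget`
#' (default one) retained gene in the whole sub-pathway may fail to increase
#' the difference, and only when at least one of its neighbours then yields
#' a positive gain. Direction `"B"` is computed symmetrically with subtype
#' roles swapped. The result is emitted only when the direction-oriented
#' coverage difference reaches `params$diffThreshold` and the two-sided
#' Fisher exact p on the sub-pathway's 2x2 table is below `params$alpha`.
#'
#' @param component character vector of genes (one connected component).
#' @param pathway the source [Pathway-class].
#' @param profileA,profileB per-subtype [MutationProfile-class] objects.
#' @param direction `"A"` or `"B"`.
#' @param params a [pathMGParams()] list.
#' @param componentIndex integer index recorded in the result.
#' @return list with `subPathway` (a [SubtypeSubPathway-class] or `NULL`)
#'   and `trace`. Reported `coverageA`, `coverageB` and `diff` are always in
#'   the original A/B orientation (so B-specific results have negative
#'   `diff`).
#' @export
growSubtypeSubPathway <- function(component, pathway, profileA, profileB,
                                  direction = c("A", "B"),
                                  params = pathMGParams(),
                                  componentIndex = 1L) {
    direction <- match.arg(direction)
    # orient so that "up" is the subtype whose coverage should be higher
    up <- if (direction == "A") profileA else profileB
    dn <- if (direction == "A") profileB else profileA

    part <- partitionGenes(up, dn, component)
    cand <- part$Ga            # v > 0 in the oriented frame
    if (!length(cand)) return(list(subPathway = NULL, trace = NULL))
    seed <- cand[order(-part$v[cand], cand)][1L]

    nUp <- nSamples(up); nDn <- nSamples(dn)
    hitsUp <- .geneHits(up, component)
    hitsDn <- .geneHits(dn, component)
    coveredUp <- logical(nUp); coveredDn <- logical(nDn)
    gainFun <- function(g)
        sum(!coveredUp[hitsUp[[g]]]) / nUp - sum(!coveredDn[hitsDn[[g]]]) / nDn
    commitFun <- function(g) {
        coveredUp[hitsUp[[g]]] <<- TRUE
        coveredDn[hitsDn[[g]]] <<- TRUE
    }
    snapshotFun <- function() list(up = coveredUp, dn = coveredDn)
    restoreFun <- function(s) {
        coveredUp <<- s$up
        coveredDn <<- s$dn
    }

    res <- .greedyGrow(.componentAdjacency(pathway, component), cand, seed,
                       gainFun, commitFun, snapshotFun, restoreFun,
                       nonGainBudget = params$nonGainBudget)

    covA <- mutationCoverage(profileA, res$genes)   # from-scratch audit
    covB <- mutationCoverage(profileB, res$genes)
    orientedDiff <- if (direction == "A") covA - covB else covB - covA
    fp <- .subPathwayFisher(profileA, profileB, res$genes)
    sp <- NULL
    if (orientedDiff >= params$diffThreshold && fp < params$alpha)
        sp <- new("SubtypeSubPathway", pathwayId = pathwayId(pathway),
                  pathwayName = pathwayName(pathway),
                  componentIndex = as.integer(componentIndex),
                  direction = paste0(direction, "-specific"),
                  genes = res$genes, coverageA = covA, coverageB = covB,
                  diff = covA - covB, fisherP = fp, trace = res$trace)
    list(subPathway = sp, trace = res$trace)
}

#' Find all subtype-specific sub-pathways
#'
#' Runs [growSubtypeSubPathway()] in both directions on every connected
#' component of every supplied pathway (normally the ones retained by
#' [fisherPathwayScreen()]), deduplicates identical (pathway, direction,
#' gene set) results and sorts by `|diff|` descending.
#'
#' @param profileA,profileB per-subtype [MutationProfile-class] objects.
#' @param pathways list of [Pathway-class] objects.
#' @param params a [pathMGParams()] list.
#' @return list of [SubtypeSubPathway-class] objects (possibly empty).
#' @export
findSubtypeSubPathways <- function(profileA, profileB, pathways,
                                   params = pathMGParams()) {
    out <- list()
    for (pw in pathways) {
        comps <- pathwayComponents(pw)
        for (ci in seq_along(comps)) {
            for (dir in c("A", "B")) {
                r <- growSubtypeSubPathway(comps[[ci]], pw, profileA,
                                           profileB, direction = dir,
                                           params = params,
                                           componentIndex = ci)
                if (!is.null(r$subPathway))
                    out[[length(out) + 1L]] <- r$subPathway
            }
        }
    }
    if (!length(out)) return(out)
    key <- vapply(out, function(s)
        paste(s@pathwayId, s@direction,
              paste(sort(s@genes), collapse = ";")), "")
    out <- out[!duplicated(key)]
    out[order(-abs(vapply(out, function(s) s@diff, 0)),
              vapply(out, function(s) s@pathwayId, ""))]
}
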