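# Fixture builders and independent oracles used across the suite.

# Profile from a list mapping gene -> mutated sample indices, over N samples.
makeProfile <- function(hits, N, samples = sprintf("s%d", seq_len(N))) {
    genes <- names(hits)
    m <- matrix(0, length(genes), N, dimnames = list(genes, samples))
    for (g in genes) m[g, hits[[g]]] <- 1
    MutationProfile(m)
}

# Union-find connected components, independent of igraph.
ufComponents <- function(genes, edges) {
    parent <- stats::setNames(genes, genes)
    find <- function(x) {
        while (parent[[x]] != x) {
            parent[[x]] <<- parent[[parent[[x]]]]
            x <- parent[[x]]
        }
        x
    }
    if (NROW(edges)) for (k in seq_len(nrow(edges))) {
        ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
        if (ra != rb) parent[[ra]] <- rb
    }
    roots <- vapply(genes, find, "")
    unname(lapply(split(genes, roots), sort))
}

# Coverage by explicit per-sample enumeration.
coverageOracle <- function(profile, genes) {
    m <- as.matrix(mutationMatrix(profile))
    genes <- intersect(genes, rownames(m))
    if (!length(genes)) return(0)
    mean(vapply(seq_len(ncol(m)), function(s)
        any(m[genes, s] == 1), TRUE))
}

# Adjacency list of a pathway restricted to a gene set.
adjacencyOf <- function(pathway, genes) {
    e <- pathwayEdges(pathway)
    adj <- stats::setNames(rep(list(character()), length(genes)), genes)
    if (nrow(e)) for (k in seq_len(nrow(e))) {
        a <- e[k, 1]; b <- e[k, 2]
        if (a %in% genes && b %in% genes) {
            adj[[a]] <- c(adj[[a]], b)
            adj[[b]] <- c(adj[[b]], a)
        }
    }
    adj
}

# Is a gene set connected in the pathway graph? (BFS, independent of igraph)
isConnectedSet <- function(pathway, genes) {
    if (length(genes) <= 1L) return(TRUE)
    adj <- adjacencyOf(pathway, genes)
    seen <- genes[1L]
    repeat {
        nxt <- setdiff(unique(unlist(adj[seen])), seen)
        if (!length(nxt)) break
        seen <- c(seen, nxt)
    }
    setequal(seen, genes)
}

# Maximum of evalFun over every connected subgraph of a small component.
# evalFun takes a character vector of genes.
maxOverConnectedSubgraphs <- function(pathway, component, evalFun) {
    m <- length(component)
    stopifnot(m <= 14L)
    best <- -Inf
    for (mask in seq_len(2^m - 1L)) {
        sel <- component[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0]
        if (isConnectedSet(pathway, sel)) {
            v <- evalFun(sel)
            if (v > best) best <- v
        }
    }
    best
}

# A pathway whose first `plantSize` genes form a connected planted set:
# random connected host graph (spanning tree + extra random edges).
plantedPathway <- function(id, genes, extraEdgeProb = 0.3) {
    n <- length(genes)
    edges <- NULL
    for (i in 2:n)  # attach each gene to a random earlier one: connected
        edges <- rbind(edges, c(genes[sample.int(i - 1L, 1L)], genes[i]))
    for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (stats::runif(1) < extraEdgeProb)
            edges <- rbind(edges, c(genes[i], genes[j]))
    Pathway(id, genes = genes, edges = edges)
}

# Structural audit shared by several tests: every emitted sub-pathway must
# induce a connected subgraph, report statistics that match a from-scratch
# recomputation, and respect its emission gates.
checkCommonInvariants <- function(sub, pathway, profile, params) {
    expect_true(isConnectedSet(pathway, memberGenes(sub)))
    expect_equal(sub@coverage, coverageOracle(profile, memberGenes(sub)))
    expect_gte(sub@coverage, params$coverageThreshold)
    expect_gte(length(memberGenes(sub)), params$minGenes)
    tr <- greedyTrace(sub)
    retained <- tr[tr$class %in% c("seed", "GI", "GN-retained"), ]
    expect_equal(sum(retained$gain), sub@coverage, tolerance = 1e-12)
    expect_setequal(retained$gene, memberGenes(sub))
}

checkSubtypeInvariants <- function(sub, pathway, profileA, profileB, params) {
    expect_true(isConnectedSet(pathway, memberGenes(sub)))
    covA <- coverageOracle(profileA, memberGenes(sub))
    covB <- coverageOracle(profileB, memberGenes(sub))
    expect_equal(sub@coverageA, covA)
    expect_equal(sub@coverageB, covB)
    expect_equal(sub@diff, covA - covB)
    expect_gte(abs(sub@diff), params$diffThreshold)
    expect_lt(sub@fisherP, params$alpha)
    tr <- greedyTrace(sub)
    expect_lte(sum(tr$class == "GN-retained"), params$nonGainBudget)
}
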