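# Greedy common sub-pathway extraction: component decomposition, marginal
# gains, the GI/GN growth loop with zero-gain rescue, and emission gates.

test_that("pathway components match a union-find oracle", {
    pw <- Pathway("P1", genes = c("a", "b", "c", "d"),
                  edges = rbind(c("a", "b"), c("b", "c")))
    comps <- pathwayComponents(pw)
    expect_length(comps, 2L)
    expect_setequal(comps[[1L]], c("a", "b", "c"))
    expect_equal(unname(comps[[2L]]), "d")

    lone <- Pathway("P2", genes = sprintf("g%d", 1:5))
    expect_length(pathwayComponents(lone), 5L)

    set.seed(17)
    for (rep in 1:10) {
        genes <- sprintf("n%02d", 1:30)
        ne <- sample(10:40, 1)
        edges <- cbind(sample(genes, ne, replace = TRUE),
                       sample(genes, ne, replace = TRUE))
        edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
        pw <- Pathway("R", genes = genes, edges = edges)
        got <- lapply(pathwayComponents(pw), function(x) sort(unname(x)))
        want <- ufComponents(genes, pathwayEdges(pw))
        expect_setequal(lapply(got, paste, collapse = ","),
                        lapply(want, paste, collapse = ","))
    }
})

test_that("coverage and marginal gain match explicit enumeration", {
    prof <- makeProfile(list(g1 = 1:2, g2 = 2:3, g3 = integer()), 5)
    expect_equal(mutationCoverage(prof, c("g1", "g2")), 0.6)
    expect_equal(mutationCoverage(prof, character()), 0)
    expect_equal(mutationCoverage(prof, "g3"), 0)

    # candidate covering only already-covered samples gains nothing
    expect_equal(marginalGain(prof, "g1", "g3"), 0)
    prof2 <- makeProfile(list(a = 1, b = 2:3), 4)
    expect_equal(marginalGain(prof2, "a", "b"), 0.5)
    expect_error(marginalGain(prof2, c("a", "b"), "b"), "already in")

    # against the per-sample enumeration oracle on random sets
    set.seed(29)
    rp <- makeProfile(setNames(lapply(1:10, function(i)
        sample.int(15, sample.int(5, 1))), letters[1:10]), 15)
    for (rep in 1:20) {
        gs <- sample(letters[1:10], sample.int(6, 1))
        expect_equal(mutationCoverage(rp, gs), coverageOracle(rp, gs))
    }
})

test_that("a path-graph component is grown in descending-gain order", {
    # g1 covers {1,2}, g2 {3}, g3 {4,5}; seed ties on f broken
    # lexicographically to g1, then g2 (+0.2) and g3 (+0.4) both gain
    prof <- makeProfile(list(g1 = 1:2, g2 = 3, g3 = 4:5), 5)
    pw <- Pathway("P", genes = c("g1", "g2", "g3"),
                  edges = rbind(c("g1", "g2"), c("g2", "g3")))
    params <- pathMGParams(coverageThreshold = 0.9, minGenes = 3)
    r <- growCommonSubPathway(c("g1", "g2", "g3"), pw, prof, params)
    expect_s4_class(r$subPathway, "SubPathway")
    expect_equal(memberGenes(r$subPathway), c("g1", "g2", "g3"))
    expect_equal(r$subPathway@coverage, 1.0)
    expect_equal(r$trace$class, c("seed", "GI", "GI"))
    expect_equal(r$trace$gain, c(0.4, 0.2, 0.4))
})

test_that("a zero-gain gene is retained when it bridges to new coverage", {
    # g2 adds nothing on top of g1 but connects to g3, which covers the
    # remaining samples: g2 must be kept (GN rescue) and g3 seeded
    prof <- makeProfile(list(g1 = 1:8, g2 = 1:2, g3 = 9:10), 10)
    pw <- Pathway("P", genes = c("g1", "g2", "g3"),
                  edges = rbind(c("g1", "g2"), c("g2", "g3")))
    params <- pathMGParams(coverageThreshold = 0.9, minGenes = 3)
    r <- growCommonSubPathway(c("g1", "g2", "g3"), pw, prof, params)
    expect_equal(sort(memberGenes(r$subPathway)), c("g1", "g2", "g3"))
    expect_equal(r$subPathway@coverage, 1.0)
    tr <- r$trace
    expect_equal(tr$class[tr$gene == "g2"], "GN-retained")
    expect_equal(tr$class[tr$gene == "g3"], "GI")
})

test_that("a zero-gain gene without gainful neighbours is excluded", {
    prof <- makeProfile(list(g1 = 1:8, g2 = 1:2, g3 = 1:3), 10)
    pw <- Pathway("P", genes = c("g1", "g2", "g3"),
                  edges = rbind(c("g1", "g2"), c("g2", "g3")))
    params <- pathMGParams(coverageThreshold = 0.5, minGenes = 1)
    r <- growCommonSubPathway(c("g1", "g2", "g3"), pw, prof, params)
    expect_equal(memberGenes(r$subPathway), "g1")
    expect_true(all(r$trace$class[r$trace$gene %in% c("g2")] ==
                    "GN-rejected"))
})

test_that("emission gates on coverage and gene count are enforced", {
    prof <- makeProfile(list(g1 = 1:10), 10)
    pw <- Pathway("P", genes = "g1")
    r1 <- growCommonSubPathway("g1", pw, prof,
                               pathMGParams(minGenes = 1))
    expect_equal(memberGenes(r1$subPathway), "g1")
    expect_equal(r1$subPathway@coverage, 1.0)
    r5 <- growCommonSubPathway("g1", pw, prof, pathMGParams())  # minGenes 5
    expect_null(r5$subPathway)

    lowProf <- makeProfile(list(g1 = 1:5), 10)   # coverage 0.5 < 0.9
    rl <- growCommonSubPathway("g1", pw, lowProf,
                               pathMGParams(minGenes = 1))
    expect_null(rl$subPathway)
})

test_that("planted connected signals are recovered with default settings", {
    sc <- syntheticScenario(nSamples = 200, nBackgroundGenes = 300,
                            pathwaySizes = 12L, edgeDensity = 0.5,
                            mutationMean = 15, seed = 31)
    db <- generatePathwayDB(sc)
    planted <- pathMG:::.largestComponentGenes(db$pathways[[1L]], 6L)
    prof <- plantCommonSignal(simulateCohort(sc), planted, 0.95, seed = 32)
    subs <- findCommonSubPathways(prof, db$pathways[1L], pathMGParams())
    expect_gte(length(subs), 1L)
    expect_true(all(planted %in% memberGenes(subs[[1L]])))
    expect_gte(subs[[1L]]@coverage, 0.90)
    checkCommonInvariants(subs[[1L]], db$pathways[[1L]], prof,
                          pathMGParams())
})

test_that("pathways sharing gene content are reported per pathway", {
    prof <- makeProfile(list(g1 = 1:2, g2 = 3, g3 = 4:5), 5)
    e <- rbind(c("g1", "g2"), c("g2", "g3"))
    pws <- list(Pathway("P1", genes = c("g1", "g2", "g3"), edges = e),
                Pathway("P2", genes = c("g1", "g2", "g3"), edges = e))
    params <- pathMGParams(coverageThreshold = 0.9, minGenes = 3)
    subs <- findCommonSubPathways(prof, pws, params)
    expect_length(subs, 2L)
    expect_setequal(vapply(subs, pathwayId, ""), c("P1", "P2"))
    # and nothing is emitted when no component reaches the threshold
    noisy <- makeProfile(list(g1 = 1, g2 = 1, g3 = 1), 5)
    expect_length(findCommonSubPathways(noisy, pws, params), 0L)
})
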