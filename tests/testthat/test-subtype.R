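# Subtype-specific pathways and sub-pathways: Fisher screen, gene
# partitioning by frequency difference, Pv gains, the single non-gain-gene
# budget, direction symmetry and emission gates.

test_that("the Fisher pathway screen matches closed forms and symmetry", {
    # equal mutation proportions in equal subtypes: no association
    A <- makeProfile(list(g1 = 1:5), 10)
    B <- makeProfile(list(g1 = 1:5), 10)
    pw <- Pathway("P", genes = "g1")
    sEq <- fisherPathwayScreen(A, B, list(pw), fdr = 2)
    expect_equal(sEq$p, 1)

    # [[10,0],[0,10]]: p = 2 / C(20,10), a closed-form hypergeometric sum
    Aall <- makeProfile(list(g1 = 1:10), 10)
    Bnone <- makeProfile(list(g1 = integer()), 10)
    sX <- fisherPathwayScreen(Aall, Bnone, list(pw), fdr = 2)
    expect_equal(sX$p, 2 / choose(20, 10), tolerance = 1e-12)

    # two-sided p is invariant under swapping the subtype labels
    A2 <- makeProfile(list(g1 = 1:7), 12)
    B2 <- makeProfile(list(g1 = 1:2), 9)
    expect_equal(fisherPathwayScreen(A2, B2, list(pw), fdr = 2)$p,
                 fisherPathwayScreen(B2, A2, list(pw), fdr = 2)$p)

    expect_error(fisherPathwayScreen(A, B[, integer(0)], list(pw)),
                 "at least one sample")
})

test_that("genes partition by the sign of their frequency difference", {
    A <- makeProfile(list(up = 1:6, down = 1, flat = 1:3), 10)
    B <- makeProfile(list(up = 1, down = 1:6, flat = 1:3), 10)
    part <- partitionGenes(A, B, c("up", "down", "flat"))
    expect_equal(unname(part$v["up"]), 0.5)
    expect_equal(part$Ga, "up")
    expect_equal(part$Gb, "down")
    expect_false("flat" %in% c(part$Ga, part$Gb))  # v = 0: neither set

    # brute-force frequency recomputation on a random profile
    set.seed(41)
    genes <- letters[1:8]
    A2 <- makeProfile(setNames(lapply(genes, function(g)
        sample.int(12, sample.int(6, 1))), genes), 12)
    B2 <- makeProfile(setNames(lapply(genes, function(g)
        sample.int(9, sample.int(6, 1))), genes), 9)
    part2 <- partitionGenes(A2, B2, genes)
    for (g in genes) {
        fa <- mean(as.matrix(mutationMatrix(A2))[g, ])
        fb <- mean(as.matrix(mutationMatrix(B2))[g, ])
        expect_equal(unname(part2$v[g]), fa - fb)
        expect_equal(g %in% part2$Ga, fa > fb)
        expect_equal(g %in% part2$Gb, fa < fb)
    }
})

test_that("Pv is the change in coverage difference and may be negative", {
    A <- makeProfile(list(cur = 1, cand = 2:3, none = integer()), 10)
    B <- makeProfile(list(cur = 1, cand = 2, none = integer()), 10)
    expect_equal(marginalDiffGain(A, B, "cur", "cand"), 0.2 - 0.1)
    expect_equal(marginalDiffGain(A, B, "cur", "none"), 0)
    Bheavy <- makeProfile(list(cur = 1, cand = 2:5, none = integer()), 10)
    expect_lt(marginalDiffGain(A, Bheavy, "cur", "cand"), 0)
    expect_error(marginalDiffGain(A, B, "cur", "cur"), "already in")
})

test_that("at most one retained gene may fail to increase the difference", {
    # chain g1-g2-g3-g4-g5: g2 and g4 are zero-gain bridges; only the
    # first can spend the budget, so growth stops before g4/g5
    A <- makeProfile(list(g1 = 1:3, g2 = 1, g3 = 4:5, g4 = 4, g5 = 6:7), 10)
    B <- makeProfile(list(g1 = integer(), g2 = integer(), g3 = integer(),
                          g4 = integer(), g5 = integer()), 10)
    pw <- Pathway("P", genes = sprintf("g%d", 1:5),
                  edges = cbind(sprintf("g%d", 1:4), sprintf("g%d", 2:5)))
    params <- pathMGParams(diffThreshold = 0.25)
    r <- growSubtypeSubPathway(sprintf("g%d", 1:5), pw, A, B,
                               direction = "A", params = params)
    expect_equal(sort(memberGenes(r$subPathway)), c("g1", "g2", "g3"))
    expect_equal(sum(r$trace$class == "GN-retained"), 1L)
    expect_true(any(r$trace$gene == "g4" &
                    r$trace$class == "GN-rejected"))
    # with a larger budget the second bridge is usable too
    r2 <- growSubtypeSubPathway(sprintf("g%d", 1:5), pw, A, B,
                                direction = "A",
                                params = pathMGParams(nonGainBudget = 2))
    expect_equal(sort(memberGenes(r2$subPathway)), sprintf("g%d", 1:5))
})

test_that("direction B grows symmetrically and reports a negative diff", {
    A <- makeProfile(list(g1 = 1, g2 = integer()), 10)
    B <- makeProfile(list(g1 = 1:6, g2 = 7:8), 10)
    pw <- Pathway("P", genes = c("g1", "g2"), edges = rbind(c("g1", "g2")))
    params <- pathMGParams(diffThreshold = 0.25)
    rB <- growSubtypeSubPathway(c("g1", "g2"), pw, A, B,
                                direction = "B", params = params)
    expect_s4_class(rB$subPathway, "SubtypeSubPathway")
    expect_equal(rB$subPathway@direction, "B-specific")
    expect_lt(rB$subPathway@diff, 0)
    # swapping the profiles mirrors the result into direction A
    rA <- growSubtypeSubPathway(c("g1", "g2"), pw, B, A,
                                direction = "A", params = params)
    expect_equal(sort(memberGenes(rA$subPathway)),
                 sort(memberGenes(rB$subPathway)))
    expect_equal(rA$subPathway@diff, -rB$subPathway@diff)
    expect_equal(rA$subPathway@fisherP, rB$subPathway@fisherP)
})

test_that("components with no direction-specific genes yield nothing", {
    A <- makeProfile(list(g1 = 1:3), 10)
    B <- makeProfile(list(g1 = 1:3), 10)
    pw <- Pathway("P", genes = "g1")
    r <- growSubtypeSubPathway("g1", pw, A, B, direction = "A",
                               params = pathMGParams())
    expect_null(r$subPathway)
})

test_that("planted subtype signals are recovered and label-swap mirrors", {
    sc <- syntheticScenario(nSamples = 400, nBackgroundGenes = 300,
                            pathwaySizes = 12L, edgeDensity = 0.5,
                            mutationMean = 15, seed = 51)
    db <- generatePathwayDB(sc)
    planted <- pathMG:::.largestComponentGenes(db$pathways[[1L]], 6L)
    noise <- simulateCohort(sc)
    pl <- plantSubtypeSignal(noise[, 1:200], noise[, 201:400], planted,
                             targetDiff = 0.4, seed = 52)
    params <- pathMGParams()
    subs <- findSubtypeSubPathways(pl$A, pl$B, db$pathways[1L], params)
    expect_gte(length(subs), 1L)
    top <- subs[[1L]]
    expect_equal(top@direction, "A-specific")
    expect_gte(top@diff, 0.25)
    expect_lt(top@fisherP, 0.05)
    checkSubtypeInvariants(top, db$pathways[[1L]], pl$A, pl$B, params)

    swapped <- findSubtypeSubPathways(pl$B, pl$A, db$pathways[1L], params)
    expect_equal(swapped[[1L]]@direction, "B-specific")
    expect_equal(swapped[[1L]]@diff, -top@diff)
    expect_setequal(memberGenes(swapped[[1L]]), memberGenes(top))

    # identical subtype profiles produce no results at all
    expect_length(findSubtypeSubPathways(pl$A, pl$A, db$pathways[1L],
                                         params), 0L)
})
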