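test_that("components match hand-derived values on frozen examples", {
    # points on the 45-degree line give t = 0 exactly
    pe <- makePE(matrix(c(2, 7), 1, 2), matrix(c(2, 7), 1, 2))
    expect_identical(computeComponents(pe, logTransform = FALSE)$t, 0)

    # degenerate cloud: all pairs at (3,4) -> v = 0, s = 5, t = 1/sqrt(2)
    pe <- makePE(matrix(3, 1, 4), matrix(4, 1, 4))
    cs <- computeComponents(pe, logTransform = FALSE)
    expect_identical(cs$v, 0)
    expect_equal(cs$s, 5, tolerance = 1e-15)
    expect_equal(cs$t, 1 / sqrt(2), tolerance = 1e-15)

    # pairs (1,3), (2,4), (3,5): centroid (2,4), t = sqrt(2), s = sqrt(20),
    # v = sqrt(4/3)
    pe <- makePE(matrix(c(1, 2, 3), 1, 3), matrix(c(3, 4, 5), 1, 3))
    cs <- computeComponents(pe, logTransform = FALSE)
    expect_equal(cs$cx, 2, tolerance = 1e-15)
    expect_equal(cs$cy, 4, tolerance = 1e-15)
    expect_equal(cs$t, 2 / sqrt(2), tolerance = 1e-12)
    expect_equal(cs$s, sqrt(20), tolerance = 1e-12)
    expect_equal(cs$v, sqrt(4 / 3), tolerance = 1e-12)
})

test_that("log-transform of linear data requires a positive pseudocount", {
    pe <- randomPE(4, 3, seed = 2, scaleHint = "linear")
    expect_error(computeComponents(pe, logTransform = TRUE, pseudocount = 0),
                 "positive pseudocount")
    expect_silent(computeComponents(pe, logTransform = TRUE, pseudocount = 1))
    # log-scale input ignores the transform request
    pel <- randomPE(4, 3, seed = 2, scaleHint = "log")
    expect_identical(computeComponents(pel, TRUE, 1), computeComponents(pel, FALSE, 1))
})

test_that("score combination follows the rank conventions", {
    # equal temporal change and signal: the lower-variance gene wins
    cs <- S4Vectors::DataFrame(v = c(1, 2), s = c(10, 10), t = c(5, 5),
                               row.names = c("A", "B"))
    st <- combineScores(cs)
    expect_lt(st["A", "score"], st["B", "score"])

    # full tie: every score is (N+1)/2 and a warning is emitted
    cs <- S4Vectors::DataFrame(v = rep(1, 4), s = rep(2, 4), t = rep(-3, 4),
                               row.names = paste0("g", 1:4))
    expect_warning(st <- combineScores(cs), "identical in all three components")
    expect_equal(st$score, rep(2.5, 4), tolerance = 1e-15)

    # rank cycle (1,2,3),(2,3,1),(3,1,2): all combined scores equal 2
    cs <- S4Vectors::DataFrame(v = c(1, 2, 3), s = c(5, 1, 9), t = c(1, 9, 5),
                               row.names = c("x", "y", "z"))
    st <- combineScores(cs)
    expect_identical(st$rank_v, c(1, 2, 3))
    expect_identical(st$rank_s, c(2, 3, 1))
    expect_identical(st$rank_t, c(3, 1, 2))
    expect_equal(st$score, rep(2, 3), tolerance = 1e-15)

    # direction from the sign of t; flat only at exactly zero
    cs <- S4Vectors::DataFrame(v = c(1, 1, 1), s = c(1, 1, 1),
                               t = c(2, -0.5, 0), row.names = c("u", "d", "f"))
    expect_identical(combineScores(cs)$direction, c("up", "down", "flat"))

    expect_error(combineScores(cs[1, ]), "at least 2 features")
    expect_error(combineScores(cs, weights = c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("SD selection matches hand computation and degenerate rules", {
    st <- S4Vectors::DataFrame(score = c(1, 2, 3, 4, 5),
                               row.names = paste0("f", 1:5))
    sel <- sdSelect(st, kSd = 1)
    expect_equal(sel$z_sd, (0:4) / sqrt(2.5), tolerance = 1e-12)
    expect_identical(sel$selected, c(TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_equal(S4Vectors::metadata(sel)$fraction_selected, 0.4)

    # all scores identical: everything selected, z = 0, warning
    st <- S4Vectors::DataFrame(score = c(5, 5, 5), row.names = paste0("f", 1:3))
    expect_warning(sel <- sdSelect(st), "SD = 0")
    expect_identical(sel$z_sd, c(0, 0, 0))
    expect_true(all(sel$selected))

    # the minimal-score feature is always selected, for any k
    for (seed in 1:25) {
        sc <- withr::with_seed(seed, rnorm(50))
        sel <- sdSelect(S4Vectors::DataFrame(score = sc), kSd = 0)
        expect_true(sel$selected[which.min(sc)])
        expect_true(all(sel$z_sd >= 0))
    }
})

test_that("component contributions follow the inverse-rank rule", {
    # equal ranks on all three components -> exactly (1/3, 1/3, 1/3)
    cs <- S4Vectors::DataFrame(v = c(1, 2, 3), s = c(3, 2, 1), t = c(3, 2, 1),
                               row.names = c("a", "b", "c"))
    cc <- componentContribution(cs, "b")
    expect_identical(cc$pct_v, 1 / 3)
    expect_identical(cc$pct_s, 1 / 3)
    expect_identical(cc$pct_t, 1 / 3)

    # single feature: ranks (1,1,1) -> (1/3, 1/3, 1/3)
    cs1 <- S4Vectors::DataFrame(v = 2, s = 5, t = -1, row.names = "only")
    expect_identical(unname(as.matrix(componentContribution(cs1)[, 1:3])[1, ]),
                     rep(1 / 3, 3))

    # N = 10, ranks (1, 10, 10) -> invranks (10, 1, 1) -> (10/12, 1/12, 1/12)
    cs <- S4Vectors::DataFrame(v = c(0.1, 2:10), s = c(1, 11:19),
                               t = c(0.01, 2:10), row.names = paste0("g", 1:10))
    cc <- componentContribution(cs, "g1")
    expect_equal(unname(as.matrix(cc[, 1:3])[1, ]), c(10, 1, 1) / 12,
                 tolerance = 1e-15)

    # rows always sum to 1
    cs <- S4Vectors::DataFrame(v = runif(30), s = runif(30), t = rnorm(30),
                               row.names = paste0("r", 1:30))
    cc <- componentContribution(cs)
    expect_equal(cc$pct_v + cc$pct_s + cc$pct_t, rep(1, 30), tolerance = 1e-12)

    expect_error(componentContribution(cs, "absent"), "absent")
    expect_error(componentContribution(cs[0, ]), "no features")
})

test_that("early/late swap negates t and preserves v, s, ranks and scores", {
    for (seed in 1:40) {
        pe <- randomPE(12, 5, seed = seed)
        swapped <- PairedExperiment(lateAssay(pe), earlyAssay(pe),
                                    subject = subjectIds(pe),
                                    ageEarly = ageEarly(pe), ageLate = ageLate(pe),
                                    scaleHint = "log")
        a <- combineScores(computeComponents(pe, FALSE))
        b <- combineScores(computeComponents(swapped, FALSE))
        expect_equal(b$t, -a$t, tolerance = 1e-12)
        expect_equal(b$v, a$v, tolerance = 1e-12)
        expect_equal(b$s, a$s, tolerance = 1e-12)
        expect_identical(b$rank_v, a$rank_v)
        expect_identical(b$rank_s, a$rank_s)
        expect_identical(b$rank_t, a$rank_t)
        expect_equal(b$score, a$score, tolerance = 1e-12)
    }
})

test_that("linear intensity scaling scales v, s, |t| and preserves ranks", {
    for (seed in 1:40) {
        k <- withr::with_seed(seed, runif(1, 0.2, 8))
        pe <- randomPE(10, 4, seed = seed, scaleHint = "linear")
        peK <- PairedExperiment(earlyAssay(pe) * k, lateAssay(pe) * k,
                                subject = subjectIds(pe),
                                ageEarly = ageEarly(pe), ageLate = ageLate(pe),
                                scaleHint = "linear")
        a <- computeComponents(pe, logTransform = FALSE)
        b <- computeComponents(peK, logTransform = FALSE)
        expect_equal(b$v, k * a$v, tolerance = 1e-12)
        expect_equal(b$s, k * a$s, tolerance = 1e-12)
        expect_equal(b$t, k * a$t, tolerance = 1e-12)
        sa <- sdSelect(combineScores(a))
        sb <- sdSelect(combineScores(b))
        expect_equal(sa$score, sb$score, tolerance = 1e-12)
        expect_identical(sa$selected, sb$selected)
        expect_equal(as.matrix(componentContribution(a)[, 1:3]),
                     as.matrix(componentContribution(b)[, 1:3]),
                     tolerance = 1e-12)
    }
})

test_that("|t| never exceeds s and scores match the brute-force oracle", {
    for (seed in 1:50) {
        nf <- withr::with_seed(seed, sample(2:8, 1))
        np <- withr::with_seed(seed + 100, sample(2:4, 1))
        pe <- randomPE(nf, np, seed = seed)
        cs <- computeComponents(pe, logTransform = FALSE)
        expect_true(all(abs(cs$t) <= cs$s + 1e-12))
        ora <- oracleComponents(earlyAssay(pe), lateAssay(pe))
        expect_equal(cs$v, ora$v, tolerance = 1e-12)
        expect_equal(cs$s, ora$s, tolerance = 1e-12)
        expect_equal(cs$t, ora$t, tolerance = 1e-12)
        expect_equal(combineScores(cs)$score, oracleCombine(cs$v, cs$s, cs$t),
                     tolerance = 1e-12)
    }
})

test_that("improving one component rank never worsens the combined score", {
    for (seed in 1:30) {
        cs <- withr::with_seed(seed, S4Vectors::DataFrame(
            v = runif(15), s = runif(15), t = rnorm(15),
            row.names = paste0("g", 1:15)))
        st0 <- combineScores(cs)
        i <- withr::with_seed(seed, sample(15, 1))
        cs2 <- cs
        cs2$v[i] <- min(cs$v) - 1e-3        # strictly best variance rank
        st1 <- combineScores(cs2)
        expect_lte(st1$score[i], st0$score[i] + 1e-12)
    }
})

test_that("shuffled control is seeded, value-conserving, and kills temporal signal", {
    sim <- simulatePairedExpression(simulationConfig(
        nGenes = 1000L, nPairs = 10L,
        plantedSets = list(list(name = "down", nGenes = 50L, effect = -1)),
        noiseSd = 0.25, seed = 42))
    pe <- sim$pe
    expect_identical(earlyAssay(shuffledControl(pe, 7)),
                     earlyAssay(shuffledControl(pe, 7)))
    sh <- shuffledControl(pe, 7)
    expect_equal(sort(c(earlyAssay(sh), lateAssay(sh))),
                 sort(c(earlyAssay(pe), lateAssay(pe))), tolerance = 0)

    st <- scorePairedExperiment(pe)
    top <- rownames(st)[order(st$score)][1:200]
    meanAbsT <- mean(abs(st[top, "t"]))
    shuffledMeans <- vapply(1:200, function(s) {
        stS <- scorePairedExperiment(shuffledControl(pe, s))
        topS <- rownames(stS)[order(stS$score)][1:200]
        mean(abs(stS[topS, "t"]))
    }, numeric(1))
    expect_lt(mean(shuffledMeans), meanAbsT)
})

test_that("transcript-to-gene collapse keeps the right representative", {
    st <- S4Vectors::DataFrame(
        v = c(1, 1, 1), s = c(1, 1, 1), t = c(0.2, -0.9, 0.5),
        score = c(4, 7, 2),
        row.names = c("tx1", "tx2", "tx9"))
    map <- data.frame(transcript = c("tx1", "tx2", "tx9"),
                      gene = c("GENE1", "GENE1", "GENE2"))
    byScore <- collapseToGenes(st, map, mode = "min_score")
    expect_identical(byScore["GENE1", "transcript"], "tx1")
    byT <- collapseToGenes(st, map, mode = "max_abs_t")
    expect_identical(byT["GENE1", "transcript"], "tx2")
    expect_identical(rownames(byScore), c("GENE1", "GENE2"))

    # criterion ties break lexicographically by transcript id
    st2 <- S4Vectors::DataFrame(v = c(1, 1), s = c(1, 1), t = c(0.3, 0.3),
                                score = c(5, 5), row.names = c("txB", "txA"))
    map2 <- data.frame(transcript = c("txA", "txB"), gene = c("G", "G"))
    expect_identical(collapseToGenes(st2, map2, "min_score")["G", "transcript"],
                     "txA")

    # unmapped transcripts dropped with a reported count
    map3 <- data.frame(transcript = "tx1", gene = "GENE1")
    expect_message(res <- collapseToGenes(st, map3), "2 unmapped")
    expect_identical(nrow(res), 1L)
    expect_identical(S4Vectors::metadata(res)$n_unmapped, 2L)
    expect_error(collapseToGenes(st, map3[0, ]), "empty")
})
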