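test_that("hypergeometric tails reproduce the worked urn and its identities", {
    labs <- setNames(rep(c("X", "Y"), c(8, 12)), sprintf("c%02d", 1:20))
    tgt <- sprintf("c%02d", c(1, 9:17))     # 10 target cells, 1 in cluster X
    bg <- setdiff(names(labs), tgt)
    et <- hypergeomClusterTest(tgt, bg, labs, "X")
    expect_equal(et$p_deplete, 1826 / 184756, tolerance = 1e-12)
    expect_equal(et$p_enrich + et$p_deplete - dhyper(et$k, et$K, et$N - et$K, et$n),
                 1, tolerance = 1e-12)

    # forced distribution: every urn cell in the cluster
    labs2 <- setNames(rep("X", 20), names(labs))
    et2 <- hypergeomClusterTest(tgt, bg, labs2, "X")
    expect_equal(et2$p_deplete, 1)
    expect_equal(et2$p_enrich, 1)

    expect_error(hypergeomClusterTest(character(), bg, labs), "non-empty")
})

test_that("cells in both sets are counted once, as target cells", {
    labs <- setNames(rep(c("X", "Y"), 10), sprintf("c%02d", 1:20))
    et <- hypergeomClusterTest(sprintf("c%02d", 1:10),
                               sprintf("c%02d", 6:20), labs, "X")
    expect_equal(et$N[1], 20L)   # no double counting
})

test_that("pseudotime shift test is exact for small groups and handles ties", {
    r <- pseudotimeShiftTest(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$U, 0)
    expect_equal(r$p, 0.1)           # 2/20 exact two-sided
    expect_equal(r$medianDiff, -3)
    expect_true(r$exact)

    r2 <- pseudotimeShiftTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r2$p, 1)
    expect_equal(r2$medianDiff, 0)
    expect_false(r2$exact)

    expect_error(pseudotimeShiftTest(numeric(), 1:3), "non-empty")
})

test_that("the normal approximation tracks the exact U distribution at n = 8", {
    ## worst-case agreement of the continuity-corrected approximation over
    ## tie-free splits at n1 = n2 = 8
    set.seed(12)
    worst <- 0
    for (i in 1:100) {
        x <- sample(1:16)
        pe <- wilcox.test(x[1:8], x[9:16], exact = TRUE)$p.value
        pa <- suppressWarnings(wilcox.test(x[1:8], x[9:16], exact = FALSE,
                                           correct = TRUE)$p.value)
        worst <- max(worst, abs(pe - pa))
    }
    expect_lte(worst, 0.011)
})

test_that("per-gene Mann-Whitney separates disjoint distributions", {
    set.seed(2)
    cells <- sprintf("c%02d", 1:60)
    lay <- cbind(G1 = c(rep(0, 30), runif(30, 1, 2)),
                 G2 = rep(1, 60))
    rownames(lay) <- cells
    r <- geneDeTest(lay, "G1", cells[1:30], cells[31:60])
    expect_lt(r$p, 1e-6)
    expect_equal(r$sign, -1)
    r2 <- geneDeTest(lay, "G2", cells[1:30], cells[31:60])
    expect_true(r2$zeroVariance)
    expect_equal(r2$p, 1)
    expect_error(geneDeTest(lay, "NOPE", cells[1:2], cells[3:4]), "NOPE")
})

test_that("label permutation gives uniform per-gene p-values", {
    set.seed(8)
    cells <- sprintf("c%03d", 1:80)
    lay <- matrix(rnorm(80), 80, 1, dimnames = list(cells, "G1"))
    ps <- replicate(1000, {
        pick <- sample(cells, 40)
        geneDeTest(lay, "G1", pick, setdiff(cells, pick))$p
    })
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("pairwise state gene sets split by direction and respect the FDR", {
    set.seed(4)
    genes <- c(sprintf("UPA%02d", 1:20), sprintf("UPB%02d", 1:20),
               sprintf("NULL%02d", 1:60))
    lay <- randomLogLayer(400, genes, seed = 4)
    labels <- setNames(rep(c("mid", "late"), each = 200), rownames(lay))
    lay[labels == "mid", 1:20] <- lay[labels == "mid", 1:20] + 2      # 2 SD
    lay[labels == "late", 21:40] <- lay[labels == "late", 21:40] + 2
    res <- pairwiseStateGenes(lay, labels, "mid", "late")
    expect_gte(mean(sprintf("UPA%02d", 1:20) %in% res$genesA), 0.9)
    expect_gte(mean(sprintf("UPB%02d", 1:20) %in% res$genesB), 0.9)
    falseCalls <- sum(sprintf("NULL%02d", 1:60) %in% c(res$genesA, res$genesB))
    expect_lte(falseCalls / 60, 0.05 + 0.05)   # null gene false-assignment

    expect_error(pairwiseStateGenes(lay, labels[1:2], "mid", "late"),
                 "at least 3")
})

test_that("unique top cluster genes exclude shared markers and recover planted ones", {
    set.seed(6)
    states <- c("progenitor", "early", "mid", "late")
    genes <- c(as.vector(outer(sprintf("MK%s", substr(states, 1, 2)), 1:15,
                               paste0)), "SHARED", sprintf("BG%02d", 1:30))
    lay <- randomLogLayer(400, genes, seed = 6)
    labels <- setNames(rep(states, each = 100), rownames(lay))
    for (s in seq_along(states)) {
        mk <- paste0(sprintf("MK%s", substr(states[s], 1, 2)), 1:15)
        lay[labels == states[s], mk] <- lay[labels == states[s], mk] + 3
        lay[labels == states[s], "SHARED"] <-
            lay[labels == states[s], "SHARED"] + 3 * (s %in% c(2, 3))
    }
    tops <- rankClusterGenes(lay, labels, nTop = 16)
    expect_false("SHARED" %in% unlist(tops))   # enriched in two clusters
    for (s in states) {
        mk <- paste0(sprintf("MK%s", substr(s, 1, 2)), 1:15)
        expect_gte(mean(mk %in% tops[[s]]), 0.9)
        expect_equal(tops[[s]][1], rankClusterGenes(lay, labels, s, 16)[1])
    }
})

test_that("resampling Z-test is seed-deterministic with coherent tails", {
    lay <- randomLogLayer(300, sprintf("G%02d", 1:10), seed = 10)
    cells <- rownames(lay)
    pert <- cells[1:40]; pool <- cells[41:300]
    r1 <- genesetResamplingZtest(lay, sprintf("G%02d", 1:5), pert, pool,
                                 nIter = 500, seed = 123)
    r2 <- genesetResamplingZtest(lay, sprintf("G%02d", 1:5), pert, pool,
                                 nIter = 500, seed = 123)
    expect_identical(r1, r2)
    expect_equal(r1$z, (r1$observedMean - r1$nullMean) / r1$nullSd)
    expect_equal(r1$pDeplete, pnorm(r1$z))
    expect_equal(r1$pEnrich + r1$pDeplete, 1)

    # z = -2 maps to the lower normal tail
    expect_equal(pnorm(-2), 0.02275, tolerance = 1e-4)

    # degenerate null
    lay0 <- lay; lay0[] <- 1
    r3 <- genesetResamplingZtest(lay0, "G01", pert, pool, nIter = 50, seed = 1)
    expect_true(r3$degenerate)
    expect_true(is.na(r3$z))

    expect_error(genesetResamplingZtest(lay, "G01", cells, cells[1:3],
                                        nIter = 10, seed = 1), "at least as large")
    expect_error(genesetResamplingZtest(lay, character(), pert, pool,
                                        nIter = 10, seed = 1), "non-empty")
})

test_that("pseudotime profiles smooth correctly and preserve monotone trends", {
    cells <- sprintf("c%03d", 1:100)
    ranks <- setNames(sample(0:99), cells)
    lay <- matrix(2, 100, 2, dimnames = list(cells, c("A", "B")))
    prof <- genesetPseudotimeProfile(lay, c("A", "B"), ranks, window = 7)
    expect_true(all(prof$smoothed == 2))                   # flat stays flat

    lay2 <- matrix(0, 100, 1, dimnames = list(cells, "A"))
    lay2[order(ranks), 1] <- (1:100) / 10 + rnorm(100, sd = 0.01)
    raw <- genesetPseudotimeProfile(lay2, "A", ranks, window = 1)
    expect_equal(raw$smoothed, lay2[raw$cell, 1], ignore_attr = TRUE)
    sm <- genesetPseudotimeProfile(lay2, "A", ranks, window = 11)
    expect_gt(cor(sm$smoothed, sm$rank, method = "spearman"), 0.99)
})

test_that("bulk fold changes average over the gene set per time point", {
    rpkm <- data.frame(gene = c("A", "B"),
                       day0 = c(1, 2), day4 = c(2, 4))
    fc <- bulkTimecourseFoldchange(rpkm, c("A", "B"), epsilon = 0)
    expect_equal(unname(fc["day4"]), 2.0)
    expect_equal(unname(fc["day0"]), 1.0)

    rpkm2 <- data.frame(gene = "Z", day0 = 0, day4 = 5)
    fc2 <- bulkTimecourseFoldchange(rpkm2, "Z", epsilon = 0.1)
    expect_equal(unname(fc2["day4"]), 5.1 / 0.1)

    expect_warning(bulkTimecourseFoldchange(rpkm, c("A", "MISSING")),
                   "MISSING")
    expect_error(bulkTimecourseFoldchange(rpkm, "A", day0 = "day9"), "day9")
})
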