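## Build an assignment where each cell carries exactly one guide and cluster
## labels are drawn per guide from given per-cluster cell counts.
qcFixture <- function(countsPerGuide) {
    cells <- character(); guides <- character(); labels <- character()
    i <- 0L
    for (g in names(countsPerGuide)) {
        for (cl in names(countsPerGuide[[g]])) {
            k <- countsPerGuide[[g]][[cl]]
            if (k == 0) next
            newCells <- sprintf("c%05d", i + seq_len(k))
            i <- i + k
            cells <- c(cells, newCells)
            guides <- c(guides, rep(g, k))
            labels <- c(labels, rep(cl, k))
        }
    }
    list(assignment = assignmentFromCalls(cells, guides),
         labels = setNames(labels, cells))
}

test_that("exchangeable NT guides survive debiasing; a skewed one is removed", {
    counts <- list()
    for (g in sprintf("NT%d", 1:5))
        counts[[g]] <- c(A = 12, B = 38)
    fx <- qcFixture(counts)
    kept <- debiasNtBackground(fx$assignment, fx$labels, names(counts))
    expect_setequal(as.character(kept), names(counts))

    # one NT with 40/50 cells in cluster A against a 60/250 pooled background
    counts2 <- list(NT1 = c(A = 40, B = 10))
    for (g in sprintf("NT%d", 2:5)) counts2[[g]] <- c(A = 5, B = 45)
    fx2 <- qcFixture(counts2)
    # exact enrichment tail for the skewed guide, via the oracle
    pOracle <- hyperTailOracle(40, N = 250, K = 60, n = 50, upper = TRUE)
    expect_lt(pOracle * 2 * 2 * 5, 1e-6)   # far below alpha after Bonferroni
    kept2 <- debiasNtBackground(fx2$assignment, fx2$labels,
                                names(counts2))
    expect_false("NT1" %in% kept2)
    expect_identical(attr(kept2, "removed"), "NT1")
})

test_that("debiasing never goes below two NT guides", {
    counts <- list(NT1 = c(A = 50, B = 0), NT2 = c(A = 0, B = 50))
    fx <- qcFixture(counts)
    kept <- debiasNtBackground(fx$assignment, fx$labels, c("NT1", "NT2"))
    expect_setequal(as.character(kept), c("NT1", "NT2"))
    expect_error(debiasNtBackground(fx$assignment, fx$labels, "NT1"),
                 "at least 2")
})

test_that("combination enumeration yields 2^k - 1 subsets and 2 x clusters lists", {
    counts <- list(g1 = c(A = 20, B = 20, C = 20, D = 20),
                   g2 = c(A = 20, B = 20, C = 20, D = 20),
                   g3 = c(A = 20, B = 20, C = 20, D = 20),
                   NT1 = c(A = 50, B = 50, C = 50, D = 50),
                   NT2 = c(A = 50, B = 50, C = 50, D = 50))
    fx <- qcFixture(counts)
    ntCells <- cellsWithGuide(fx$assignment, c("NT1", "NT2"))
    pv <- enumerateCombinationPvalues(c("g1", "g2", "g3"), fx$assignment,
                                      fx$labels, ntCells)
    expect_length(pv$combos, 7L)
    expect_equal(sum(vapply(pv$combos, function(cc) "g2" %in% cc, TRUE)), 4L)
    expect_length(pv$lists, 8L)   # 4 clusters x 2 directions
    for (lst in pv$lists) expect_false(is.unsorted(lst$p))

    expect_null(enumerateCombinationPvalues("g1", fx$assignment, fx$labels,
                                            ntCells))
})

test_that("a guide monopolizing the top combinations is flagged at p = 1/35", {
    combos <- screenkit:::.guideCombos(c("a", "b", "c"))
    hasC <- vapply(combos, function(cc) "c" %in% cc, logical(1))
    mk <- function(ord) data.frame(combo = ord, p = seq(0.001, 0.9,
                                                        length.out = 7))
    lists <- list(A.deplete = mk(c(which(hasC), which(!hasC))))
    fl <- flagBiasedGuides(list(combos = combos, lists = lists))
    expect_equal(fl$perList$p_over[fl$perList$guide == "c"], 1 / 35)
    expect_identical(fl$removed, "c")
    expect_false(fl$keptAll)
})

test_that("more than half flagged means every guide is kept", {
    combos <- screenkit:::.guideCombos(c("a", "b", "c"))
    hasG <- function(g) vapply(combos, function(cc) g %in% cc, logical(1))
    mk <- function(g) data.frame(combo = c(which(hasG(g)), which(!hasG(g))),
                                 p = seq(0.001, 0.9, length.out = 7))
    lists <- list(A.deplete = mk("a"), A.enrich = mk("b"))
    ## alpha large enough that the k = 3 count test clears the per-list
    ## correction (its smallest attainable p is 1/35)
    fl <- flagBiasedGuides(list(combos = combos, lists = lists), alpha = 0.2)
    expect_setequal(fl$candidates, c("a", "b"))
    expect_true(fl$keptAll)          # 2 > 3/2
    expect_length(fl$removed, 0)
})

test_that("the keep-all rule holds exhaustively for k in 2..4", {
    for (k in 2:4) {
        guides <- letters[seq_len(k)]
        combos <- screenkit:::.guideCombos(guides)
        for (s in 0:k) {
            flagged <- guides[seq_len(s)]
            lists <- lapply(seq_len(s), function(i) {
                hasG <- vapply(combos, function(cc) flagged[i] %in% cc,
                               logical(1))
                data.frame(combo = c(which(hasG), which(!hasG)),
                           p = seq(1e-6, 0.9, length.out = length(combos)))
            })
            names(lists) <- if (s > 0) paste0("L", seq_len(s), ".deplete")
            if (s == 0) lists <- list(L1.deplete = data.frame(
                combo = seq_along(combos), p = rep(0.99, length(combos))))
            ## alpha = 0.8 so that even k = 2 can flag (its smallest
            ## attainable over-representation p is 1/3) under the
            ## per-list correction
            fl <- flagBiasedGuides(list(combos = combos, lists = lists),
                                   alpha = 0.8)
            expect_setequal(fl$candidates, flagged)
            expect_identical(fl$keptAll, s > k / 2)
            if (s > k / 2) expect_length(fl$removed, 0)
            else expect_setequal(fl$removed, flagged)
        }
    }
})

test_that("an off-target guide with a shifted state distribution is removed", {
    set.seed(42)
    base <- c(progenitor = 0.25, early = 0.30, mid = 0.25, late = 0.20)
    odds <- base; odds["late"] <- odds["late"] * 3
    shifted <- odds / sum(odds)
    removedBad <- 0L; keptGood <- 0L
    reps <- 20
    for (r in seq_len(reps)) {
        counts <- list()
        for (g in c("g1", "g2", "g3"))
            counts[[g]] <- table(factor(drawLabels(200, base), names(base)))
        counts[["g4"]] <- table(factor(drawLabels(200, shifted), names(base)))
        counts[["NT1"]] <- table(factor(drawLabels(400, base), names(base)))
        counts[["NT2"]] <- table(factor(drawLabels(400, base), names(base)))
        fx <- qcFixture(lapply(counts, as.list))
        ntCells <- cellsWithGuide(fx$assignment, c("NT1", "NT2"))
        pv <- enumerateCombinationPvalues(paste0("g", 1:4), fx$assignment,
                                          fx$labels, ntCells,
                                          clusters = names(base))
        fl <- flagBiasedGuides(pv)
        if ("g4" %in% fl$removed) removedBad <- removedBad + 1L
        if (!any(c("g1", "g2", "g3") %in% fl$removed)) keptGood <- keptGood + 1L
    }
    expect_gte(removedBad / reps, 0.9)
    expect_gte(keptGood / reps, 0.9)
})

test_that("exchangeable targets rarely lose a guide", {
    set.seed(515)
    base <- c(progenitor = 0.25, early = 0.30, mid = 0.25, late = 0.20)
    lost <- 0L; reps <- 100
    for (r in seq_len(reps)) {
        counts <- lapply(setNames(nm = c(sprintf("g%d", 1:4), "NT1", "NT2")),
                         function(g) as.list(table(factor(
                             drawLabels(if (startsWith(g, "NT")) 500 else 200,
                                        base), names(base)))))
        fx <- qcFixture(counts)
        ntCells <- cellsWithGuide(fx$assignment, c("NT1", "NT2"))
        pv <- enumerateCombinationPvalues(sprintf("g%d", 1:4), fx$assignment,
                                          fx$labels, ntCells,
                                          clusters = names(base))
        fl <- flagBiasedGuides(pv)
        if (length(fl$removed)) lost <- lost + 1L
    }
    expect_lte(lost / reps, 2 * 0.05)
})
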