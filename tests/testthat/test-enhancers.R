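bedGR <- function(chrom, start, end, name = NULL) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
    if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
    gr
}

test_that("peak merging and extension follow the midpoint rule", {
    p <- bedGR(c("chr1", "chr1"), c(100, 250), c(300, 450))
    out <- mergeExtendPeaks(p)
    expect_equal(GenomicRanges::start(out) - 1L, 25L)   # BED [25,525)
    expect_equal(GenomicRanges::end(out), 525L)
    expect_false(S4Vectors::mcols(out)$clipped)

    fixed <- mergeExtendPeaks(bedGR("chr2", 1000, 1500))
    expect_equal(GenomicRanges::start(fixed) - 1L, 1000L)
    expect_equal(GenomicRanges::end(fixed), 1500L)

    clipped <- mergeExtendPeaks(bedGR("chr3", 0, 100))
    expect_equal(GenomicRanges::start(clipped) - 1L, 0L)
    expect_equal(GenomicRanges::end(clipped), 300L)
    expect_true(S4Vectors::mcols(clipped)$clipped)
})

test_that("merged regions are sorted and pairwise distinct", {
    set.seed(14)
    p <- bedGR(sample(c("chr1", "chr2"), 200, TRUE),
               s <- sample(1:10000, 200), s + sample(50:400, 200, TRUE))
    out <- mergeExtendPeaks(p)
    expect_false(any(duplicated(out)))
    expect_identical(out, GenomicRanges::sort(out, ignore.strand = TRUE))
})

test_that("ChIP enrichment is input-normalized RPKM on the log2 scale", {
    # count 100 over 500 bp in a 1e6-read library -> RPKM 200
    e <- chipEnrichment(matrix(100), matrix(100), 500, 1e6, 1e6,
                        pseudocount = 0)
    expect_equal(as.numeric(e), 0)        # chip = input -> exactly 0
    rpkm <- 100 / (0.5 * 1)
    expect_equal(rpkm, 200)
    # chip RPKM 3 vs input 1 with c -> 0
    e2 <- chipEnrichment(matrix(3), matrix(1), 1000, 1e6, 1e6, pseudocount = 0)
    expect_equal(as.numeric(e2), log2(3), tolerance = 1e-12)
    expect_error(chipEnrichment(matrix(1), matrix(1), 0, 1e6, 1e6), "width")
})

test_that("candidate gates apply strict activity and inclusive distance windows", {
    regions <- bedGR(rep("chr1", 3), c(25, 5000, 9000), c(525, 5500, 9500))
    enr <- matrix(c(1.585, 0.30, 1.0,
                    0.10, 0.20, 0.9), 3, 2)
    variants <- bedGR("chr1", c(1500, 5200), c(1501, 5201))
    genes <- bedGR("chr1", 2000, 3000, name = "TBX5")
    cand <- selectCandidates(regions, enr, variants = variants, genes = genes)
    # region 1: max 1.585 > log2(1.5); variant distance 1500-524 = 976 <= 1000
    expect_equal(GenomicRanges::start(cand) - 1L, 25L)
    expect_equal(S4Vectors::mcols(cand)$nearest_variant_distance, 976)
    expect_equal(S4Vectors::mcols(cand)$linked_genes, "TBX5")
    # region 3 passes activity but nearest variant is 9000-5200 = 3800 away

    # pushing the variant to 1600 puts region 1 at distance 1076 -> dropped
    v2 <- bedGR("chr1", 1600, 1601)
    cand2 <- selectCandidates(regions, enr, variants = v2, genes = genes)
    expect_length(cand2, 0)

    # a region overlapping a gene body has gene distance 0
    g2 <- bedGR("chr1", 100, 200, name = "NKX2-5")
    cand3 <- selectCandidates(regions, enr, variants = variants, genes = g2,
                              geneWindow = 1)
    expect_equal(S4Vectors::mcols(cand3)$linked_genes, "NKX2-5")

    expect_error(selectCandidates(regions, enr,
                                  variants = GenomicRanges::GRanges(),
                                  genes = genes), "empty")
})

## brute-force oracle for the full gate chain, in BED coordinates
candidateOracle <- function(regions, enr, thr, variants, vw, genes, gw) {
    rs <- GenomicRanges::start(regions) - 1L; re <- GenomicRanges::end(regions)
    rc <- as.character(GenomicRanges::seqnames(regions))
    dist1 <- function(c1, s1, e1, c2, s2, e2) {
        if (c1 != c2) return(Inf)
        if (s1 < e2 && s2 < e1) return(0)
        if (s2 >= e1) s2 - (e1 - 1) else s1 - (e2 - 1)
    }
    keep <- logical(length(regions))
    for (i in seq_along(regions)) {
        if (max(enr[i, ]) <= thr) next
        dv <- min(vapply(seq_along(variants), function(j)
            dist1(rc[i], rs[i], re[i],
                  as.character(GenomicRanges::seqnames(variants))[j],
                  GenomicRanges::start(variants)[j] - 1L,
                  GenomicRanges::end(variants)[j]), numeric(1)))
        if (dv > vw) next
        dg <- min(vapply(seq_along(genes), function(j)
            dist1(rc[i], rs[i], re[i],
                  as.character(GenomicRanges::seqnames(genes))[j],
                  GenomicRanges::start(genes)[j] - 1L,
                  GenomicRanges::end(genes)[j]), numeric(1)))
        if (dg > gw) next
        keep[i] <- TRUE
    }
    which(keep)
}

test_that("the gate chain matches the all-pairs oracle and is monotone", {
    set.seed(31)
    n <- 400
    regions <- bedGR(sample(c("chr1", "chr2"), n, TRUE),
                     s <- sample(seq(0, 2e5, by = 10), n), s + 500)
    enr <- matrix(rnorm(n * 3, 0.5, 0.5), n, 3)
    variants <- bedGR(sample(c("chr1", "chr2"), 60, TRUE),
                      v <- sample(0:2e5, 60), v + 1)
    genes <- bedGR(sample(c("chr1", "chr2"), 15, TRUE),
                   g <- sample(0:2e5, 15), g + sample(1000:20000, 15),
                   name = sprintf("GN%02d", 1:15))
    cand <- selectCandidates(regions, enr, variants = variants, genes = genes)
    oracle <- candidateOracle(regions, enr, log2(1.5), variants, 1000,
                              genes, 100000)
    key <- function(gr) paste0(GenomicRanges::seqnames(gr), ":",
                               GenomicRanges::start(gr))
    expect_setequal(key(cand), key(regions[oracle]))

    # monotonicity: tightening any gate never adds candidates
    tighter <- selectCandidates(regions, enr, threshold = 1.2,
                                variants = variants, variantWindow = 500,
                                genes = genes, geneWindow = 50000)
    expect_true(all(key(tighter) %in% key(cand)))
})
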