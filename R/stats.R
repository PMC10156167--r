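#' Hypergeometric cell-state enrichment and depletion test
#'
#' Pools the target and background (control) cells into one urn and asks,
#' per trajectory cluster, whether the target cells are over- or
#' under-represented in that cluster. With `N` urn cells of which `K` are
#' in the cluster, and `n` target cells of which `k` are in the cluster,
#' depletion is the lower tail `P(X <= k)` of Hypergeom(N, K, n) and
#' enrichment the inclusive upper tail `P(X >= k)`, so
#' `p_enrich + p_deplete = 1 + P(X = k)` exactly. The exclusive upper
#' tail `P(X > k)` is also emitted (`p_enrich_exclusive`) for users who
#' want the literal survival-function convention.
#'
#' @param targetCells,backgroundCells character vectors of cell barcodes;
#'   a cell in both is treated as a target cell and removed from the
#'   background.
#' @param labels named character vector: cell barcode -> cluster label.
#' @param clusters clusters to test (default: all labels seen in the urn).
#' @return data.frame with one row per cluster: counts
#'   `k, n, n_background_in_cluster, n_background, K, N` and p-values
#'   `p_enrich`, `p_deplete`, `p_enrich_exclusive`.
#' @examples
#' labs <- setNames(rep(c("A", "B"), c(8, 12)), sprintf("c%02d", 1:20))
#' hypergeomClusterTest(sprintf("c%02d", c(1, 9:17)), sprintf("c%02d", c(2:8, 18:20)),
#'                      labs, "A")
#' @export
hypergeomClusterTest <- function(targetCells, backgroundCells, labels,
                                 clusters = NULL) {
    backgroundCells <- setdiff(backgroundCells, targetCells)
    if (!length(targetCells) || !length(backgroundCells))
        stop("target and background cell sets must both be non-empty")
    urn <- c(targetCells, backgroundCells)
    if (anyNA(labels[urn])) stop("every urn cell must be labeled")
    if (is.null(clusters)) clusters <- sort(unique(labels[urn]))
    n <- length(targetCells)
    N <- length(urn)
    res <- lapply(clusters, function(cl) {
        k <- sum(labels[targetCells] == cl)
        kb <- sum(labels[backgroundCells] == cl)
        K <- k + kb
        data.frame(cluster = cl, k = k, n = n,
                   n_background_in_cluster = kb, n_background = N - n,
                   K = K, N = N,
                   p_deplete = stats::phyper(k, K, N - K, n),
                   p_enrich = stats::phyper(k - 1, K, N - K, n,
                                            lower.tail = FALSE),
                   p_enrich_exclusive = stats::phyper(k, K, N - K, n,
                                                      lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Mann-Whitney pseudotime-shift test
#'
#' Tests whether the pseudotime ranks of perturbed cells are shifted
#' relative to control cells. The exact null distribution is enumerated
#' when both groups have at most 8 observations and there are no ties;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction) is used.
#'
#' @param targetRanks,backgroundRanks numeric vectors of pseudotime ranks.
#' @param alternative passed to [stats::wilcox.test()] (default
#'   two-sided).
#' @return List with `U` (Mann-Whitney U of the target sample), `p`,
#'   `medianDiff` = median(target) - median(background), and `exact`.
#' @examples
#' pseudotimeShiftTest(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
pseudotimeShiftTest <- function(targetRanks, backgroundRanks,
                                alternative = "two.sided") {
    if (!length(targetRanks) || !length(backgroundRanks))
        stop("both rank lists must be non-empty")
    ties <- anyDuplicated(c(targetRanks, backgroundRanks)) > 0
    exact <- length(targetRanks) <= 8 && length(backgroundRanks) <= 8 && !ties
    wt <- suppressWarnings(stats::wilcox.test(
        targetRanks, backgroundRanks, alternative = alternative,
        exact = exact, correct = TRUE))
    list(U = unname(wt$statistic), p = wt$p.value,
         medianDiff = stats::median(targetRanks) - stats::median(backgroundRanks),
         exact = exact)
}

#' Per-gene differential expression (Mann-Whitney)
#'
#' Two-sided Mann-Whitney U test on log-layer expression of one gene in
#' perturbed versus control cells, plus the sign of the mean difference
#' for Manhattan-style displays.
#'
#' @param logLayer dense cells x genes matrix (the log layer).
#' @param gene gene name.
#' @param perturbedCells,controlCells barcode vectors.
#' @return List with `p`, `sign` (-1, 0, 1 of mean difference) and
#'   `zeroVariance` (TRUE when both groups are constant, in which case
#'   p = 1).
#' @export
geneDeTest <- function(logLayer, gene, perturbedCells, controlCells) {
    if (!gene %in% colnames(logLayer)) stop("gene not present: ", gene)
    if (!length(perturbedCells) || !length(controlCells))
        stop("both cell sets must be non-empty")
    a <- logLayer[perturbedCells, gene]
    b <- logLayer[controlCells, gene]
    if (stats::var(c(a, b)) == 0)
        return(list(p = 1, sign = 0, zeroVariance = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    list(p = wt$p.value, sign = sign(mean(a) - mean(b)), zeroVariance = FALSE)
}

## Vectorized one-vs-rest / two-group rank-sum over all genes.
## Returns per-gene z (positive when group A is higher) and two-sided p,
## using the tie-corrected normal approximation.
.rankSumVec <- function(logLayer, cellsA, cellsB) {
    m <- logLayer[c(cellsA, cellsB), , drop = FALSE]
    n1 <- length(cellsA); n2 <- length(cellsB); n <- n1 + n2
    z <- p <- numeric(ncol(m))
    for (j in seq_len(ncol(m))) {
        r <- rank(m[, j])
        U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
        t <- table(m[, j])
        tieTerm <- sum(t^3 - t)
        sig2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
        if (sig2 <= 0) { z[j] <- 0; p[j] <- 1; next }
        z[j] <- (U - n1 * n2 / 2) / sqrt(sig2)
        p[j] <- 2 * stats::pnorm(-abs(z[j]))
    }
    data.frame(gene = colnames(m), z = z, p = p, stringsAsFactors = FALSE)
}

#' State-defining gene sets by pairwise rank-sum test
#'
#' Compares every gene between two trajectory states with a two-sided
#' Wilcoxon rank-sum test, adjusts with Benjamini-Hochberg, and splits
#' the significant genes by direction of the mean log-layer difference.
#' This is how the mid-CM and late-CM signature sets are defined.
#'
#' @param logLayer dense cells x genes matrix.
#' @param labels named cluster labels per cell.
#' @param stateA,stateB the two states to contrast.
#' @param fdr Benjamini-Hochberg threshold (default 0.05).
#' @return List with `genesA` (higher in `stateA`), `genesB`, and the
#'   full per-gene `table`.
#' @export
pairwiseStateGenes <- function(logLayer, labels, stateA, stateB, fdr = 0.05) {
    cellsA <- names(labels)[labels == stateA]
    cellsB <- names(labels)[labels == stateB]
    cellsA <- intersect(cellsA, rownames(logLayer))
    cellsB <- intersect(cellsB, rownames(logLayer))
    if (length(cellsA) < 3 || length(cellsB) < 3)
        stop("each state needs at least 3 cells")
    tab <- .rankSumVec(logLayer, cellsA, cellsB)
    tab$meanDiff <- colMeans(logLayer[cellsA, , drop = FALSE]) -
        colMeans(logLayer[cellsB, , drop = FALSE])
    tab$padj <- stats::p.adjust(tab$p, method = "BH")
    sigUp <- tab$padj < fdr & tab$meanDiff > 0
    sigDn <- tab$padj < fdr & tab$meanDiff < 0
    list(genesA = tab$gene[sigUp], genesB = tab$gene[sigDn], table = tab)
}

#' Top uniquely enriched genes per cluster
#'
#' Scores every gene one-vs-rest per cluster with the rank-sum z score,
#' takes each cluster's top `nTop`, and removes genes that appear in more
#' than one cluster's top list ("uniquely enriched"). Ties in score are
#' broken by gene name.
#'
#' @param logLayer dense cells x genes matrix.
#' @param labels named cluster labels per cell.
#' @param cluster the cluster whose list is returned; `NULL` returns the
#'   per-cluster lists for all clusters.
#' @param nTop list size before the uniqueness filter (default 100).
#' @return Character vector of genes (or a named list of them when
#'   `cluster` is NULL), ordered by decreasing score.
#' @export
rankClusterGenes <- function(logLayer, labels, cluster = NULL, nTop = 100) {
    labels <- labels[intersect(names(labels), rownames(logLayer))]
    clusters <- sort(unique(labels))
    tops <- lapply(clusters, function(cl) {
        cellsA <- names(labels)[labels == cl]
        cellsB <- names(labels)[labels != cl]
        sc <- .rankSumVec(logLayer, cellsA, cellsB)
        sc <- sc[order(-sc$z, sc$gene), ]
        utils::head(sc$gene, nTop)
    })
    names(tops) <- clusters
    shared <- unlist(tops, use.names = FALSE)
    shared <- unique(shared[duplicated(shared)])
    tops <- lapply(tops, function(g) setdiff(g, shared))
    if (is.null(cluster)) return(tops)
    if (!cluster %in% clusters) stop("cluster not present: ", cluster)
    tops[[cluster]]
}

#' Resampling Z-test of gene-set expression in perturbed cells
#'
#' The observed statistic is the mean, over perturbed cells, of each
#' cell's mean log-layer expression of the gene set. A null distribution
#' is built by drawing `nIter` samples without replacement of
#' `length(perturbedCells)` cells from the control pool and recording the
#' same statistic; z = (observed - null mean) / null sd. Depletion
#' p-value is the lower normal tail `pnorm(z)` and enrichment the upper
#' tail, so small depletion p means the perturbed cells express the set
#' below control level.
#'
#' @param logLayer dense cells x genes matrix.
#' @param geneSet character vector of gene names (non-empty).
#' @param perturbedCells barcode vector of perturbed cells.
#' @param controlPool barcode vector, at least as large as
#'   `perturbedCells`.
#' @param nIter resampling iterations (default 1000).
#' @param seed integer seed; identical seed gives identical results.
#' @return List: `observedMean`, `nullMean`, `nullSd`, `z`, `pEnrich`,
#'   `pDeplete`, `nPerturbed`, `nIter`, `seed`, `degenerate` (TRUE when
#'   the null sd is zero, in which case z and p are NA).
#' @export
genesetResamplingZtest <- function(logLayer, geneSet, perturbedCells,
                                   controlPool, nIter = 1000, seed) {
    if (missing(seed)) stop("seed must be given explicitly")
    if (!length(geneSet)) stop("gene set must be non-empty")
    miss <- setdiff(geneSet, colnames(logLayer))
    if (length(miss)) stop("genes absent from layer: ", paste(miss, collapse = ", "))
    if (length(controlPool) < length(perturbedCells))
        stop("control pool must be at least as large as the perturbed set")
    sub <- logLayer[, geneSet, drop = FALSE]
    cellMean <- rowMeans(sub)
    observed <- mean(cellMean[perturbedCells])
    m <- length(perturbedCells)
    poolVals <- cellMean[controlPool]
    M <- length(poolVals)
    set.seed(as.integer(seed))
    nullStats <- vapply(seq_len(nIter),
                        function(i) mean(poolVals[sample.int(M, m)]),
                        numeric(1))
    nullMean <- mean(nullStats)
    nullSd <- stats::sd(nullStats)
    degenerate <- !is.finite(nullSd) || nullSd == 0
    z <- if (degenerate) NA_real_ else (observed - nullMean) / nullSd
    list(observedMean = observed, nullMean = nullMean, nullSd = nullSd,
         z = z,
         pEnrich = if (degenerate) NA_real_ else stats::pnorm(z, lower.tail = FALSE),
         pDeplete = if (degenerate) NA_real_ else stats::pnorm(z),
         nPerturbed = m, nIter = as.integer(nIter), seed = as.integer(seed),
         degenerate = degenerate)
}

#' Smoothed gene-set expression along pseudotime
#'
#' Orders cells by pseudotime rank and applies a centered rolling mean
#' (window truncated at the edges) to the per-cell gene-set mean.
#'
#' @param logLayer dense cells x genes matrix.
#' @param geneSet character vector of gene names.
#' @param ranks named pseudotime ranks covering the cells of `logLayer`.
#' @param window rolling window size in cells (>= 1; 1 returns the raw
#'   per-cell series).
#' @return data.frame with `cell`, `rank` and `smoothed` in rank order.
#' @export
genesetPseudotimeProfile <- function(logLayer, geneSet, ranks, window = 1) {
    stopifnot(window >= 1)
    cells <- intersect(names(ranks), rownames(logLayer))
    ord <- cells[order(ranks[cells])]
    v <- rowMeans(logLayer[ord, geneSet, drop = FALSE])
    n <- length(v)
    lo <- floor((window - 1) / 2)
    hi <- window - 1 - lo
    sm <- vapply(seq_len(n), function(i)
        mean(v[max(1, i - lo):min(n, i + hi)]), numeric(1))
    data.frame(cell = ord, rank = unname(ranks[ord]), smoothed = sm,
               stringsAsFactors = FALSE)
}

#' Bulk time-course fold change of a gene set
#'
#' For every gene in the set, computes the fold change of (replicate-
#' averaged) RPKM at each time point over the day-0 value, with a
#' pseudocount to keep ratios finite, and averages fold changes over the
#' set per time point.
#'
#' @param rpkm data.frame with a `gene` column and one numeric column per
#'   time point.
#' @param geneSet character vector of genes; genes absent from the table
#'   are dropped with a warning.
#' @param day0 name of the baseline column (default `"day0"`).
#' @param epsilon RPKM pseudocount (default 0.1).
#' @return Named numeric vector: mean fold change per time point
#'   (including the baseline, which is 1 only if all genes are nonzero at
#'   baseline in the exact-ratio sense; with the pseudocount it is exactly
#'   1).
#' @export
bulkTimecourseFoldchange <- function(rpkm, geneSet, day0 = "day0",
                                     epsilon = 0.1) {
    if (!day0 %in% names(rpkm)) stop("no baseline column '", day0, "' in table")
    miss <- setdiff(geneSet, rpkm$gene)
    if (length(miss))
        warning("genes absent from table, excluded: ",
                paste(miss, collapse = ", "))
    sub <- rpkm[rpkm$gene %in% geneSet, , drop = FALSE]
    if (!nrow(sub)) stop("no gene of the set present in the table")
    tpCols <- setdiff(names(sub), "gene")
    base <- sub[[day0]] + epsilon
    fc <- vapply(tpCols, function(cl) mean((sub[[cl]] + epsilon) / base),
                 numeric(1))
    fc
}
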