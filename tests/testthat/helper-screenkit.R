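## Shared fixtures and independent oracles used across the suite.

## Build a GuideAssignment directly from a cell -> guide call table,
## bypassing knee calling (used by guide-QC and power simulations where
## the carriage structure is the controlled input).
assignmentFromCalls <- function(cells, guides, allCells = cells,
                                allGuides = sort(unique(guides)), umi = 10L) {
    m <- Matrix::sparseMatrix(
        i = match(cells, allCells), j = match(guides, allGuides),
        x = rep(umi, length(cells)),
        dims = c(length(allCells), length(allGuides)),
        dimnames = list(allCells, allGuides))
    new("GuideAssignment", adjusted = m,
        kneeReport = data.frame(guide = allGuides, knee_rank = NA_integer_,
                                cells_called = as.integer(Matrix::colSums(m > 0))))
}

## Independent knee oracle: explicit point-to-chord distance via vector
## projection, scanning every rank (no shared code with kneeIndex).
kneeOracle <- function(v) {
    v <- v[v > 0]
    m <- length(v)
    if (m == 0) return(NA_integer_)
    if (m == 1) return(1L)
    x <- seq_len(m) / m
    y <- cumsum(v) / sum(v)
    a <- c(x[1], y[1]); b <- c(x[m], y[m])
    ab <- b - a
    d <- numeric(m)
    for (r in seq_len(m)) {
        p <- c(x[r], y[r]) - a
        proj <- sum(p * ab) / sum(ab * ab)
        d[r] <- sqrt(sum((p - proj * ab)^2))
    }
    which(d >= max(d) - 1e-9)[1]   # earliest rank within tolerance
}

## Exact hypergeometric tail oracle by direct probability-mass summation
## (choose() products; independent of phyper).
hyperTailOracle <- function(k, N, K, n, upper = FALSE) {
    kk <- max(0, n - (N - K)):min(n, K)
    pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
    if (upper) sum(pmf[kk >= k]) else sum(pmf[kk <= k])
}

## Multinomial state labels for simulated null/power cell sets.
drawLabels <- function(n, probs, states = names(probs)) {
    sample(states, n, replace = TRUE, prob = probs)
}

## A small deterministic expression layer for rank-test fixtures.
randomLogLayer <- function(nCells, genes, seed = 1) {
    set.seed(seed)
    m <- matrix(rnorm(nCells * length(genes)), nCells, length(genes),
                dimnames = list(sprintf("c%04d", seq_len(nCells)), genes))
    m
}
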