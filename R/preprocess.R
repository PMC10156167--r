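#' Per-cell mitochondrial UMI fraction
#'
#' @param expr a [CountMatrix-class] of cells x genes.
#' @param mitoPrefix feature-name prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return Named numeric vector of fractions in [0,1], one per cell.
#'   Cells with zero total UMIs get fraction 0 and are flagged in the
#'   `zero_total` attribute.
#' @export
computeMitoFraction <- function(expr, mitoPrefix = "MT-") {
    stopifnot(is(expr, "CountMatrix"))
    m <- umiCounts(expr)
    isMito <- startsWith(colnames(m), mitoPrefix)
    if (!any(isMito))
        warning("no feature matches mito prefix '", mitoPrefix,
                "'; all fractions are 0")
    tot <- Matrix::rowSums(m)
    mito <- Matrix::rowSums(m[, isMito, drop = FALSE])
    frac <- ifelse(tot > 0, mito / tot, 0)
    out <- stats::setNames(as.numeric(frac), rownames(m))
    attr(out, "zero_total") <- rownames(m)[tot == 0]
    out
}

#' Cell and gene retention filters
#'
#' Removes cells whose mitochondrial fraction is strictly above `mitoMax`
#' (a cell at exactly the threshold is retained) and genes whose total
#' UMI count over all input cells is strictly below `minGeneTotal`. Both
#' filters are computed on the input matrix, so their order does not
#' matter.
#'
#' @param expr a [CountMatrix-class].
#' @param mitoFraction per-cell fractions from [computeMitoFraction()].
#' @param mitoMax maximum tolerated mitochondrial fraction (default 0.20).
#' @param minGeneTotal minimum total count for a gene to be kept
#'   (default 1, i.e. only all-zero genes are dropped).
#' @return List with `cells` and `genes`: the retained barcode and
#'   feature names.
#' @export
filterCellsGenes <- function(expr, mitoFraction, mitoMax = 0.20,
                             minGeneTotal = 1) {
    stopifnot(is(expr, "CountMatrix"))
    m <- umiCounts(expr)
    keepCells <- rownames(m)[mitoFraction[rownames(m)] <= mitoMax]
    if (!length(keepCells)) stop("all cells removed by the mito filter")
    keepGenes <- colnames(m)[Matrix::colSums(m) >= minGeneTotal]
    list(cells = keepCells, genes = keepGenes)
}

#' Build the raw / log / scaled expression layers
#'
#' The log layer is `ln(1 + raw)` entrywise; the scaled layer standardizes
#' each gene of the log layer to zero mean and unit population variance
#' (divide by n) over the retained cells. Constant genes become all-zero
#' columns. No library-size normalization is applied by default;
#' `normalize = "median"` divides each cell by its total and multiplies by
#' the median total first.
#'
#' @param expr a [CountMatrix-class], already filtered.
#' @param normalize `"none"` (default) or `"median"`.
#' @return An [ExpressionLayers-class].
#' @export
makeLayers <- function(expr, normalize = c("none", "median")) {
    stopifnot(is(expr, "CountMatrix"))
    normalize <- match.arg(normalize)
    raw <- as.matrix(umiCounts(expr))
    base <- raw
    if (normalize == "median") {
        tot <- rowSums(base)
        med <- stats::median(tot[tot > 0])
        pos <- tot > 0
        base[pos, ] <- base[pos, , drop = FALSE] / tot[pos] * med
    }
    logLayer <- log1p(base)
    mu <- colMeans(logLayer)
    v <- colMeans(logLayer^2) - mu^2   # population variance
    scaled <- sweep(logLayer, 2, mu, "-")
    sdv <- sqrt(pmax(v, 0))
    const <- sdv < 1e-12
    sdv[const] <- 1
    scaled <- sweep(scaled, 2, sdv, "/")
    scaled[, const] <- 0
    new("ExpressionLayers", raw = expr, logLayer = logLayer, scaled = scaled)
}

#' Remove clusters holding fewer than a fraction of all cells
#'
#' @param labels per-cell cluster labels.
#' @param minFrac minimum fraction of all cells (default 0.01); a cluster
#'   with strictly fewer than `minFrac * length(labels)` cells is dropped.
#' @return Character vector of retained cluster names.
#' @export
filterSmallClusters <- function(labels, minFrac = 0.01) {
    tab <- table(labels)
    names(tab)[tab >= minFrac * length(labels)]
}
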