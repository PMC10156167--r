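#' Merge ATAC peaks and extend to fixed-width regions
#'
#' Overlapping or bookended peaks on the same chromosome are unioned;
#' each union is replaced by a `width`-bp interval centered on the floor
#' of the union midpoint, clipped at position 0 (clipped regions are
#' flagged). Output is sorted and deduplicated.
#'
#' @param peaks a `GRanges` of peaks.
#' @param width target region width in bp (default 500).
#' @return A sorted `GRanges` of fixed-width regions with a logical
#'   `clipped` metadata column.
#' @examples
#' p <- GenomicRanges::GRanges(c("chr1", "chr1"),
#'                             IRanges::IRanges(c(101, 251), c(300, 450)))
#' mergeExtendPeaks(p)  # one region chr1 26..525 (BED [25,525))
#' @export
mergeExtendPeaks <- function(peaks, width = 500) {
    merged <- GenomicRanges::reduce(peaks, ignore.strand = TRUE)
    ## work in 0-based half-open coordinates for the midpoint rule
    s <- GenomicRanges::start(merged) - 1L
    e <- GenomicRanges::end(merged)
    mid <- floor((s + e) / 2)
    half <- floor(width / 2)
    newS <- mid - half
    newE <- mid + (width - half)
    clipped <- newS < 0
    newS[clipped] <- 0L
    out <- GenomicRanges::GRanges(GenomicRanges::seqnames(merged),
                                  IRanges::IRanges(newS + 1L, newE))
    S4Vectors::mcols(out)$clipped <- clipped
    out <- unique(GenomicRanges::sort(out, ignore.strand = TRUE))
    out
}

#' Input-normalized H3K27ac enrichment over regions
#'
#' Counts are converted to RPKM (`count / (width_kb * libsize_millions)`)
#' for the ChIP and input libraries and the region x timepoint
#' enrichment is `log2((RPKM_chip + c) / (RPKM_input + c))` with
#' pseudocount `c`.
#'
#' @param chipCounts,inputCounts regions x timepoints matrices of
#'   non-negative read counts.
#' @param regionWidths region widths in bp (> 0).
#' @param chipLibSize,inputLibSize per-timepoint library sizes (> 0).
#' @param pseudocount RPKM pseudocount `c` (default 0.5).
#' @return A regions x timepoints matrix of log2 enrichments.
#' @export
chipEnrichment <- function(chipCounts, inputCounts, regionWidths,
                           chipLibSize, inputLibSize, pseudocount = 0.5) {
    chipCounts <- as.matrix(chipCounts)
    inputCounts <- as.matrix(inputCounts)
    if (any(regionWidths <= 0)) stop("region widths must be positive")
    if (any(chipLibSize <= 0) || any(inputLibSize <= 0))
        stop("library sizes must be positive")
    wkb <- regionWidths / 1000
    rpkmChip <- sweep(chipCounts / wkb, 2, chipLibSize / 1e6, "/")
    rpkmInput <- sweep(inputCounts / wkb, 2, inputLibSize / 1e6, "/")
    log2((rpkmChip + pseudocount) / (rpkmInput + pseudocount))
}

## distance in the base-to-base sense: 0 when ranges overlap, otherwise
## the difference between the closest included bases (GRanges gap + 1)
.baseDistanceToNearest <- function(query, subject) {
    hits <- GenomicRanges::distanceToNearest(query, subject,
                                             ignore.strand = TRUE)
    d <- rep(NA_real_, length(query))
    gap <- S4Vectors::mcols(hits)$distance
    d[S4Vectors::queryHits(hits)] <- ifelse(gap == 0, 0, gap + 1)
    ## adjacent ranges have GRanges gap 0 but base distance 1; detect overlap
    ov <- GenomicRanges::countOverlaps(query, subject, ignore.strand = TRUE) > 0
    adj <- !ov & !is.na(d) & d == 0
    d[adj] <- 1
    d
}

#' Select candidate CHD enhancers
#'
#' Applies the prioritization chain: (1) activity gate - keep regions
#' whose maximum enrichment across timepoints is strictly greater than
#' `threshold`; (2) variant gate - keep regions whose base-to-base
#' distance to the nearest variant is at most `variantWindow`
#' (0 when overlapping); (3) gene gate - keep regions within
#' `geneWindow` of a gene-body interval.
#'
#' @param regions a `GRanges` of fixed-width regions.
#' @param enrichment regions x timepoints matrix from [chipEnrichment()].
#' @param threshold activity threshold in log2 units (default
#'   `log2(1.5)`), strict.
#' @param variants a `GRanges` of variant positions (non-empty).
#' @param variantWindow maximum distance to a variant in bp (default
#'   1000), inclusive.
#' @param genes a `GRanges` of gene bodies with a `name` metadata column
#'   (non-empty).
#' @param geneWindow maximum distance to a gene in bp (default 100000),
#'   inclusive.
#' @return A `GRanges` of candidates with metadata `max_enrichment`,
#'   `nearest_variant_distance` and `linked_genes` (comma-separated).
#' @export
selectCandidates <- function(regions, enrichment, threshold = log2(1.5),
                             variants, variantWindow = 1000,
                             genes, geneWindow = 100000) {
    if (length(regions) != nrow(as.matrix(enrichment)))
        stop("enrichment matrix must align with regions")
    if (!length(variants)) stop("variant list is empty; filter undefined")
    if (!length(genes)) stop("gene list is empty; filter undefined")
    maxEnr <- apply(as.matrix(enrichment), 1, max)
    keep <- maxEnr > threshold
    cand <- regions[keep]
    candEnr <- maxEnr[keep]
    if (!length(cand)) return(cand)
    dv <- .baseDistanceToNearest(cand, variants)
    keep2 <- !is.na(dv) & dv <= variantWindow
    cand <- cand[keep2]; candEnr <- candEnr[keep2]; dv <- dv[keep2]
    if (!length(cand)) return(cand)
    hits <- GenomicRanges::findOverlaps(cand, genes,
                                        maxgap = max(geneWindow - 1, 0),
                                        ignore.strand = TRUE)
    geneNames <- S4Vectors::mcols(genes)$name
    if (is.null(geneNames)) geneNames <- as.character(seq_along(genes))
    linked <- rep("", length(cand))
    sp <- split(geneNames[S4Vectors::subjectHits(hits)],
                factor(S4Vectors::queryHits(hits), levels = seq_along(cand)))
    linked <- vapply(sp, function(g) paste(sort(unique(g)), collapse = ","), "")
    keep3 <- lengths(sp) > 0
    out <- cand[keep3]
    S4Vectors::mcols(out)$max_enrichment <- candEnr[keep3]
    S4Vectors::mcols(out)$nearest_variant_distance <- dv[keep3]
    S4Vectors::mcols(out)$linked_genes <- unname(linked[keep3])
    out
}
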