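#' Knee (inflection) rank of a descending UMI curve
#'
#' Given per-cell UMI counts for one feature, sorted in descending order,
#' locates the knee of the cumulative saturation curve: the normalized
#' curve (x = rank / n, y = cumulative UMIs / total) is compared with the
#' chord joining its first and last points, and the 1-based rank with the
#' maximum perpendicular distance to that chord is returned. Ties are
#' broken toward the earliest rank. Only strictly positive counts enter
#' the curve; zero-count cells can never be called.
#'
#' @param counts numeric vector of per-cell UMIs for one feature, sorted
#'   descending.
#' @return The 1-based knee rank, or `NA_integer_` when all counts are
#'   zero (no knee; the feature is skipped by callers).
#' @examples
#' kneeIndex(c(100, 90, 80, 5, 4, 3, 2, 1))  # 3
#' @export
kneeIndex <- function(counts) {
    if (is.unsorted(rev(counts))) stop("counts must be sorted descending")
    m <- sum(counts > 0)
    if (m == 0) return(NA_integer_)
    if (m == 1) return(1L)
    y <- cumsum(counts[seq_len(m)]) / sum(counts[seq_len(m)])
    x <- seq_len(m) / m
    dx <- x[m] - x[1]
    dy <- y[m] - y[1]
    d <- abs(dy * x - dx * y + x[m] * y[1] - y[m] * x[1]) / sqrt(dx^2 + dy^2)
    ## earliest rank wins ties, up to numerical tolerance on the distance
    which(d >= max(d) - 1e-9)[1]
}

#' Assign sgRNAs to cells by saturation-curve thresholding
#'
#' For each guide independently, cells are sorted by raw UMI count
#' (descending, ties broken by lexicographic barcode order), the knee rank
#' of the cumulative curve is computed with [kneeIndex()], and UMIs of
#' cells past the knee are set to zero. A guide is called in a cell
#' exactly when its adjusted UMI count is greater than 0.
#'
#' @param guideUmis a [CountMatrix-class] of cells x guides.
#' @param library a [GuideLibrary-class]; every guide feature must appear
#'   in it.
#' @return A [GuideAssignment-class].
#' @export
assignGuides <- function(guideUmis, library) {
    stopifnot(is(guideUmis, "CountMatrix"), is(library, "GuideLibrary"))
    missing <- setdiff(featureIds(guideUmis), guideIds(library))
    if (length(missing))
        stop("guides absent from library: ", paste(missing, collapse = ", "))
    adj <- .kneeAdjust(guideUmis)
    new("GuideAssignment", adjusted = adj$adjusted, kneeReport = adj$report)
}

.kneeAdjust <- function(cm) {
    raw <- as.matrix(umiCounts(cm))
    bc <- rownames(raw)
    adjusted <- matrix(0, nrow(raw), ncol(raw), dimnames = dimnames(raw))
    report <- data.frame(guide = colnames(raw),
                         knee_rank = NA_integer_,
                         cells_called = 0L, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(raw))) {
        v <- raw[, j]
        ord <- order(-v, bc)
        r <- kneeIndex(v[ord])
        if (is.na(r)) next
        keep <- ord[seq_len(r)]
        adjusted[keep, j] <- v[keep]
        report$knee_rank[j] <- r
        report$cells_called[j] <- sum(v[keep] > 0)
    }
    list(adjusted = Matrix(adjusted, sparse = TRUE), report = report)
}

#' Hashing-tag singlet assignment
#'
#' Applies the same saturation-curve knee procedure to each hashing
#' antibody tag, then retains only cells in which exactly one tag is
#' called (singlets), labeled with that tag. Cells with zero or two or
#' more called tags are dropped; their counts are attached as attributes
#' `n_unlabeled` and `n_multiplet`.
#'
#' @param hashUmis a [CountMatrix-class] of cells x hash tags.
#' @return Named character vector mapping retained cell barcodes to their
#'   hash label.
#' @export
assignHashSinglets <- function(hashUmis) {
    stopifnot(is(hashUmis, "CountMatrix"))
    if (ncol(umiCounts(hashUmis)) < 1) stop("need at least one hash feature")
    adj <- .kneeAdjust(hashUmis)$adjusted
    ncalls <- Matrix::rowSums(adj > 0)
    singlet <- ncalls == 1
    labels <- if (any(singlet))
        colnames(adj)[apply(as.matrix(adj[singlet, , drop = FALSE]) > 0,
                            1, which.max)]
    else character()
    out <- stats::setNames(labels, rownames(adj)[singlet])
    attr(out, "n_unlabeled") <- sum(ncalls == 0)
    attr(out, "n_multiplet") <- sum(ncalls >= 2)
    out
}

#' Drop cells without a detected sgRNA
#'
#' Cells in which no guide could be called carry no usable perturbation
#' label and are removed from the screen.
#'
#' @param assignment a [GuideAssignment-class].
#' @return Character vector of barcodes with at least one called guide.
#' @export
dropUnassignedCells <- function(assignment) {
    stopifnot(is(assignment, "GuideAssignment"))
    rownames(assignment@adjusted)[Matrix::rowSums(assignment@adjusted > 0) > 0]
}
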