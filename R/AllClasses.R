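#' @import methods
#' @importFrom Matrix Matrix sparseMatrix readMM writeMM t colSums rowSums
#' @importClassesFrom Matrix Matrix
#' @importFrom stats setNames
NULL

setClassUnion("matrixOrMatrix", c("matrix", "Matrix"))

#' CountMatrix: cells x features UMI counts
#'
#' A thin container for a non-negative integer UMI count matrix with cell
#' barcodes as rows and feature identifiers (genes, sgRNAs or hashing tags)
#' as columns. The matrix may be dense or sparse ([Matrix::Matrix]); all
#' constructors in this package produce sparse `dgCMatrix` storage.
#'
#' @slot counts cells x features matrix of non-negative integral values,
#'   with rownames (barcodes) and colnames (feature identifiers) set.
#'
#' @seealso [CountMatrix()], [readCountTriplet()], [writeCountTriplet()]
#' @export
setClass("CountMatrix", representation(counts = "matrixOrMatrix"))

setValidity("CountMatrix", function(object) {
    m <- object@counts
    msg <- character()
    if ((is.null(rownames(m)) && nrow(m) > 0) ||
        (is.null(colnames(m)) && ncol(m) > 0))
        msg <- c(msg, "counts must carry barcode rownames and feature colnames")
    else {
        if (anyDuplicated(rownames(m)))
            msg <- c(msg, "barcodes must be unique")
        if (anyDuplicated(colnames(m)))
            msg <- c(msg, "feature identifiers must be unique")
    }
    v <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
    if (length(v) && (any(v < 0) || any(v != floor(v))))
        msg <- c(msg, "counts must be non-negative integers")
    if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts a matrix or Matrix of non-negative integer UMI counts,
#'   cells in rows and features in columns.
#' @param barcodes,features optional character vectors overriding the
#'   dimnames of `counts`.
#' @return A [CountMatrix-class] object with sparse storage.
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 3L), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("g1", "g2")))
#' CountMatrix(m)
#' @export
CountMatrix <- function(counts, barcodes = NULL, features = NULL) {
    if (!is.null(barcodes)) rownames(counts) <- barcodes
    if (!is.null(features)) colnames(counts) <- features
    dn <- dimnames(counts)
    counts <- as(as(as(Matrix(counts, sparse = TRUE), "dMatrix"),
                    "generalMatrix"), "CsparseMatrix")
    dimnames(counts) <- dn   # zero-extent dimnames survive the coercion
    new("CountMatrix", counts = counts)
}

#' GuideLibrary: sgRNA to target mapping
#'
#' Maps each sgRNA to its target element and target class. Classes follow
#' the screen design: `enhancer` and `promoter` guides silence a genomic
#' element through dCas9-KRAB; `non_targeting` (NT) guides have no genomic
#' target and define the control background.
#'
#' @slot table data.frame with columns `guide_id`, `target_id`, `class`
#'   (one of enhancer/promoter/non_targeting) and optional `gene`.
#' @export
setClass("GuideLibrary", representation(table = "data.frame"))

.GUIDE_CLASSES <- c("enhancer", "promoter", "non_targeting")

setValidity("GuideLibrary", function(object) {
    tab <- object@table
    msg <- character()
    need <- c("guide_id", "target_id", "class")
    if (!all(need %in% names(tab)))
        return(paste("library table needs columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(tab$guide_id))
        msg <- c(msg, "guide ids must be unique")
    if (!all(tab$class %in% .GUIDE_CLASSES))
        msg <- c(msg, paste("class must be one of:", paste(.GUIDE_CLASSES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a GuideLibrary from a data.frame
#'
#' @param table data.frame with columns `guide_id`, `target_id`, `class`
#'   and optionally `gene`.
#' @return A [GuideLibrary-class].
#' @export
GuideLibrary <- function(table) {
    table <- as.data.frame(table, stringsAsFactors = FALSE)
    if (!"gene" %in% names(table)) table$gene <- NA_character_
    rownames(table) <- NULL
    new("GuideLibrary", table = table[, c("guide_id", "target_id", "class", "gene")])
}

#' GuideAssignment: per-cell sgRNA calls from knee thresholding
#'
#' Result of saturation-curve guide calling. `adjusted` holds the UMI
#' matrix after zeroing all entries past each guide's knee rank; a guide is
#' called in a cell exactly when its adjusted UMI is greater than 0.
#'
#' @slot adjusted cells x guides sparse matrix of adjusted UMI counts.
#' @slot kneeReport data.frame with one row per guide: `guide`,
#'   `knee_rank` (NA when the guide had no positive cell), `cells_called`.
#' @export
setClass("GuideAssignment",
         representation(adjusted = "matrixOrMatrix", kneeReport = "data.frame"))

setValidity("GuideAssignment", function(object) {
    if (!all(c("guide", "knee_rank", "cells_called") %in% names(object@kneeReport)))
        return("kneeReport needs columns guide, knee_rank, cells_called")
    TRUE
})

#' SimulationConfig: parameters of a synthetic screen
#'
#' Fully specifies a synthetic CRISPRi screen: cell number, trajectory
#' states and their baseline proportions, guide multiplicity (MOI), ambient
#' sgRNA background, per-target state-odds effects, marker-gene structure,
#' target-gene repression, mitochondrial content and hashing doublets.
#'
#' @slot nCells number of cells.
#' @slot clusterNames ordered trajectory state labels (early to late).
#' @slot clusterProportions baseline state probabilities, summing to 1.
#' @slot moi mean number of integrated guides per cell (Poisson mean).
#' @slot ambientRate mean ambient UMIs per (cell, guide) pair.
#' @slot carrierUmiMean mean UMIs of a truly carried guide; must exceed
#'   `ambientRate` so that the cumulative UMI curve has a knee.
#' @slot nTargets,guidesPerTarget,nNtGuides library design counts.
#' @slot effectTable named list: target id -> named positive numeric vector
#'   of multiplicative odds shifts per cluster (1 = no effect).
#' @slot markerGenesPerCluster marker genes elevated in each state.
#' @slot targetGeneRepression fraction in [0,1] by which a target's linked
#'   gene is repressed in carrier cells.
#' @slot mitoMean,mitoSd mean/sd of the per-cell mitochondrial fraction.
#' @slot doubletRate fraction of cells given a second hashing tag.
#' @slot seed integer seed; identical config + seed gives identical output.
#' @export
setClass("SimulationConfig", representation(
    nCells = "integer", clusterNames = "character",
    clusterProportions = "numeric", moi = "numeric", ambientRate = "numeric",
    carrierUmiMean = "numeric", nTargets = "integer",
    guidesPerTarget = "integer", nNtGuides = "integer", effectTable = "list",
    markerGenesPerCluster = "integer", targetGeneRepression = "numeric",
    mitoMean = "numeric", mitoSd = "numeric", doubletRate = "numeric",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    p <- object@clusterProportions
    if (length(p) != length(object@clusterNames))
        msg <- c(msg, "clusterProportions must match clusterNames in length")
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
        msg <- c(msg, "clusterProportions must be non-negative and sum to 1")
    if (object@nCells < 0) msg <- c(msg, "nCells must be non-negative")
    if (object@moi <= 0) msg <- c(msg, "moi must be positive")
    if (object@ambientRate < 0) msg <- c(msg, "ambientRate must be non-negative")
    if (object@carrierUmiMean <= object@ambientRate)
        msg <- c(msg, "carrierUmiMean must exceed ambientRate (no knee otherwise)")
    if (object@targetGeneRepression < 0 || object@targetGeneRepression > 1)
        msg <- c(msg, "targetGeneRepression must lie in [0,1]")
    if (object@doubletRate < 0 || object@doubletRate > 1)
        msg <- c(msg, "doubletRate must lie in [0,1]")
    for (tgt in names(object@effectTable)) {
        ef <- object@effectTable[[tgt]]
        if (any(ef <= 0))
            msg <- c(msg, sprintf("effect shifts for %s must be strictly positive", tgt))
        if (!all(names(ef) %in% object@clusterNames))
            msg <- c(msg, sprintf("effect table for %s names unknown clusters", tgt))
    }
    if (length(msg)) msg else TRUE
})

#' SyntheticScreen: a simulated CRISPRi screen with ground truth
#'
#' @slot expression,guideUmis,hashUmis [CountMatrix-class] objects sharing
#'   one ordered barcode list.
#' @slot truthGuides per-cell list of truly carried guide ids.
#' @slot truthStates per-cell state label.
#' @slot truthPseudotime per-cell 0-based integer pseudotime rank, unique
#'   across cells.
#' @slot library the [GuideLibrary-class] used.
#' @slot config the generating [SimulationConfig-class].
#' @export
setClass("SyntheticScreen", representation(
    expression = "CountMatrix", guideUmis = "CountMatrix",
    hashUmis = "CountMatrix", truthGuides = "list", truthStates = "character",
    truthPseudotime = "integer", library = "GuideLibrary",
    config = "SimulationConfig"))

setValidity("SyntheticScreen", function(object) {
    msg <- character()
    bc <- rownames(object@expression@counts)
    if (!identical(bc, rownames(object@guideUmis@counts)) ||
        !identical(bc, rownames(object@hashUmis@counts)))
        msg <- c(msg, "all matrices must share one ordered barcode list")
    if (length(object@truthGuides) != length(bc) ||
        length(object@truthStates) != length(bc) ||
        length(object@truthPseudotime) != length(bc))
        msg <- c(msg, "truth vectors must have one entry per cell")
    gl <- object@library@table$guide_id
    if (!all(unlist(object@truthGuides) %in% gl))
        msg <- c(msg, "every truth guide must appear in the library")
    pt <- object@truthPseudotime
    if (length(pt) && (anyDuplicated(pt) || any(pt < 0) || any(pt >= length(pt))))
        msg <- c(msg, "pseudotime ranks must be unique integers in [0, nCells)")
    if (length(msg)) msg else TRUE
})

#' ExpressionLayers: raw, log and scaled expression
#'
#' Layers used by all downstream statistics: the raw UMI counts, the
#' natural-log layer `ln(1 + raw)`, and the per-gene standardized layer
#' (zero mean, unit population variance over the retained cells; constant
#' genes are set to all-zero).
#'
#' @slot raw [CountMatrix-class] of retained cells x retained genes.
#' @slot logLayer dense matrix, `log(1 + raw)` entrywise.
#' @slot scaled dense matrix, per-gene standardized `logLayer`.
#' @export
setClass("ExpressionLayers", representation(
    raw = "CountMatrix", logLayer = "matrix", scaled = "matrix"))

setValidity("ExpressionLayers", function(object) {
    if (!identical(dim(object@raw@counts), dim(object@logLayer)) ||
        !identical(dim(object@raw@counts), dim(object@scaled)))
        return("raw, log and scaled layers must share dimensions")
    TRUE
})
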