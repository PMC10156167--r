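#' @rdname CountMatrix-class
#' @export
setMethod("barcodes", "CountMatrix", function(x)
    rownames(x@counts) %||% character())

#' @rdname CountMatrix-class
#' @export
setMethod("featureIds", "CountMatrix", function(x)
    colnames(x@counts) %||% character())

#' @rdname CountMatrix-class
#' @export
setMethod("umiCounts", "CountMatrix", function(x) x@counts)

#' @rdname CountMatrix-class
#' @param object a CountMatrix.
#' @export
setMethod("show", "CountMatrix", function(object) {
    d <- dim(object@counts)
    nz <- if (inherits(object@counts, "sparseMatrix"))
        length(object@counts@x) else sum(object@counts != 0)
    cat(sprintf("CountMatrix: %d cells x %d features (%d nonzero entries)\n",
                d[1], d[2], nz))
})

setMethod("dim", "CountMatrix", function(x) dim(x@counts))

#' Subset a CountMatrix by barcode and/or feature
#'
#' @param x a CountMatrix.
#' @param i,j barcode and feature selectors (indices or names).
#' @param ... ignored.
#' @param drop ignored; the result is always a CountMatrix.
#' @export
setMethod("[", "CountMatrix", function(x, i, j, ..., drop = FALSE) {
    m <- x@counts
    if (!missing(i)) m <- m[i, , drop = FALSE]
    if (!missing(j)) m <- m[, j, drop = FALSE]
    new("CountMatrix", counts = m)
})

#' @rdname GuideLibrary-class
#' @export
setMethod("guideIds", "GuideLibrary", function(x) x@table$guide_id)

#' @rdname GuideLibrary-class
#' @export
setMethod("targetIds", "GuideLibrary", function(x)
    unique(x@table$target_id[x@table$class != "non_targeting"]))

#' @rdname GuideLibrary-class
#' @export
setMethod("ntGuides", "GuideLibrary", function(x)
    x@table$guide_id[x@table$class == "non_targeting"])

#' @rdname GuideLibrary-class
#' @export
setMethod("guidesForTarget", "GuideLibrary", function(x, target)
    x@table$guide_id[x@table$target_id == target])

#' @rdname GuideLibrary-class
#' @param object a GuideLibrary.
#' @export
setMethod("show", "GuideLibrary", function(object) {
    tab <- object@table
    cat(sprintf("GuideLibrary: %d guides, %d targets, %d non-targeting\n",
                nrow(tab), length(unique(tab$target_id[tab$class != "non_targeting"])),
                sum(tab$class == "non_targeting")))
})

#' @rdname GuideLibrary-class
#' @param x a GuideLibrary.
#' @export
libraryTable <- function(x) x@table

#' @rdname GuideAssignment-class
#' @export
setMethod("assignmentTable", "GuideAssignment", function(x) {
    m <- as(x@adjusted, "TsparseMatrix")
    ord <- order(m@j, m@i)
    data.frame(cell = rownames(m)[m@i[ord] + 1L],
               guide = colnames(m)[m@j[ord] + 1L],
               adjusted_umi = as.integer(m@x[ord]),
               stringsAsFactors = FALSE)
})

#' @rdname GuideAssignment-class
#' @export
setMethod("kneeReport", "GuideAssignment", function(x) x@kneeReport)

#' @rdname GuideAssignment-class
#' @export
setMethod("cellsWithGuide", "GuideAssignment", function(x, guides) {
    guides <- intersect(guides, colnames(x@adjusted))
    if (!length(guides)) return(character())
    sub <- x@adjusted[, guides, drop = FALSE]
    rownames(sub)[Matrix::rowSums(sub > 0) > 0]
})

#' @rdname GuideAssignment-class
#' @export
setMethod("calledGuides", "GuideAssignment", function(x) {
    m <- as(x@adjusted, "TsparseMatrix")
    res <- split(colnames(m)[m@j + 1L], factor(rownames(m)[m@i + 1L],
                                               levels = rownames(m)))
    lapply(res, sort)
})

#' @rdname GuideAssignment-class
#' @param object a GuideAssignment.
#' @export
setMethod("show", "GuideAssignment", function(object) {
    ncalled <- sum(Matrix::rowSums(object@adjusted > 0) > 0)
    cat(sprintf("GuideAssignment: %d guides over %d cells (%d cells with >=1 call)\n",
                ncol(object@adjusted), nrow(object@adjusted), ncalled))
})

#' @rdname SyntheticScreen-class
#' @param object a SyntheticScreen.
#' @export
setMethod("show", "SyntheticScreen", function(object) {
    cat(sprintf(paste0("SyntheticScreen: %d cells, %d genes, %d guides, ",
                       "%d hash tags\nstates: %s\n"),
                nrow(object@expression@counts), ncol(object@expression@counts),
                ncol(object@guideUmis@counts), ncol(object@hashUmis@counts),
                paste(object@config@clusterNames, collapse = " < ")))
})

#' @rdname SimulationConfig-class
#' @param object a SimulationConfig.
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0("SimulationConfig: %d cells, MOI %.2f, %d targets x %d ",
                       "guides + %d NT, seed %d\n"),
                object@nCells, object@moi, object@nTargets,
                object@guidesPerTarget, object@nNtGuides, object@seed))
})
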