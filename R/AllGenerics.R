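#' @rdname CountMatrix-class
#' @param x a CountMatrix (or object with cells).
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname CountMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname CountMatrix-class
#' @export
setGeneric("umiCounts", function(x) standardGeneric("umiCounts"))

#' @rdname GuideLibrary-class
#' @param x a GuideLibrary.
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))

#' @rdname GuideLibrary-class
#' @export
setGeneric("ntGuides", function(x) standardGeneric("ntGuides"))

#' @rdname GuideLibrary-class
#' @param target a target id.
#' @export
setGeneric("guidesForTarget", function(x, target) standardGeneric("guidesForTarget"))

#' @rdname GuideAssignment-class
#' @param x a GuideAssignment.
#' @export
setGeneric("assignmentTable", function(x) standardGeneric("assignmentTable"))

#' @rdname GuideAssignment-class
#' @export
setGeneric("kneeReport", function(x) standardGeneric("kneeReport"))

#' @rdname GuideAssignment-class
#' @param guides character vector of guide ids.
#' @export
setGeneric("cellsWithGuide", function(x, guides) standardGeneric("cellsWithGuide"))

#' @rdname GuideAssignment-class
#' @export
setGeneric("calledGuides", function(x) standardGeneric("calledGuides"))
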