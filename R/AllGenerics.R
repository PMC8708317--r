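#' @rdname TEAnnotation-class
#' @param x,object an object of the documented class.
#' @param ... further arguments (unused).
#' @export
setGeneric("teLoci", function(x, ...) standardGeneric("teLoci"))

#' @rdname TEAnnotation-class
#' @export
setGeneric("locusIds", function(x, ...) standardGeneric("locusIds"))

#' @rdname TEAnnotation-class
#' @export
setGeneric("teTaxonomy", function(x, ...) standardGeneric("teTaxonomy"))

#' @rdname TEAnnotation-class
#' @param query a `GRanges` of query intervals.
#' @export
setGeneric("queryLoci", function(x, query, ...) standardGeneric("queryLoci"))

#' @rdname SpotAlignments-class
#' @export
setGeneric("readIds", function(x, ...) standardGeneric("readIds"))

#' @rdname SpotAlignments-class
#' @export
setGeneric("nHits", function(x, ...) standardGeneric("nHits"))

#' @rdname SpotAlignments-class
#' @export
setGeneric("spotLabels", function(x, ...) standardGeneric("spotLabels"))

#' @rdname SpotAlignments-class
#' @export
setGeneric("mappingStatus", function(x, ...) standardGeneric("mappingStatus"))

#' @rdname SpotAlignments-class
#' @export
setGeneric("readLog", function(x, ...) standardGeneric("readLog"))

#' @rdname SpotMatrix-class
#' @export
setGeneric("featureIds", function(x, ...) standardGeneric("featureIds"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truthReads", function(x, ...) standardGeneric("truthReads"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truthLocusCounts", function(x, ...)
  standardGeneric("truthLocusCounts"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truthSubfamilyCounts", function(x, ...)
  standardGeneric("truthSubfamilyCounts"))
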