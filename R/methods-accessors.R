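## Accessors and show methods.

#' @rdname TEAnnotation-class
#' @export
setMethod("teLoci", "TEAnnotation", function(x, ...) x@loci)

#' @rdname TEAnnotation-class
#' @export
setMethod("locusIds", "TEAnnotation", function(x, ...)
  mcols(x@loci)$locus_id)

#' @describeIn TEAnnotation-class unique subfamily -> (family, te_class)
#'   lookup as a data.frame.
#' @export
setMethod("teTaxonomy", "TEAnnotation", function(x, ...) {
  m <- as.data.frame(mcols(x@loci)[, c("subfamily", "family", "te_class")])
  unique(m)
})

#' @describeIn TEAnnotation-class subset to loci overlapping `query` by at
#'   least one base (results identical to a linear scan).
#' @export
setMethod("queryLoci", "TEAnnotation", function(x, query, ...) {
  stopifnot(is(query, "GRanges"))
  hits <- findOverlaps(x@loci, query, minoverlap = 1L, ignore.strand = TRUE)
  initialize(x, loci = x@loci[sort(unique(queryHits(hits)))])
})

#' @rdname TEAnnotation-class
#' @export
setMethod("length", "TEAnnotation", function(x) length(x@loci))

setMethod("show", "TEAnnotation", function(object) {
  cls <- table(factor(mcols(object@loci)$te_class, levels = TE_CLASSES))
  cat("TEAnnotation with", length(object@loci), "loci,",
      length(unique(mcols(object@loci)$subfamily)), "subfamilies\n")
  cat("  classes:", paste(names(cls), cls, sep = "=", collapse = " "), "\n")
})

#' @rdname BarcodeMap-class
#' @param x,object a `BarcodeMap`.
#' @export
setMethod("length", "BarcodeMap", function(x) length(x@barcode))

#' @describeIn BarcodeMap-class resolve one or more barcodes to spot
#'   labels; unknown barcodes are an error.
#' @param barcodes character vector of barcode sequences.
#' @export
spotForBarcode <- function(x, barcodes) {
  stopifnot(is(x, "BarcodeMap"))
  idx <- match(barcodes, x@barcode)
  if (anyNA(idx))
    stop("unknown barcode(s): ",
         paste(head(barcodes[is.na(idx)], 5L), collapse = ", "))
  x@spot[idx]
}

setMethod("show", "BarcodeMap", function(object) {
  cat("BarcodeMap with", length(object@barcode), "barcodes (",
      sum(object@inTissue), "in tissue )\n")
})

#' @rdname SpotAlignments-class
#' @param x,object a `SpotAlignments`.
#' @export
setMethod("length", "SpotAlignments", function(x) length(x@blocks))

#' @rdname SpotAlignments-class
#' @export
setMethod("readIds", "SpotAlignments", function(x, ...) x@readId)

#' @rdname SpotAlignments-class
#' @export
setMethod("nHits", "SpotAlignments", function(x, ...) x@nHits)

#' @rdname SpotAlignments-class
#' @export
setMethod("spotLabels", "SpotAlignments", function(x, ...) x@spot)

#' @describeIn SpotAlignments-class classify each read as `"unique"` or
#'   `"multi"`: unique iff the reported hit count is 1; when no hit-count
#'   tag was present, fall back to the aligner's unique-MAPQ convention
#'   (default: MAPQ 255 means unique).
#' @export
setMethod("mappingStatus", "SpotAlignments", function(x, ...) {
  st <- ifelse(x@nHits == 1L, "unique", "multi")
  fb <- is.na(x@nHits)
  st[fb] <- ifelse(x@mapq[fb] == x@uniqueMapq, "unique", "multi")
  st
})

#' @rdname SpotAlignments-class
#' @export
setMethod("readLog", "SpotAlignments", function(x, ...) x@log)

setMethod("show", "SpotAlignments", function(object) {
  st <- mappingStatus(object)
  cat("SpotAlignments:", length(object), "reads across",
      length(unique(object@spot)), "spots (",
      sum(st == "unique"), "unique /", sum(st == "multi"), "multi )\n")
})

#' Construct quantification parameters
#'
#' Thresholds controlling TE filtering and partitioning; see
#' [QuantParams-class] for the meaning and defaults of each.
#'
#' @param coverageMin minimum pooled coverage percentage (default 0).
#' @param msLocusMin minimum mapping score for locus resolution
#'   (default 100).
#' @param msSubfamilyMax maximum mapping score for subfamily resolution
#'   (default 0).
#' @param minOverlapBases minimum read/locus overlap in bases (default 1).
#' @return a validated [QuantParams-class] object.
#' @examples
#' quantParams()
#' quantParams(coverageMin = 50, msLocusMin = 90, msSubfamilyMax = 10)
#' @export
quantParams <- function(coverageMin = 0, msLocusMin = 100,
                        msSubfamilyMax = 0, minOverlapBases = 1L) {
  new("QuantParams", coverageMin = as.numeric(coverageMin),
      msLocusMin = as.numeric(msLocusMin),
      msSubfamilyMax = as.numeric(msSubfamilyMax),
      minOverlapBases = as.integer(minOverlapBases))
}

setMethod("show", "QuantParams", function(object) {
  cat("QuantParams: coverageMin=", object@coverageMin,
      " msLocusMin=", object@msLocusMin,
      " msSubfamilyMax=", object@msSubfamilyMax,
      " minOverlapBases=", object@minOverlapBases, "\n", sep = "")
})

#' @rdname SpotMatrix-class
#' @param x,object a `SpotMatrix`.
#' @export
setMethod("spotLabels", "SpotMatrix", function(x, ...) rownames(x@counts))

#' @rdname SpotMatrix-class
#' @export
setMethod("featureIds", "SpotMatrix", function(x, ...) colnames(x@counts))

#' @describeIn SpotMatrix-class the raw count matrix (spots in rows),
#'   via the standard `BiocGenerics::counts` generic.
#' @export
setMethod("counts", "SpotMatrix", function(object, ...) object@counts)

#' @rdname SpotMatrix-class
#' @export
setMethod("dim", "SpotMatrix", function(x) dim(x@counts))

setMethod("show", "SpotMatrix", function(object) {
  cat("SpotMatrix (", object@featureType, "): ",
      nrow(object@counts), " spots x ", ncol(object@counts),
      " features, total ", sum(object@counts), "\n", sep = "")
})

#' @rdname GroundTruth-class
#' @param x,object a `GroundTruth`.
#' @export
setMethod("truthReads", "GroundTruth", function(x, ...) x@reads)

#' @describeIn GroundTruth-class true read counts per (spot, locus) as a
#'   data.frame with columns `spot`, `locus_id`, `n`.
#' @export
setMethod("truthLocusCounts", "GroundTruth", function(x, ...) {
  dt <- as.data.table(as.data.frame(x@reads))
  as.data.frame(dt[, .(n = .N), by = .(spot, locus_id)])
})

#' @describeIn GroundTruth-class true read counts per (spot, subfamily);
#'   by construction these are the locus-level truth summed over
#'   subfamily members, so the marginals are always consistent.
#' @export
setMethod("truthSubfamilyCounts", "GroundTruth", function(x, ...) {
  dt <- as.data.table(as.data.frame(x@reads))
  as.data.frame(dt[, .(n = .N), by = .(spot, subfamily)])
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@reads), "reads,",
      length(unique(object@reads$spot)), "spots,",
      length(unique(object@reads$locus_id)), "loci\n")
})

setMethod("show", "BenchmarkReport", function(object) {
  cat("BenchmarkReport\n",
      "  spot-misassigned reads:        ", object@spotMisassignedReads, "\n",
      "  locus-level correlation:       ",
      round(object@locusCorrelation, 4), "\n",
      "  subfamily-level correlation:   ",
      round(object@subfamilyCorrelation, 4), "\n",
      "  reads misassigned at locus (%):",
      round(object@fractionReadsMisassignedLocus, 2), "\n", sep = "")
})

setMethod("show", "TEGenome", function(object) {
  cat("TEGenome:", length(object@genome), "chromosomes,",
      length(object@annotation), "planted TE loci,",
      length(object@exons), "planted exons\n")
})
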