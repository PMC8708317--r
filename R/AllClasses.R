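## Central S4 classes. Coordinates are GRanges-native (1-based, closed);
## BED-convention conversion happens only when reading or writing files.

TE_CLASSES <- c("LINE", "SINE", "LTR", "DNA", "Other")

## RepeatMasker classes that are repeats but not transposable elements;
## dropped by default when parsing.
DEFAULT_EXCLUDED_CLASSES <- c(
  "Simple_repeat", "Low_complexity", "Satellite",
  "rRNA", "tRNA", "snRNA", "srpRNA", "scRNA"
)

#' TEAnnotation: an annotated set of transposable element loci
#'
#' Wraps a [GenomicRanges::GRanges] of TE loci whose metadata columns carry
#' the repeat taxonomy: `locus_id` (unique, human-readable,
#' `"subfamily|chrom:start-end(strand)"` with 1-based inclusive
#' coordinates), `subfamily` (RepeatMasker repeat name, e.g. `L1Md_F2`),
#' `family` (e.g. `L1`) and `te_class` (one of LINE, SINE, LTR, DNA,
#' Other). Overlap queries are served by [GenomicRanges::findOverlaps] on
#' the underlying ranges, so a query returns exactly the loci overlapping
#' it by at least one base.
#'
#' @slot loci `GRanges` with metadata columns `locus_id`, `subfamily`,
#'   `family`, `te_class`.
#' @seealso [readRepeatMasker()], [queryLoci()], [teTaxonomy()]
#' @export
setClass("TEAnnotation", representation(loci = "GRanges"))

setValidity("TEAnnotation", function(object) {
  g <- object@loci
  m <- mcols(g)
  need <- c("locus_id", "subfamily", "family", "te_class")
  if (!all(need %in% colnames(m)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(m)), collapse = ", ")))
  if (anyDuplicated(m$locus_id))
    return("locus_id values must be unique")
  if (length(g) && any(width(g) < 1L))
    return("all loci must have positive length")
  if (!all(m$te_class %in% TE_CLASSES))
    return(paste("te_class must be one of:", paste(TE_CLASSES, collapse = ", ")))
  if (length(g) && !all(as.character(strand(g)) %in% c("+", "-")))
    return("strand must be + or -")
  TRUE
})

#' BarcodeMap: spatial barcode to spot lookup
#'
#' An injective mapping from barcode sequence to spot grid coordinates.
#' Spot labels are canonical `"XxY"` strings (e.g. `"11x5"`); for
#' tissue-position tables (10X dialect) `x` is the array row and `y` the
#' array column. Out-of-tissue barcodes are retained but flagged so that
#' in-tissue filtering stays a downstream option.
#'
#' @slot barcode character, barcode sequences (unique).
#' @slot x,y integer grid coordinates.
#' @slot spot character, canonical `"XxY"` labels.
#' @slot inTissue logical flag per barcode.
#' @seealso [readBarcodeMap()]
#' @export
setClass("BarcodeMap", representation(
  barcode = "character", x = "integer", y = "integer",
  spot = "character", inTissue = "logical"
))

setValidity("BarcodeMap", function(object) {
  n <- length(object@barcode)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@spot) != n || length(object@inTissue) != n)
    return("all slots must have equal length")
  if (anyDuplicated(object@barcode))
    return("barcodes must be unique")
  TRUE
})

#' SpotAlignments: spot-resolved reads from a spatial alignment file
#'
#' One element per emitted read (alignment records sharing a read name are
#' folded together): the union of aligned genomic blocks across all of the
#' read's reported alignment locations, the number of reported hits, the
#' best MAPQ, and the resolved spot label. Reads whose spatial information
#' could not be resolved are not emitted; they are tallied in the `log`
#' slot so that read accounting stays auditable.
#'
#' @slot blocks `GRangesList`, one element per read: non-overlapping,
#'   ascending aligned blocks (union over all alignment locations).
#' @slot readId character read names.
#' @slot nHits integer number of reported alignments per read (>= 1);
#'   `NA` when no hit-count tag was present and only one record was seen
#'   (the MAPQ fallback decides uniqueness).
#' @slot mapq integer best MAPQ per read.
#' @slot spot character resolved spot label per read.
#' @slot umi character UMI per read (`NA` when absent).
#' @slot uniqueMapq integer, MAPQ value treated as "unique" when the
#'   hit-count tag is absent (aligner convention, default 255).
#' @slot log list of read-disposition tallies (records read, reads
#'   emitted, reads skipped for unresolvable spots, ...).
#' @seealso [readSpotAlignments()], [mappingStatus()], [filterNonExonic()]
#' @export
setClass("SpotAlignments", representation(
  blocks = "GRangesList", readId = "character", nHits = "integer",
  mapq = "integer", spot = "character", umi = "character",
  uniqueMapq = "integer", log = "list"
))

setValidity("SpotAlignments", function(object) {
  n <- length(object@blocks)
  if (length(object@readId) != n || length(object@nHits) != n ||
      length(object@mapq) != n || length(object@spot) != n ||
      length(object@umi) != n)
    return("per-read slots must have equal length")
  if (n && any(lengths(object@blocks) == 0L))
    return("every read must have at least one aligned block")
  if (n && any(!is.na(object@nHits) & object@nHits < 1L))
    return("nHits must be >= 1")
  if (anyDuplicated(object@readId))
    return("readId must be unique after record folding")
  TRUE
})

#' QuantParams: thresholds controlling TE quantification
#'
#' @slot coverageMin numeric percentage in `[0, 100]`; TE loci whose
#'   pooled read coverage is below this are dropped before partitioning.
#'   Default 0: everything with at least one read is reported.
#' @slot msLocusMin numeric percentage; loci with mapping score `>=` this
#'   are quantified at locus resolution. Default 100: only loci carrying
#'   exclusively uniquely mapped reads.
#' @slot msSubfamilyMax numeric percentage; loci with mapping score `<=`
#'   this are summarized at subfamily resolution. Default 0: only loci
#'   carrying exclusively multi-mapped reads.
#' @slot minOverlapBases integer, minimum total read/locus overlap (union
#'   over aligned blocks) for a read to be assigned to a locus. Default 1.
#' @seealso [quantParams()], [partitionTEs()]
#' @export
setClass("QuantParams", representation(
  coverageMin = "numeric", msLocusMin = "numeric",
  msSubfamilyMax = "numeric", minOverlapBases = "integer"
), prototype(
  coverageMin = 0, msLocusMin = 100, msSubfamilyMax = 0,
  minOverlapBases = 1L
))

setValidity("QuantParams", function(object) {
  if (length(object@coverageMin) != 1L || object@coverageMin < 0 ||
      object@coverageMin > 100)
    return("coverageMin must be a single value in [0, 100]")
  if (length(object@msLocusMin) != 1L || length(object@msSubfamilyMax) != 1L)
    return("msLocusMin and msSubfamilyMax must be single values")
  if (object@msSubfamilyMax < 0 || object@msLocusMin > 100 ||
      object@msSubfamilyMax > object@msLocusMin)
    return("need 0 <= msSubfamilyMax <= msLocusMin <= 100")
  if (length(object@minOverlapBases) != 1L || object@minOverlapBases < 1L)
    return("minOverlapBases must be a single integer >= 1")
  TRUE
})

#' SpotMatrix: counts indexed by (spot, feature)
#'
#' A dense matrix whose rows are spot labels (`"XxY"`) and whose columns
#' are feature identifiers: TE locus ids, subfamily names, or TE classes,
#' according to `featureType`. All-zero columns are never stored. Values
#' are non-negative; integer at locus/subfamily/class level, real after
#' [log2Normalize()].
#'
#' @slot counts numeric matrix with unique row and column names.
#' @slot featureType one of `"locus"`, `"subfamily"`, `"class"`.
#' @seealso [writeSpotMatrix()], [readSpotMatrix()]
#' @export
setClass("SpotMatrix", representation(
  counts = "matrix", featureType = "character"
))

setValidity("SpotMatrix", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("row (spot) labels must be present and unique")
  if (ncol(m) > 0L && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
    return("column (feature) labels must be present and unique")
  if (length(m) && any(m < 0))
    return("counts must be non-negative")
  if (ncol(m) > 0L && any(colSums(m) == 0))
    return("all-zero columns must not be stored")
  if (length(object@featureType) != 1L ||
      !object@featureType %in% c("locus", "subfamily", "class"))
    return("featureType must be 'locus', 'subfamily' or 'class'")
  TRUE
})

#' TEAssignments: read-to-locus assignments plus their provenance
#'
#' Produced by [assignTEReads()]; carries the per-(read, locus) assignment
#' table, the per-pair block/locus intersection intervals used for
#' coverage, and references to the inputs so downstream steps
#' ([teReadStats()], [quantifyByLocus()], [quantifyBySubfamily()]) need no
#' further arguments.
#'
#' @slot table `DataFrame` with columns `read_id`, `spot`, `status`
#'   (`unique`/`multi`), `locus_id`, `subfamily`, `te_class`, `overlap`
#'   (total overlapping bases).
#' @slot coverIntervals `DataFrame` of per-(read, locus) intersection
#'   intervals (`locus_id`, `istart`, `iend`, genomic, 1-based closed).
#' @slot reads the input [SpotAlignments-class].
#' @slot annotation the input [TEAnnotation-class].
#' @slot params the [QuantParams-class] used.
#' @export
setClass("TEAssignments", representation(
  table = "DataFrame", coverIntervals = "DataFrame",
  reads = "SpotAlignments", annotation = "TEAnnotation",
  params = "QuantParams"
))

#' GroundTruth: per-read provenance of a simulated spatial run
#'
#' @slot reads `DataFrame` with one row per simulated read: `read_id`,
#'   `spot` (true spot label), `locus_id` (true source locus),
#'   `subfamily`, `te_class`.
#' @seealso [simulateSpotReads()], [truthLocusCounts()],
#'   [truthSubfamilyCounts()]
#' @export
setClass("GroundTruth", representation(reads = "DataFrame"))

#' BenchmarkReport: accuracy of a quantification run against ground truth
#'
#' @slot spotMisassignedReads integer; reads counted at a spot other than
#'   their true spot (measured at subfamily resolution, which is robust to
#'   locus-level confusion between near-identical copies).
#' @slot locusCorrelation Pearson r between estimated and true
#'   (spot, locus) counts over the union of occupied cells.
#' @slot subfamilyCorrelation Pearson r at (spot, subfamily) level.
#' @slot fractionReadsMisassignedLocus percentage of reads whose
#'   locus-level assignment is not exactly their true source locus.
#' @seealso [evaluateBenchmark()], [runBenchmark()]
#' @export
setClass("BenchmarkReport", representation(
  spotMisassignedReads = "integer", locusCorrelation = "numeric",
  subfamilyCorrelation = "numeric",
  fractionReadsMisassignedLocus = "numeric"
))

setValidity("BenchmarkReport", function(object) {
  ok_r <- function(r) is.na(r) || (r >= -1 - 1e-12 && r <= 1 + 1e-12)
  if (!ok_r(object@locusCorrelation) || !ok_r(object@subfamilyCorrelation))
    return("correlations must lie in [-1, 1]")
  f <- object@fractionReadsMisassignedLocus
  if (!is.na(f) && (f < 0 || f > 100))
    return("fractionReadsMisassignedLocus must lie in [0, 100]")
  if (object@spotMisassignedReads < 0L)
    return("spotMisassignedReads must be >= 0")
  TRUE
})

#' GenomeSpec: plan for a synthetic TE mini-genome
#'
#' @slot nChroms,chromLength integer; number and length of background
#'   chromosomes.
#' @slot tePlan data.frame with columns `subfamily`, `family`, `te_class`,
#'   `n_copies`, `copy_length`, `divergence_pct`. Each subfamily gets a
#'   random consensus; copies are the consensus with substitutions at
#'   `divergence_pct` per 100 bases (old TEs: high divergence, separable;
#'   young TEs: <= 1 percent, near-identical).
#' @slot exonPlan data.frame of planted exon intervals (`chrom`, `start`,
#'   `end`, 1-based closed); TE copies are placed outside them.
#' @slot seed integer random seed making the genome reproducible.
#' @seealso [genomeSpec()], [simulateTEGenome()]
#' @export
setClass("GenomeSpec", representation(
  nChroms = "integer", chromLength = "integer", tePlan = "data.frame",
  exonPlan = "data.frame", seed = "integer"
))

setValidity("GenomeSpec", function(object) {
  p <- object@tePlan
  need <- c("subfamily", "family", "te_class", "n_copies", "copy_length",
            "divergence_pct")
  if (!all(need %in% colnames(p)))
    return(paste("tePlan must have columns:", paste(need, collapse = ", ")))
  if (any(p$divergence_pct < 0 | p$divergence_pct > 50))
    return("divergence_pct must lie in [0, 50]")
  if (any(p$n_copies < 1L) || any(p$copy_length < 10L))
    return("n_copies must be >= 1 and copy_length >= 10")
  if (anyDuplicated(p$subfamily))
    return("tePlan subfamilies must be unique")
  e <- object@exonPlan
  if (nrow(e) && !all(c("chrom", "start", "end") %in% colnames(e)))
    return("exonPlan must have columns chrom, start, end")
  TRUE
})

#' TEGenome: a realized synthetic mini-genome
#'
#' @slot genome `DNAStringSet` of chromosome sequences (TE copies written
#'   in place).
#' @slot annotation [TEAnnotation-class] of the planted loci, with exact
#'   coordinates.
#' @slot exons `GRanges` of planted exons.
#' @slot consensus `DNAStringSet`, one consensus per subfamily.
#' @slot spec the [GenomeSpec-class] that produced it.
#' @seealso [simulateTEGenome()], [writeTEGenome()]
#' @export
setClass("TEGenome", representation(
  genome = "DNAStringSet", annotation = "TEAnnotation", exons = "GRanges",
  consensus = "DNAStringSet", spec = "GenomeSpec"
))

#' SpotPlan: per-spot simulated read allocation
#'
#' @slot counts data.frame with columns `spot`, `locus_id`, `n_reads`:
#'   how many reads to draw from each planted locus at each spot.
#' @slot readLength integer read length in bases.
#' @slot errorRate numeric per-base sequencing error probability.
#' @slot seed integer random seed.
#' @seealso [spotPlan()], [randomSpotPlan()], [simulateSpotReads()]
#' @export
setClass("SpotPlan", representation(
  counts = "data.frame", readLength = "integer", errorRate = "numeric",
  seed = "integer"
))

setValidity("SpotPlan", function(object) {
  cc <- object@counts
  if (!all(c("spot", "locus_id", "n_reads") %in% colnames(cc)))
    return("counts must have columns spot, locus_id, n_reads")
  if (any(cc$n_reads < 0L))
    return("n_reads must be >= 0")
  if (object@errorRate < 0 || object@errorRate > 0.2)
    return("errorRate must lie in [0, 0.2]")
  if (!grepl("^[0-9]+x[0-9]+$", "1x1"))
    return("unreachable")
  if (length(cc$spot) && !all(grepl("^[0-9]+x[0-9]+$", cc$spot)))
    return("spot labels must be 'XxY'")
  TRUE
})
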