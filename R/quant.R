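## Core TE quantification: non-exonic restriction, read-to-locus
## assignment, coverage and mapping score, locus/subfamily partition and
## spot-by-feature count matrices.

#' Remove reads overlapping annotated exons
#'
#' A read is removed iff any of its aligned blocks — across all of its
#' reported alignment locations — overlaps any exon interval by at least
#' one base. One exonic hit is enough: for multi-mappers this is the
#' conservative choice against mRNA contamination. Everything retained is
#' by construction non-exonic.
#'
#' @param reads a [SpotAlignments-class].
#' @param exons reduced exon `GRanges` from [readExonAnnotation()].
#' @return the filtered [SpotAlignments-class]; the removal count is
#'   appended to its log as `exonicRemoved`.
#' @export
filterNonExonic <- function(reads, exons) {
  stopifnot(is(reads, "SpotAlignments"), is(exons, "GRanges"))
  hits <- countOverlaps(reads@blocks, exons, minoverlap = 1L,
                        ignore.strand = TRUE)
  keep <- hits == 0L
  out <- initialize(reads,
                    blocks = reads@blocks[keep],
                    readId = reads@readId[keep],
                    nHits = reads@nHits[keep],
                    mapq = reads@mapq[keep],
                    spot = reads@spot[keep],
                    umi = reads@umi[keep])
  out@log <- c(reads@log, list(exonicRemoved = sum(!keep)))
  out
}

#' Assign reads to TE loci
#'
#' A read is assigned to a locus when the union of its aligned-block
#' overlaps with that locus totals at least `minOverlapBases`. A uniquely
#' mapped read overlapping several loci (nested or adjacent TEs) is
#' assigned to the single locus with the largest overlap, ties broken by
#' lexicographically smallest `locus_id`; a multi-mapped read is assigned
#' (as an MMR) to every locus any of its alignment locations overlaps, at
#' most once per locus.
#'
#' @param reads a non-exonic [SpotAlignments-class].
#' @param annotation a [TEAnnotation-class].
#' @param params a [QuantParams-class].
#' @param dedupUMI when `TRUE` and UMIs are present, collapse assignments
#'   sharing (spot, UMI, locus) to a single read.
#' @return a [TEAssignments-class].
#' @export
assignTEReads <- function(reads, annotation, params = quantParams(),
                          dedupUMI = FALSE) {
  stopifnot(is(reads, "SpotAlignments"), is(annotation, "TEAnnotation"))
  validObject(params)
  loci <- annotation@loci
  status <- mappingStatus(reads)

  ubl <- unlist(reads@blocks, use.names = FALSE)
  read_of_block <- rep.int(seq_along(reads@blocks), lengths(reads@blocks))
  ov <- findOverlaps(ubl, loci, minoverlap = 1L, ignore.strand = TRUE)
  if (!length(ov)) {
    empty <- DataFrame(read_id = character(), spot = character(),
                       status = character(), locus_id = character(),
                       subfamily = character(), te_class = character(),
                       overlap = integer())
    return(new("TEAssignments", table = empty,
               coverIntervals = DataFrame(locus_id = character(),
                                          istart = integer(),
                                          iend = integer()),
               reads = reads, annotation = annotation, params = params))
  }
  qi <- queryHits(ov); si <- subjectHits(ov)
  inter <- pintersect(ranges(ubl)[qi], ranges(loci)[si])
  pairs <- data.table(read = read_of_block[qi], locus = si,
                      istart = start(inter), iend = end(inter),
                      w = width(inter))
  byrl <- pairs[, .(ov = sum(w)), by = .(read, locus)]
  byrl <- byrl[ov >= params@minOverlapBases]

  lid <- mcols(loci)$locus_id
  byrl[, status := status[read]]
  ## unique reads: single best locus (max overlap, then lexicographic id)
  uq <- byrl[status == "unique"]
  if (nrow(uq)) {
    uq[, locus_id := lid[locus]]
    setorder(uq, read, -ov, locus_id)
    uq <- uq[, .SD[1L], by = read]
  }
  mm <- byrl[status == "multi"]
  if (nrow(mm)) mm[, locus_id := lid[locus]]
  asg <- rbind(uq, mm, fill = TRUE)

  asg[, read_id := reads@readId[read]]
  asg[, spot := reads@spot[read]]
  asg[, subfamily := mcols(loci)$subfamily[locus]]
  asg[, te_class := mcols(loci)$te_class[locus]]
  asg[, umi := reads@umi[read]]

  if (dedupUMI && any(!is.na(asg$umi))) {
    has <- !is.na(asg$umi)
    dup <- has & duplicated(asg[, .(spot, umi, locus)])
    asg <- asg[!dup]
  }

  ## keep only intersection intervals of retained (read, locus) pairs
  setkey(pairs, read, locus)
  cov <- pairs[asg[, .(read, locus)], nomatch = 0L]
  cov[, locus_id := lid[locus]]
  setorder(asg, locus_id, read_id)

  new("TEAssignments",
      table = DataFrame(read_id = asg$read_id, spot = asg$spot,
                        status = asg$status, locus_id = asg$locus_id,
                        subfamily = asg$subfamily, te_class = asg$te_class,
                        overlap = as.integer(asg$ov)),
      coverIntervals = DataFrame(locus_id = cov$locus_id,
                                 istart = cov$istart, iend = cov$iend),
      reads = reads, annotation = annotation, params = params)
}

#' Mapping score of a TE locus
#'
#' The mapping score of a TE is the number of uniquely mapped reads
#' (UMRs) assigned to it divided by the total reads assigned to it (UMRs
#' plus multi-mapped reads, MMRs), expressed as a percentage:
#' `MS = 100 * UMR / (UMR + MMR)`. It is 100 exactly when a locus carries
#' only UMRs and 0 exactly when it carries only MMRs, and is defined only
#' for loci with at least one assigned read.
#'
#' @param umr,mmr integer vectors of unique- and multi-mapped read counts.
#' @return numeric vector of mapping scores in `[0, 100]`.
#' @examples
#' mappingScore(7, 0)   # 100: locus-resolved under the default threshold
#' mappingScore(0, 5)   # 0: subfamily-resolved under the default threshold
#' mappingScore(3, 1)   # 75
#' @export
mappingScore <- function(umr, mmr) {
  umr <- as.numeric(umr); mmr <- as.numeric(mmr)
  if (any(umr < 0 | mmr < 0)) stop("read counts must be non-negative")
  if (any(umr + mmr < 1))
    stop("mapping score is undefined for loci with no assigned reads")
  100 * umr / (umr + mmr)
}

#' Per-locus read statistics: counts, coverage and mapping score
#'
#' For every locus with at least one assigned read, tallies UMRs and
#' MMRs, the number of locus bases covered by the union of assigned
#' reads' aligned blocks (UMR and MMR alike, pooled across all spots),
#' the resulting coverage percentage, and the mapping score.
#'
#' @param assignments a [TEAssignments-class].
#' @return a `DataFrame` with one row per covered locus: `locus_id`,
#'   `subfamily`, `family`, `te_class`, `umr_count`, `mmr_count`,
#'   `covered_bases`, `locus_length`, `coverage_pct`, `ms`.
#' @export
teReadStats <- function(assignments) {
  stopifnot(is(assignments, "TEAssignments"))
  tab <- as.data.table(as.data.frame(assignments@table))
  if (!nrow(tab))
    return(DataFrame(locus_id = character(), subfamily = character(),
                     family = character(), te_class = character(),
                     umr_count = integer(), mmr_count = integer(),
                     covered_bases = integer(), locus_length = integer(),
                     coverage_pct = numeric(), ms = numeric()))
  cnt <- tab[, .(umr_count = sum(status == "unique"),
                 mmr_count = sum(status == "multi")), by = locus_id]

  civ <- as.data.table(as.data.frame(assignments@coverIntervals))
  ir <- IRanges(civ$istart, civ$iend)
  covered <- sum(width(reduce(S4Vectors::split(
    ir, factor(civ$locus_id, levels = cnt$locus_id)))))
  cnt[, covered_bases := as.integer(covered[locus_id])]

  g <- assignments@annotation@loci
  idx <- match(cnt$locus_id, mcols(g)$locus_id)
  cnt[, `:=`(locus_length = width(g)[idx],
             subfamily = mcols(g)$subfamily[idx],
             family = mcols(g)$family[idx],
             te_class = mcols(g)$te_class[idx])]
  cnt[, coverage_pct := 100 * covered_bases / locus_length]
  cnt[, ms := mappingScore(umr_count, mmr_count)]
  setorder(cnt, locus_id)
  DataFrame(locus_id = cnt$locus_id, subfamily = cnt$subfamily,
            family = cnt$family, te_class = cnt$te_class,
            umr_count = cnt$umr_count, mmr_count = cnt$mmr_count,
            covered_bases = cnt$covered_bases,
            locus_length = cnt$locus_length,
            coverage_pct = cnt$coverage_pct, ms = cnt$ms)
}

#' Partition covered TE loci into locus- and subfamily-resolved sets
#'
#' First, loci with pooled coverage below `coverageMin` are dropped
#' (default 0: nothing is dropped and all results are reported). Of the
#' remainder, loci with mapping score `>= msLocusMin` form the
#' locus-resolved set (default 100: only-UMR loci) and loci with mapping
#' score `<= msSubfamilyMax` form the subfamily-resolved set (default 0:
#' only-MMR loci). Loci falling strictly between the two thresholds
#' belong to neither output; they are reported in the `intermediate`
#' element so that every covered locus has exactly one disposition.
#'
#' @param stats the `DataFrame` from [teReadStats()].
#' @param params a [QuantParams-class].
#' @return list with character-vector elements `locus`, `subfamily`,
#'   `coverageDropped`, `intermediate` (locus ids), and `tallies`, a
#'   named integer vector of the four set sizes.
#' @export
partitionTEs <- function(stats, params = quantParams()) {
  validObject(params)
  covOK <- stats$coverage_pct >= params@coverageMin
  covDropped <- stats$locus_id[!covOK]
  kept <- stats[covOK, , drop = FALSE]
  locus <- kept$locus_id[kept$ms >= params@msLocusMin]
  subfam <- kept$locus_id[kept$ms <= params@msSubfamilyMax]
  inter <- setdiff(kept$locus_id, c(locus, subfam))
  list(locus = locus, subfamily = subfam,
       coverageDropped = covDropped, intermediate = inter,
       tallies = c(locus = length(locus), subfamily = length(subfam),
                   coverageDropped = length(covDropped),
                   intermediate = length(inter)))
}

## all spots observed among the emitted reads, in (x, y) order
resolvedSpots <- function(reads) sortSpotLabels(unique(reads@spot))

sortSpotLabels <- function(labels) {
  xy <- parseSpotLabels(labels)
  labels[order(xy$x, xy$y)]
}

parseSpotLabels <- function(labels) {
  m <- regmatches(labels, regexec("^([0-9]+)x([0-9]+)$", labels))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("spot labels must be 'XxY'; offending: ",
         paste(head(labels[bad], 5L), collapse = ", "))
  data.frame(x = as.integer(vapply(m, `[[`, "", 2L)),
             y = as.integer(vapply(m, `[[`, "", 3L)))
}

buildSpotMatrix <- function(cells, spots, features, featureType) {
  ## cells: data.table(spot, feature, n)
  mat <- matrix(0, nrow = length(spots), ncol = length(features),
                dimnames = list(spots, features))
  if (nrow(cells))
    mat[cbind(match(cells$spot, spots), match(cells$feature, features))] <-
      cells$n
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  new("SpotMatrix", counts = mat, featureType = featureType)
}

#' Spot-by-locus count matrix
#'
#' One column per locus-resolved TE: the count at (spot, locus) is the
#' number of reads assigned to that locus whose resolved spot is that
#' spot. All assigned reads of the locus count; under the default
#' `msLocusMin = 100` these are necessarily all UMRs. Rows cover every
#' spot observed in the alignment input, so matrices from one run share
#' their row set.
#'
#' @param assignments a [TEAssignments-class].
#' @param partition the list from [partitionTEs()].
#' @return a [SpotMatrix-class] with `featureType = "locus"`.
#' @export
quantifyByLocus <- function(assignments, partition) {
  tab <- as.data.table(as.data.frame(assignments@table))
  tab <- tab[locus_id %in% partition$locus]
  cells <- tab[, .(n = .N), by = .(spot, feature = locus_id)]
  buildSpotMatrix(cells, resolvedSpots(assignments@reads),
                  sort(partition$locus), "locus")
}

#' Spot-by-subfamily count matrix
#'
#' Subfamily-resolved TEs are summarized per subfamily: a read
#' contributes at most 1 to a (spot, subfamily) cell even when it
#' overlaps several loci of that subfamily; a multi-mapper hitting loci
#' of k distinct subfamilies in the subfamily set contributes 1 to each
#' of the k columns (a documented over-count — no fractional weighting is
#' attempted).
#'
#' @inheritParams quantifyByLocus
#' @return a [SpotMatrix-class] with `featureType = "subfamily"`.
#' @export
quantifyBySubfamily <- function(assignments, partition) {
  tab <- as.data.table(as.data.frame(assignments@table))
  tab <- tab[locus_id %in% partition$subfamily]
  ## distinct (read, spot, subfamily): once per subfamily per read
  u <- unique(tab[, .(read_id, spot, subfamily)])
  cells <- u[, .(n = .N), by = .(spot, feature = subfamily)]
  buildSpotMatrix(cells, resolvedSpots(assignments@reads),
                  sort(unique(tab$subfamily)), "subfamily")
}

#' Aggregate a spot matrix to TE-class columns
#'
#' Sums member columns row-wise into the class columns LINE, SINE, LTR,
#' DNA and Other. Locus columns are resolved to classes through the
#' annotation; subfamily columns through its subfamily taxonomy.
#'
#' @param mat a locus- or subfamily-level [SpotMatrix-class].
#' @param annotation the [TEAnnotation-class] supplying the taxonomy.
#' @return a [SpotMatrix-class] with `featureType = "class"`.
#' @export
aggregateByClass <- function(mat, annotation) {
  stopifnot(is(mat, "SpotMatrix"), is(annotation, "TEAnnotation"))
  feats <- featureIds(mat)
  if (mat@featureType == "locus") {
    cls <- mcols(annotation@loci)$te_class[
      match(feats, mcols(annotation@loci)$locus_id)]
  } else if (mat@featureType == "subfamily") {
    tax <- teTaxonomy(annotation)
    cls <- tax$te_class[match(feats, tax$subfamily)]
  } else {
    stop("matrix is already at class resolution")
  }
  if (anyNA(cls))
    stop("features not resolvable through the annotation: ",
         paste(head(feats[is.na(cls)], 5L), collapse = ", "))
  m <- counts(mat)
  out <- vapply(TE_CLASSES, function(k) {
    rowSums(m[, cls == k, drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) {                      # vapply drops to vector shape
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(m), TE_CLASSES))
  }
  out <- out[, colSums(out) > 0, drop = FALSE]
  new("SpotMatrix", counts = out, featureType = "class")
}

#' Log-scale a spot matrix
#'
#' Applies `log2(1 + count)` cell-wise: monotone and zero-preserving, the
#' usual display scale for spot-level TE expression.
#'
#' @param mat a [SpotMatrix-class].
#' @return a real-valued [SpotMatrix-class] of the same shape.
#' @export
log2Normalize <- function(mat) {
  stopifnot(is(mat, "SpotMatrix"))
  initialize(mat, counts = log2(1 + counts(mat)))
}
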