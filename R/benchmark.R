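## Benchmark scoring: compare quantification output on simulated reads
## with the simulation's ground truth.

matToCells <- function(mat) {
  m <- counts(mat)
  if (!length(m))
    return(data.table(spot = character(), feature = character(),
                      n = numeric()))
  dt <- data.table(spot = rep(rownames(m), ncol(m)),
                   feature = rep(colnames(m), each = nrow(m)),
                   n = as.vector(m))
  dt[n > 0]
}

unionCellCor <- function(est, tru) {
  ## Pearson r over the union of cells occupied in either table
  merged <- merge(est, tru, by = c("spot", "feature"), all = TRUE,
                  suffixes = c("_est", "_tru"))
  e <- ifelse(is.na(merged$n_est), 0, merged$n_est)
  t <- ifelse(is.na(merged$n_tru), 0, merged$n_tru)
  if (length(e) < 2L || sd(e) == 0 || sd(t) == 0) return(NA_real_)
  cor(e, t)
}

#' Score quantification results against simulation ground truth
#'
#' Computes the benchmark report: the number of reads counted at a spot
#' other than their true spot (per read against truth when `assignments`
#' are supplied; otherwise from subfamily-resolution cell totals, which
#' are insensitive to confusion between near-identical copies of one
#' subfamily — any cell excess over truth at a (spot, subfamily) cell is
#' a read that arrived from another spot); Pearson correlations
#' between estimated and true counts at (spot, locus) and
#' (spot, subfamily) resolution over the union of occupied cells (absent
#' cells count as 0); and, when per-read assignments are supplied, the
#' percentage of simulated reads whose locus-level assignment is not
#' exactly their true source locus.
#'
#' @param locusMat locus-level [SpotMatrix-class] from the quantifier.
#' @param subfamilyMat subfamily-level [SpotMatrix-class].
#' @param truth the [GroundTruth-class] from [simulateSpotReads()].
#' @param annotation the [TEAnnotation-class] of the simulated genome.
#' @param assignments optional [TEAssignments-class]; enables the
#'   read-level locus-misassignment fraction (otherwise `NA`).
#' @return a [BenchmarkReport-class].
#' @export
evaluateBenchmark <- function(locusMat, subfamilyMat, truth, annotation,
                              assignments = NULL) {
  stopifnot(is(locusMat, "SpotMatrix"), is(subfamilyMat, "SpotMatrix"),
            is(truth, "GroundTruth"))
  tru_reads <- as.data.frame(truth@reads)
  tru_spots <- unique(tru_reads$spot)
  est_spots <- unique(c(spotLabels(locusMat), spotLabels(subfamilyMat)))
  if (!length(intersect(tru_spots, est_spots)))
    stop("estimated and truth spot label sets are disjoint; ",
         "check the dialect / tag configuration")

  if (!is.null(assignments)) {
    ## per read: the spot the read was counted at vs its true spot
    atab <- as.data.table(as.data.frame(assignments@table))
    est_spot <- atab[, .(spot = spot[1L]), by = read_id]
    mm <- merge(est_spot,
                data.table(read_id = tru_reads$read_id,
                           true_spot = tru_reads$spot),
                by = "read_id")
    spot_mis <- sum(mm$spot != mm$true_spot)
  } else {
    ## estimated subfamily totals: the subfamily matrix where it has
    ## columns, completed by folding the locus matrix for subfamilies it
    ## lacks (so each read is counted once whether the two matrices are
    ## disjoint, as in a default run, or both complete)
    lcells <- matToCells(locusMat)
    lids <- mcols(annotation@loci)$locus_id
    lcells[, feature := mcols(annotation@loci)$subfamily[
      match(feature, lids)]]
    lcells <- lcells[!feature %in% featureIds(subfamilyMat)]
    scells <- rbind(lcells, matToCells(subfamilyMat))
    est_sub <- scells[, .(n = sum(n)), by = .(spot, feature)]
    tru_sub <- as.data.table(truthSubfamilyCounts(truth))
    setnames(tru_sub, "subfamily", "feature")
    merged <- merge(est_sub, tru_sub, by = c("spot", "feature"),
                    all = TRUE, suffixes = c("_est", "_tru"))
    e <- ifelse(is.na(merged$n_est), 0, merged$n_est)
    t <- ifelse(is.na(merged$n_tru), 0, merged$n_tru)
    spot_mis <- as.integer(round(sum(pmax(0, e - t))))
  }

  tru_loc <- as.data.table(truthLocusCounts(truth))
  setnames(tru_loc, "locus_id", "feature")
  loc_r <- unionCellCor(matToCells(locusMat), tru_loc)
  sub_r <- unionCellCor(matToCells(subfamilyMat),
                        as.data.table(truthSubfamilyCounts(truth))[
                          , .(spot, feature = subfamily, n)])

  ## a read counts as accurately assigned at locus level iff its
  ## assigned locus set is exactly its true source locus; reads assigned
  ## nowhere, or to any additional or different locus, are misassigned
  frac_mis <- NA_real_
  if (!is.null(assignments)) {
    atab <- as.data.table(as.data.frame(assignments@table))
    tmap <- setNames(tru_reads$locus_id, tru_reads$read_id)
    exact <- atab[, .(exact = .N == 1L && locus_id[1L] == tmap[read_id[1L]]),
                  by = read_id]
    n_exact <- sum(exact$exact[exact$read_id %in% tru_reads$read_id])
    frac_mis <- 100 * (nrow(tru_reads) - n_exact) / nrow(tru_reads)
  }

  new("BenchmarkReport",
      spotMisassignedReads = spot_mis,
      locusCorrelation = loc_r,
      subfamilyCorrelation = sub_r,
      fractionReadsMisassignedLocus = frac_mis)
}

#' Write a benchmark report as JSON
#'
#' @param report a [BenchmarkReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBenchmarkReport <- function(report, path) {
  stopifnot(is(report, "BenchmarkReport"))
  write_json(list(
    spot_misassigned_reads = report@spotMisassignedReads,
    locus_correlation = report@locusCorrelation,
    subfamily_correlation = report@subfamilyCorrelation,
    fraction_reads_misassigned_locus =
      report@fractionReadsMisassignedLocus),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Run one end-to-end simulation + quantification + scoring round
#'
#' Realizes the genome, draws the spot plan, simulates aligned reads,
#' quantifies them, and scores the result. So that both resolutions are
#' populated for every TE (and the locus-level correlation is defined
#' even in young-TE scenarios, where the default partition sends every
#' locus to the subfamily output), the benchmark quantifies every
#' covered TE at both resolutions: the locus and subfamily matrices are
#' each built over all covered loci. This is a benchmark-harness
#' convention, not a change to the quantifier's defaults.
#'
#' @param spec a [GenomeSpec-class].
#' @param plan optional [SpotPlan-class]; default
#'   [randomSpotPlan()] over the realized annotation.
#' @param dir working directory (default a fresh temporary directory).
#' @param maxMismatch mismatch budget of the simulator's exhaustive
#'   matcher.
#' @return list with `report` ([BenchmarkReport-class]), `locus` and
#'   `subfamily` matrices, `truth`, `assignments`, and the realized
#'   `genome`.
#' @export
runBenchmark <- function(spec = genomeSpec(), plan = NULL,
                         dir = tempfile("bench"), maxMismatch = 3L) {
  tg <- simulateTEGenome(spec)
  if (is.null(plan))
    plan <- randomSpotPlan(tg@annotation, seed = spec@seed)
  sim <- simulateSpotReads(tg, plan, dir, mode = "aligned_sam",
                           maxMismatch = maxMismatch)
  reads <- readSpotAlignments(sim$files[["sam"]], dialect = "original_st")
  reads <- filterNonExonic(reads, tg@exons)
  asg <- assignTEReads(reads, tg@annotation, quantParams())
  stats <- teReadStats(asg)
  all_covered <- list(locus = stats$locus_id, subfamily = stats$locus_id)
  locus_mat <- quantifyByLocus(asg, all_covered)
  subfam_mat <- quantifyBySubfamily(asg, all_covered)
  report <- evaluateBenchmark(locus_mat, subfam_mat, sim$truth,
                              tg@annotation, asg)
  list(report = report, locus = locus_mat, subfamily = subfam_mat,
       truth = sim$truth, assignments = asg, genome = tg)
}
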