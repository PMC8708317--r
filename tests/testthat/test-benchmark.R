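## small helper: SpotMatrix from a cells data.frame
cellsToMatrix <- function(cells, spots, features, type) {
  m <- matrix(0, length(spots), length(features),
              dimnames = list(spots, features))
  m[cbind(match(cells$spot, spots), match(cells$feature, features))] <-
    cells$n
  new("SpotMatrix", counts = m[, colSums(m) > 0, drop = FALSE],
      featureType = type)
}

toyTruth <- function() {
  reads <- S4Vectors::DataFrame(
    read_id = sprintf("t%02d", 1:12),
    spot = rep(c("1x1", "2x2"), each = 6),
    locus_id = rep(c("A|c:1-100(+)", "B|c:200-300(+)"), 6),
    subfamily = rep(c("A", "B"), 6),
    te_class = "LINE")
  new("GroundTruth", reads = reads)
}

toyAnnotation <- function() {
  makeAnnotation(data.frame(
    chrom = "c", start = c(1L, 200L), end = c(100L, 300L),
    subfamily = c("A", "B"), te_class = "LINE"))
}

test_that("perfect estimates score zero misassignment, correlation 1", {
  ## default-partition situation: subfamily A is locus-resolved, B is
  ## subfamily-resolved; unequal cell counts so correlation is informative
  tl <- data.frame(spot = c("1x1", "1x1", "2x2"),
                   locus_id = c("A|c:1-100(+)", "A2|c:400-500(+)",
                                "A|c:1-100(+)"),
                   n = c(3L, 5L, 7L))
  ts <- data.frame(spot = c("1x1", "2x2"), subfamily = "B",
                   n = c(2L, 6L))
  ann <- makeAnnotation(data.frame(
    chrom = "c", start = c(1L, 400L, 200L), end = c(100L, 500L, 300L),
    subfamily = c("A", "A2", "B"), te_class = "LINE"))
  ann@loci$locus_id <- c("A|c:1-100(+)", "A2|c:400-500(+)",
                         "B|c:200-300(+)")
  n_all <- sum(tl$n) + sum(ts$n)
  truth <- new("GroundTruth", reads = S4Vectors::DataFrame(
    read_id = sprintf("x%03d", seq_len(n_all)),
    spot = c(rep(tl$spot, tl$n), rep(ts$spot, ts$n)),
    locus_id = c(rep(tl$locus_id, tl$n),
                 rep("B|c:200-300(+)", sum(ts$n))),
    subfamily = c(sub("\\|.*", "", rep(tl$locus_id, tl$n)),
                  rep("B", sum(ts$n))),
    te_class = "LINE"))
  lm <- cellsToMatrix(data.frame(spot = tl$spot, feature = tl$locus_id,
                                 n = tl$n),
                      c("1x1", "2x2"), unique(tl$locus_id), "locus")
  sm <- cellsToMatrix(data.frame(spot = ts$spot, feature = ts$subfamily,
                                 n = ts$n),
                      c("1x1", "2x2"), "B", "subfamily")
  rep <- evaluateBenchmark(lm, sm, truth, ann)
  expect_equal(rep@spotMisassignedReads, 0L)

  ## fully complete matrices at both resolutions: estimates identical to
  ## truth give correlation 1 at both levels and zero misassignment
  tl_full <- truthLocusCounts(truth)
  ts_full <- truthSubfamilyCounts(truth)
  lm2 <- cellsToMatrix(data.frame(spot = tl_full$spot,
                                  feature = tl_full$locus_id,
                                  n = tl_full$n),
                       c("1x1", "2x2"), unique(tl_full$locus_id), "locus")
  sm2 <- cellsToMatrix(data.frame(spot = ts_full$spot,
                                  feature = ts_full$subfamily,
                                  n = ts_full$n),
                       c("1x1", "2x2"), unique(ts_full$subfamily),
                       "subfamily")
  rep2 <- evaluateBenchmark(lm2, sm2, truth, ann)
  expect_equal(rep2@spotMisassignedReads, 0L)
  expect_equal(rep2@locusCorrelation, 1)
  expect_equal(rep2@subfamilyCorrelation, 1)
})

test_that("cells swapped between spots are counted as misassigned reads", {
  truth <- toyTruth()
  ann <- toyAnnotation()
  ts <- truthSubfamilyCounts(truth)       # 3 per (spot, subfamily)
  ## move 2 reads of subfamily A from 1x1 to 2x2
  est <- data.frame(spot = c("1x1", "2x2", "1x1", "2x2"),
                    feature = c("A", "A", "B", "B"),
                    n = c(1, 5, 3, 3))
  sm <- cellsToMatrix(est, c("1x1", "2x2"), c("A", "B"), "subfamily")
  lm <- cellsToMatrix(data.frame(spot = character(), feature = character(),
                                 n = numeric()),
                      c("1x1", "2x2"), character(), "locus")
  rep <- evaluateBenchmark(lm, sm, truth, ann)
  expect_equal(rep@spotMisassignedReads, 2L)
})

test_that("disjoint spot label sets suggest a dialect problem", {
  truth <- toyTruth()
  ann <- toyAnnotation()
  sm <- cellsToMatrix(data.frame(spot = "9x9", feature = "A", n = 1),
                      "9x9", "A", "subfamily")
  expect_error(evaluateBenchmark(sm, sm, truth, ann), "dialect")
})

test_that("spot fidelity holds end to end with error-free barcodes", {
  ## several simulated scenarios; every read must land at its true spot
  for (seed in c(3L, 4L)) {
    spec <- genomeSpec(seed = seed)
    tg <- simulateTEGenome(spec)
    plan <- randomSpotPlan(tg@annotation,
                           spots = c("11x5", "10x10", "2x9"),
                           classes = c("LINE", "LTR", "SINE"),
                           totalReads = c(400L, 300L, 200L),
                           seed = seed)
    res <- runBenchmark(spec, plan)
    expect_identical(res$report@spotMisassignedReads, 0L)
    ## row labels never stray outside the resolved spot set
    expect_true(all(spotLabels(res$locus) %in%
                      c("11x5", "10x10", "2x9")))
  }
})

test_that("young scenarios favor subfamily resolution, old are exact", {
  young_spec <- genomeSpec(
    seed = 13L, nChroms = 1L, chromLength = 50000L,
    tePlan = data.frame(subfamily = "L1Md_F2", family = "L1",
                        te_class = "LINE", n_copies = 4L,
                        copy_length = 400L, divergence_pct = 0.5),
    exonPlan = data.frame(chrom = "chr1", start = 40001L, end = 40500L))
  tg <- simulateTEGenome(young_spec)
  plan <- spotPlan(data.frame(spot = c("1x1", "2x2"),
                              locus_id = locusIds(tg@annotation)[c(1, 2)],
                              n_reads = c(150L, 250L)), seed = 13L)
  young <- runBenchmark(young_spec, plan)
  expect_gte(young$report@subfamilyCorrelation,
             young$report@locusCorrelation)
  ## subfamily-level totals equal truth
  ts <- truthSubfamilyCounts(young$truth)
  m <- counts(young$subfamily)
  for (i in seq_len(nrow(ts)))
    expect_equal(unname(m[ts$spot[i], ts$subfamily[i]]), ts$n[i])

  old_spec <- genomeSpec(
    seed = 14L, nChroms = 1L, chromLength = 50000L,
    tePlan = data.frame(subfamily = "L1_Mus1", family = "L1",
                        te_class = "LINE", n_copies = 4L,
                        copy_length = 400L, divergence_pct = 20),
    exonPlan = data.frame(chrom = "chr1", start = 40001L, end = 40500L))
  tg2 <- simulateTEGenome(old_spec)
  plan2 <- spotPlan(data.frame(spot = c("1x1", "2x2"),
                               locus_id = locusIds(tg2@annotation)[c(1, 3)],
                               n_reads = c(120L, 180L)), seed = 14L)
  old <- runBenchmark(old_spec, plan2)
  tl <- truthLocusCounts(old$truth)
  ml <- counts(old$locus)
  expect_equal(sum(ml), sum(tl$n))
  for (i in seq_len(nrow(tl)))
    expect_equal(unname(ml[tl$spot[i], tl$locus_id[i]]), tl$n[i])
  expect_equal(old$report@fractionReadsMisassignedLocus, 0)
})

test_that("benchmark reports serialize to JSON", {
  rep <- new("BenchmarkReport", spotMisassignedReads = 0L,
             locusCorrelation = 0.5, subfamilyCorrelation = 0.9,
             fractionReadsMisassignedLocus = 12.5)
  path <- withr::local_tempfile(fileext = ".json")
  writeBenchmarkReport(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$spot_misassigned_reads, 0L)
  expect_equal(parsed$subfamily_correlation, 0.9)
})
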