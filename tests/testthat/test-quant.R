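simpleLoci <- function() data.frame(
  chrom = "chr1",
  start = c(1000L, 1030L, 2000L, 3000L, 4000L),
  end   = c(1599L, 1129L, 2499L, 3499L, 4399L),
  subfamily = c("L1Md_F2", "B1_Mus1", "L1Md_F2", "L1Md_F2", "RLTR10"),
  te_class  = c("LINE", "SINE", "LINE", "LINE", "LTR"))

test_that("reads touching an exon by even one base are removed", {
  exons <- GRanges("chr1", IRanges(500, 600))
  reads <- makeReads(list(
    list(blocks = data.frame(start = 300, end = 400), chrom = "chr1"),
    list(blocks = data.frame(start = 451, end = 500), chrom = "chr1"),
    list(blocks = data.frame(start = c(300, 550),
                             end = c(350, 580)), chrom = "chr1")))
  kept <- filterNonExonic(reads, exons)
  expect_equal(readIds(kept), "r001")       # intronic read retained
  expect_equal(readLog(kept)$exonicRemoved, 2L)
})

test_that("a planted exonic fraction of a fixture is removed exactly", {
  set.seed(21)
  exons <- GRanges("chr1", IRanges(5000, 6000))
  reads <- lapply(1:40, function(i) {
    st <- if (i <= 15) sample(5000:5950, 1L) else sample(100:4800, 1L)
    list(blocks = data.frame(start = st, end = st + 49L), chrom = "chr1")
  })
  kept <- filterNonExonic(makeReads(reads), exons)
  expect_equal(length(kept), 25L)
  expect_equal(readLog(kept)$exonicRemoved, 15L)
})

test_that("unique reads go to the max-overlap locus, ties to smallest id", {
  ann <- makeAnnotation(simpleLoci())
  ## read overlapping the nested SINE (100 bases wide) and the outer L1:
  ## 30 bases on the SINE-only area is impossible here, so construct
  ## overlap 70 with L1 region before the SINE and 30 inside the SINE
  reads <- makeReads(list(
    list(blocks = data.frame(start = 1100, end = 1199), chrom = "chr1")))
  asg <- assignTEReads(reads, ann)
  tab <- as.data.frame(asg@table)
  expect_equal(nrow(tab), 1L)
  ## overlap with outer L1Md_F2 locus = 100, with nested B1_Mus1 = 30
  expect_equal(tab$subfamily, "L1Md_F2")
  expect_equal(tab$overlap, 100L)
})

test_that("a multi-mapper is assigned once per locus it overlaps", {
  ann <- makeAnnotation(simpleLoci())
  reads <- makeReads(list(
    list(blocks = data.frame(start = c(1100, 2100, 3100),
                             end = c(1199, 2199, 3199)),
         chrom = "chr1", nHits = 3L, spot = "10x10")))
  asg <- assignTEReads(reads, ann)
  tab <- as.data.frame(asg@table)
  ## 3 L1Md_F2 copies plus the nested B1_Mus1 under the first location
  expect_equal(sum(tab$subfamily == "L1Md_F2"), 3L)
  expect_equal(length(unique(tab$locus_id)), nrow(tab))
  expect_true(all(tab$status == "multi"))
})

test_that("coverage is the union of read overlaps and MS the UMR fraction", {
  loci <- data.frame(chrom = "chr1", start = 1001L, end = 1156L,
                     subfamily = "L1Md_F2", te_class = "LINE")
  ann <- makeAnnotation(loci)
  reads <- makeReads(list(
    list(blocks = data.frame(start = 1001, end = 1100), chrom = "chr1"),
    list(blocks = data.frame(start = 1051, end = 1156), chrom = "chr1")))
  stats <- teReadStats(assignTEReads(reads, ann))
  expect_equal(stats$covered_bases, 156L)
  expect_equal(stats$coverage_pct, 100)
  expect_equal(stats$ms, 100)

  reads2 <- makeReads(list(
    list(blocks = data.frame(start = 1001, end = 1050), chrom = "chr1"),
    list(blocks = data.frame(start = 1001, end = 1050), chrom = "chr1"),
    list(blocks = data.frame(start = 1051, end = 1100), chrom = "chr1"),
    list(blocks = data.frame(start = 1010, end = 1060), chrom = "chr1",
         nHits = 2L)))
  stats2 <- teReadStats(assignTEReads(reads2, ann))
  expect_equal(stats2$umr_count, 3L)
  expect_equal(stats2$mmr_count, 1L)
  expect_equal(stats2$ms, 75)
  expect_equal(stats2$covered_bases, 100L)
})

test_that("the mapping score formula and its boundary cases hold", {
  expect_equal(mappingScore(7, 0), 100)
  expect_equal(mappingScore(0, 5), 0)
  expect_equal(mappingScore(3, 1), 75)
  expect_error(mappingScore(0, 0), "undefined")
  expect_error(mappingScore(-1, 2), "non-negative")
})

test_that("partitioning follows the coverage and mapping-score thresholds", {
  stats <- S4Vectors::DataFrame(
    locus_id = c("a", "b", "c", "d"),
    coverage_pct = c(100, 50, 10, 1),
    ms = c(100, 0, 75, 100))
  p <- partitionTEs(stats, quantParams())
  expect_equal(p$locus, c("a", "d"))
  expect_equal(p$subfamily, "b")
  expect_equal(p$intermediate, "c")
  expect_equal(length(p$coverageDropped), 0L)

  p2 <- partitionTEs(stats, quantParams(coverageMin = 40))
  expect_setequal(p2$coverageDropped, c("c", "d"))
  expect_equal(p2$locus, "a")

  expect_error(partitionTEs(stats, quantParams(msLocusMin = 10,
                                               msSubfamilyMax = 60)))
})

test_that("locus counts land at the read's spot; empty sets stay valid", {
  ann <- makeAnnotation(simpleLoci())
  reads <- makeReads(lapply(1:5, function(i)
    list(blocks = data.frame(start = 2000 + 10 * i,
                             end = 2099 + 10 * i),
         chrom = "chr1", spot = "11x5")))
  asg <- assignTEReads(reads, ann)
  part <- partitionTEs(teReadStats(asg), quantParams())
  m <- quantifyByLocus(asg, part)
  expect_equal(ncol(counts(m)), 1L)
  expect_equal(unname(counts(m)["11x5", 1L]), 5)

  empty <- quantifyByLocus(asg, list(locus = character(),
                                     subfamily = character()))
  expect_equal(ncol(counts(empty)), 0L)
  expect_true(nrow(counts(empty)) >= 1L)
})

test_that("subfamily counting is once per read per subfamily", {
  ann <- makeAnnotation(simpleLoci())
  ## MMR hitting the three L1Md_F2 copies: one count, one column
  reads <- makeReads(list(
    list(blocks = data.frame(start = c(1200, 2100, 3100),
                             end = c(1299, 2199, 3199)),
         chrom = "chr1", nHits = 3L, spot = "10x10"),
    ## MMR hitting an L1Md_F2 copy and the RLTR10 copy: both columns
    list(blocks = data.frame(start = c(2100, 4100),
                             end = c(2199, 4199)),
         chrom = "chr1", nHits = 2L, spot = "10x10")))
  asg <- assignTEReads(reads, ann)
  part <- partitionTEs(teReadStats(asg), quantParams())
  m <- counts(quantifyBySubfamily(asg, part))
  expect_equal(unname(m["10x10", "L1Md_F2"]), 2)
  expect_equal(unname(m["10x10", "RLTR10"]), 1)
})

test_that("class aggregation sums member columns and rejects strangers", {
  ann <- makeAnnotation(simpleLoci())
  m <- new("SpotMatrix",
           counts = matrix(c(4, 1, 6, 2), nrow = 2,
                           dimnames = list(c("1x1", "1x2"),
                                           c("L1Md_F2", "B1_Mus1"))),
           featureType = "subfamily")
  agg <- counts(aggregateByClass(m, ann))
  expect_equal(unname(agg[, "LINE"]), c(4, 1))
  expect_equal(unname(agg[, "SINE"]), c(6, 2))

  bad <- new("SpotMatrix",
             counts = matrix(1, 1, 1,
                             dimnames = list("1x1", "NotASubfamily")),
             featureType = "subfamily")
  expect_error(aggregateByClass(bad, ann), "NotASubfamily")

  set.seed(13)
  rnd <- matrix(rpois(20, 4) + 1, nrow = 4,
                dimnames = list(sprintf("1x%d", 1:4),
                                c("L1Md_F2", "B1_Mus1", "RLTR10",
                                  "L1Md_F2x", "B1x")[1:5]))
  colnames(rnd) <- c("L1Md_F2", "B1_Mus1", "RLTR10", "L1Md_F2", "B1_Mus1")
  ## duplicate names not allowed; rebuild with distinct loci ids instead
  lids <- locusIds(ann)
  rnd2 <- matrix(rpois(4 * length(lids), 3) + 1, nrow = 4,
                 dimnames = list(sprintf("1x%d", 1:4), lids))
  sm <- new("SpotMatrix", counts = rnd2, featureType = "locus")
  agg2 <- counts(aggregateByClass(sm, ann))
  cls <- mcols(teLoci(ann))$te_class
  for (k in unique(cls)) {
    expect_equal(unname(agg2[, k]),
                 unname(rowSums(rnd2[, cls == k, drop = FALSE])))
  }
})

test_that("log2 normalization is the zero-preserving log2(1 + n)", {
  m <- new("SpotMatrix",
           counts = matrix(c(0, 3, 7, 1), nrow = 2,
                           dimnames = list(c("1x1", "1x2"),
                                           c("A", "B"))),
           featureType = "class")
  lg <- counts(log2Normalize(m))
  expect_equal(unname(lg[1, 1]), 0)
  expect_equal(unname(lg[2, 1]), 2)
  expect_equal(unname(lg[1, 2]), 3)
})

test_that("stats and matrices match the per-base brute-force oracle", {
  set.seed(31)
  for (rep in 1:12) {
    inst <- randomInstance(nReads = sample(20:100, 1L),
                           nLoci = sample(5:20, 1L))
    reads <- makeReads(inst$reads)
    ann <- makeAnnotation(inst$loci)
    asg <- assignTEReads(reads, ann)
    stats <- teReadStats(asg)
    oracle <- oracleQuant(inst$reads, inst$loci)

    if (is.null(oracle$stats)) {
      expect_equal(nrow(stats), 0L)
      next
    }
    o <- oracle$stats[order(oracle$stats$locus_id), ]
    expect_equal(stats$locus_id, o$locus_id)
    expect_equal(stats$umr_count, o$umr)
    expect_equal(stats$mmr_count, o$mmr)
    expect_equal(stats$covered_bases, o$covered)
    expect_equal(stats$locus_length, o$len)

    part <- partitionTEs(stats, quantParams())
    cells <- oracleCells(inst$reads, inst$loci, oracle,
                         part$locus, part$subfamily)
    expectMatrixEqualsCells(quantifyByLocus(asg, part), cells$locus)
    expectMatrixEqualsCells(quantifyBySubfamily(asg, part),
                            cells$subfamily)
  }
})

test_that("mapping scores are bounded and pin their boundary meanings", {
  set.seed(37)
  for (rep in 1:8) {
    inst <- randomInstance(nReads = 60, nLoci = 12)
    asg <- assignTEReads(makeReads(inst$reads),
                         makeAnnotation(inst$loci))
    stats <- teReadStats(asg)
    if (!nrow(stats)) next
    expect_true(all(stats$ms >= 0 & stats$ms <= 100))
    expect_equal(stats$ms == 100, stats$mmr_count == 0)
    expect_equal(stats$ms == 0, stats$umr_count == 0)
    expect_true(all(stats$umr_count + stats$mmr_count >= 1))
    expect_true(all(stats$coverage_pct > 0 & stats$coverage_pct <= 100))
  }
})

test_that("raising thresholds never increases what is reported", {
  set.seed(41)
  inst <- randomInstance(nReads = 80, nLoci = 15)
  asg <- assignTEReads(makeReads(inst$reads), makeAnnotation(inst$loci))
  stats <- teReadStats(asg)
  nReported <- function(cov, msl) {
    p <- partitionTEs(stats, quantParams(coverageMin = cov,
                                         msLocusMin = msl))
    length(p$locus) + length(p$subfamily)
  }
  covs <- c(0, 10, 25, 50, 75, 100)
  reported <- vapply(covs, nReported, 0, msl = 100)
  expect_true(all(diff(reported) <= 0))
  nLocus <- vapply(c(0, 25, 50, 75, 100), function(msl)
    length(partitionTEs(stats, quantParams(msLocusMin = msl,
                                           msSubfamilyMax = 0))$locus),
    0)
  expect_true(all(diff(nLocus) <= 0))
})

test_that("every assigned read has exactly one disposition", {
  set.seed(43)
  inst <- randomInstance(nReads = 70, nLoci = 12)
  asg <- assignTEReads(makeReads(inst$reads), makeAnnotation(inst$loci))
  stats <- teReadStats(asg)
  part <- partitionTEs(stats, quantParams())
  tab <- as.data.frame(asg@table)
  sets <- list(part$locus, part$subfamily, part$coverageDropped,
               part$intermediate)
  ## the four locus sets partition the covered loci
  expect_setequal(unlist(sets), stats$locus_id)
  expect_equal(sum(lengths(sets)), nrow(stats))
  ## unique reads: counted in the locus matrix iff their locus is in the
  ## locus set; every unique assigned read appears in exactly one tally
  uq <- tab[tab$status == "unique", ]
  m <- counts(quantifyByLocus(asg, part))
  expect_equal(sum(m[, colnames(m) %in% part$locus, drop = FALSE]),
               sum(uq$locus_id %in% part$locus) +
                 sum(tab$status == "multi" & tab$locus_id %in% part$locus))
})

test_that("UMI deduplication collapses same-spot same-molecule reads", {
  ann <- makeAnnotation(simpleLoci())
  reads <- makeReads(list(
    list(blocks = data.frame(start = 2010, end = 2109), chrom = "chr1",
         spot = "1x1", umi = "AACC"),
    list(blocks = data.frame(start = 2020, end = 2119), chrom = "chr1",
         spot = "1x1", umi = "AACC"),
    list(blocks = data.frame(start = 2030, end = 2129), chrom = "chr1",
         spot = "1x1", umi = "GGTT")))
  with_dedup <- assignTEReads(reads, ann, dedupUMI = TRUE)
  expect_equal(nrow(with_dedup@table), 2L)
  without <- assignTEReads(reads, ann)
  expect_equal(nrow(without@table), 3L)
})
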