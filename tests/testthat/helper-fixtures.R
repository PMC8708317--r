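## Fixture builders and independent brute-force oracles. The oracles
## work on plain integer position sets (seq/intersect/union) and share
## no interval machinery with the implementation under test.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## ---- direct SpotAlignments construction (no SAM needed) --------------

## reads: list of list(blocks = data.frame(start, end) [1-based closed],
##        chrom, nHits, spot, mapq)
makeReads <- function(reads, uniqueMapq = 255L) {
  grl <- GRangesList(lapply(reads, function(r) {
    reduce(GRanges(r$chrom, IRanges(r$blocks$start, r$blocks$end)))
  }))
  names(grl) <- NULL
  new("SpotAlignments",
      blocks = grl,
      readId = vapply(seq_along(reads), function(i)
        if (!is.null(reads[[i]]$id)) reads[[i]]$id
        else sprintf("r%03d", i), ""),
      nHits = vapply(reads, function(r)
        as.integer(if (is.null(r$nHits)) 1L else r$nHits), 1L),
      mapq = vapply(reads, function(r)
        as.integer(if (is.null(r$mapq)) 255L else r$mapq), 1L),
      spot = vapply(reads, function(r)
        if (is.null(r$spot)) "1x1" else r$spot, ""),
      umi = vapply(reads, function(r)
        if (is.null(r$umi)) NA_character_ else r$umi, ""),
      uniqueMapq = as.integer(uniqueMapq),
      log = list(records = length(reads), primaryRecords = length(reads),
                 readsEmitted = length(reads), skippedNoSpot = 0L))
}

## loci: data.frame(chrom, start, end, subfamily, family, te_class)
makeAnnotation <- function(loci) {
  spotTE:::newTEAnnotation(loci$chrom, loci$start, loci$end,
                           if (is.null(loci$strand)) rep("+", nrow(loci))
                           else loci$strand,
                           loci$subfamily,
                           if (is.null(loci$family)) rep("", nrow(loci))
                           else loci$family,
                           loci$te_class)
}

## ---- random instance generator for oracle-equivalence tests ---------

randomInstance <- function(nReads, nLoci, chromLen = 2000L,
                           spots = c("1x1", "1x2", "2x1")) {
  subfams <- paste0("SF", seq_len(max(2L, ceiling(nLoci / 3))))
  loci <- data.frame(
    chrom = sample(c("chrA", "chrB"), nLoci, replace = TRUE),
    start = sample.int(chromLen - 220L, nLoci, replace = TRUE),
    subfamily = sample(subfams, nLoci, replace = TRUE),
    te_class = sample(c("LINE", "SINE", "LTR"), nLoci, replace = TRUE))
  loci$end <- loci$start + sample(30:200, nLoci, replace = TRUE)
  loci$family <- loci$subfamily
  reads <- lapply(seq_len(nReads), function(i) {
    nb <- sample(1:2, 1L)
    st <- sample.int(chromLen - 200L, 1L)
    bl <- data.frame(start = st, end = st + sample(20:80, 1L))
    if (nb == 2L) {
      st2 <- bl$end[1L] + sample(5:60, 1L)
      bl <- rbind(bl, data.frame(start = st2, end = st2 + sample(20:80, 1L)))
    }
    list(blocks = bl, chrom = sample(c("chrA", "chrB"), 1L),
         nHits = sample(c(1L, 1L, 2L, 3L), 1L),
         spot = sample(spots, 1L))
  })
  list(loci = loci, reads = reads)
}

## ---- brute-force per-base oracle ------------------------------------

## returns per-locus stats and per-read assigned locus sets computed by
## exhaustive position-set arithmetic
oracleQuant <- function(reads, loci, minOverlap = 1L) {
  lociIds <- spotTE:::makeLocusIds(
    loci$subfamily, loci$chrom, loci$start, loci$end,
    if (is.null(loci$strand)) rep("+", nrow(loci)) else loci$strand)
  lociPos <- lapply(seq_len(nrow(loci)), function(j)
    seq(loci$start[j], loci$end[j]))
  readPos <- lapply(reads, function(r)
    sort(unique(unlist(Map(seq, r$blocks$start, r$blocks$end)))))
  status <- vapply(reads, function(r)
    if (r$nHits == 1L) "unique" else "multi", "")

  assigned <- vector("list", length(reads))   # locus indices per read
  for (i in seq_along(reads)) {
    ovs <- vapply(seq_len(nrow(loci)), function(j) {
      if (reads[[i]]$chrom != loci$chrom[j]) return(0L)
      length(intersect(readPos[[i]], lociPos[[j]]))
    }, 0L)
    cand <- which(ovs >= minOverlap)
    if (!length(cand)) next
    if (status[i] == "unique") {
      best <- cand[ovs[cand] == max(ovs[cand])]
      assigned[[i]] <- best[order(lociIds[best])][1L]
    } else {
      assigned[[i]] <- cand
    }
  }

  stats <- lapply(seq_len(nrow(loci)), function(j) {
    ridx <- which(vapply(assigned, function(a) j %in% a, TRUE))
    if (!length(ridx)) return(NULL)
    covered <- sort(unique(unlist(lapply(ridx, function(i)
      intersect(readPos[[i]], lociPos[[j]])))))
    data.frame(locus_id = lociIds[j],
               umr = sum(status[ridx] == "unique"),
               mmr = sum(status[ridx] == "multi"),
               covered = length(covered),
               len = length(lociPos[[j]]))
  })
  list(stats = do.call(rbind, stats), assigned = assigned,
       lociIds = lociIds, status = status)
}

## oracle spot-by-locus and spot-by-subfamily cells over given id sets
oracleCells <- function(reads, loci, oracle, locusSet, subfamilySet) {
  loc <- list(); sub <- list()
  for (i in seq_along(reads)) {
    a <- oracle$assigned[[i]]
    if (is.null(a)) next
    s <- reads[[i]]$spot
    for (j in a) {
      id <- oracle$lociIds[j]
      if (id %in% locusSet) {
        key <- paste(s, id, sep = "\r")
        loc[[key]] <- (if (is.null(loc[[key]])) 0L else loc[[key]]) + 1L
      }
    }
    sf <- unique(loci$subfamily[a[oracle$lociIds[a] %in% subfamilySet]])
    for (f in sf) {
      key <- paste(s, f, sep = "\r")
      sub[[key]] <- (if (is.null(sub[[key]])) 0L else sub[[key]]) + 1L
    }
  }
  splitKeys <- function(l) {
    if (!length(l)) return(data.frame(spot = character(),
                                      feature = character(),
                                      n = integer()))
    ks <- strsplit(names(l), "\r", fixed = TRUE)
    data.frame(spot = vapply(ks, `[[`, "", 1L),
               feature = vapply(ks, `[[`, "", 2L),
               n = unlist(l, use.names = FALSE))
  }
  list(locus = splitKeys(loc), subfamily = splitKeys(sub))
}

## compare a SpotMatrix against oracle cells (zero cells implicit)
expectMatrixEqualsCells <- function(mat, cells) {
  m <- counts(mat)
  got <- if (length(m)) sum(m) else 0
  expect_equal(got, sum(cells$n))
  for (k in seq_len(nrow(cells))) {
    expect_true(cells$spot[k] %in% rownames(m))
    expect_true(cells$feature[k] %in% colnames(m))
    expect_equal(unname(m[cells$spot[k], cells$feature[k]]), cells$n[k])
  }
}

## ---- handcrafted RepeatMasker .out writer ---------------------------

writeRMFixture <- function(rows, path) {
  hdr <- c("   SW   perc perc perc  query  position in query  matching",
           "score   div. del. ins.  sequence begin end (left) repeat",
           "")
  writeLines(c(hdr, rows), path)
  path
}

rmRow <- function(chrom, begin, end, strand, name, clsfam, score = 1000) {
  sprintf("%d 10.1 0.0 0.0 %s %d %d (0) %s %s %s 1 100 (0) 1",
          score, chrom, begin, end, strand, name, clsfam)
}
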