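## Synthetic benchmark fixtures: a mini-genome with planted TE copies at
## controlled divergence, spot-tagged simulated reads with per-read
## ground truth, and writers for every on-disk format the quantifier
## consumes (FASTA, RepeatMasker .out, converted table, GTF, SAM, FASTQ).

DNA_BASES <- c("A", "C", "G", "T")

randomDNA <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## substitute bases at `rate` per base; never substitutes to the same base
mutateSeq <- function(seqchars, rate) {
  if (rate <= 0) return(seqchars)
  hit <- which(runif(length(seqchars)) < rate)
  if (length(hit)) {
    cur <- seqchars[hit]
    seqchars[hit] <- vapply(cur, function(b)
      sample(setdiff(DNA_BASES, b), 1L), "")
  }
  seqchars
}

#' Construct a synthetic genome specification
#'
#' The defaults describe the package's standard benchmark genome: two
#' 100 kb chromosomes carrying four TE subfamilies of five copies each —
#' one young LINE subfamily at 1 percent divergence (near-identical
#' copies whose reads multi-map) and three old subfamilies at 15–20
#' percent divergence (reads map uniquely) — plus a handful of planted
#' exons for the non-exonic filter to act on.
#'
#' @param nChroms,chromLength number and length of chromosomes.
#' @param tePlan data.frame (see [GenomeSpec-class]); one row per
#'   subfamily.
#' @param exonPlan data.frame of exon intervals (`chrom`, `start`, `end`,
#'   1-based); TE copies are placed outside them.
#' @param seed integer seed; the realized genome is a pure function of
#'   the spec.
#' @return a [GenomeSpec-class].
#' @export
genomeSpec <- function(nChroms = 2L, chromLength = 100000L,
                       tePlan = data.frame(
                         subfamily = c("L1Md_F2", "L1_Mus1", "B1_Mus1",
                                       "RLTR10"),
                         family = c("L1", "L1", "Alu", "ERVK"),
                         te_class = c("LINE", "LINE", "SINE", "LTR"),
                         n_copies = 5L,
                         copy_length = c(600L, 500L, 150L, 400L),
                         divergence_pct = c(1, 20, 15, 18)),
                       exonPlan = data.frame(
                         chrom = rep(paste0("chr", seq_len(nChroms)),
                                     each = 2L),
                         start = rep(c(2001L, 52001L), nChroms),
                         end = rep(c(3000L, 53000L), nChroms)),
                       seed = 1L) {
  new("GenomeSpec", nChroms = as.integer(nChroms),
      chromLength = as.integer(chromLength),
      tePlan = tePlan, exonPlan = exonPlan, seed = as.integer(seed))
}

#' Realize a synthetic TE genome
#'
#' Draws a random background for each chromosome and a random consensus
#' per subfamily, then plants `n_copies` copies of each consensus at
#' uniformly chosen non-overlapping positions outside the planned exons.
#' Each copy is the consensus with independent substitutions at
#' `divergence_pct` per 100 bases, emulating sequence age: high
#' divergence makes copies separable by unique alignments (old TEs),
#' divergence at or below 1 percent leaves them near-identical (young
#' TEs). The annotation records the exact planted coordinates. Identical
#' specs (including seed) yield byte-identical output.
#'
#' @param spec a [GenomeSpec-class].
#' @return a [TEGenome-class].
#' @export
simulateTEGenome <- function(spec) {
  stopifnot(is(spec, "GenomeSpec"))
  validObject(spec)
  set.seed(spec@seed)
  chroms <- paste0("chr", seq_len(spec@nChroms))
  seqs <- lapply(chroms, function(.) {
    sample(DNA_BASES, spec@chromLength, replace = TRUE)
  })
  names(seqs) <- chroms

  plan <- spec@tePlan
  total_te <- sum(plan$n_copies * plan$copy_length)
  if (total_te > 0.5 * spec@nChroms * spec@chromLength)
    stop("TE plan exceeds chromosome capacity (planted length must stay ",
         "below half the genome)")

  occupied <- if (nrow(spec@exonPlan)) {
    GRanges(spec@exonPlan$chrom,
            IRanges(spec@exonPlan$start, spec@exonPlan$end))
  } else GRanges()

  consensus <- lapply(seq_len(nrow(plan)), function(i)
    strsplit(randomDNA(plan$copy_length[i]), "")[[1L]])
  names(consensus) <- plan$subfamily

  rows <- list()
  for (i in seq_len(nrow(plan))) {
    len <- plan$copy_length[i]
    for (k in seq_len(plan$n_copies[i])) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        chrom <- sample(chroms, 1L)
        start <- sample.int(spec@chromLength - len + 1L, 1L)
        cand <- GRanges(chrom, IRanges(start, start + len - 1L))
        if (!length(findOverlaps(cand, occupied))) {
          occupied <- c(occupied, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("TE plan exceeds chromosome capacity: could not place copy ",
             k, " of ", plan$subfamily[i])
      copy <- mutateSeq(consensus[[i]], plan$divergence_pct[i] / 100)
      seqs[[chrom]][start:(start + len - 1L)] <- copy
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = start + len - 1L,
        subfamily = plan$subfamily[i], family = plan$family[i],
        te_class = plan$te_class[i], divergence = plan$divergence_pct[i])
    }
  }
  tedf <- do.call(rbind, rows)
  ann <- newTEAnnotation(tedf$chrom, tedf$start, tedf$end,
                         rep("+", nrow(tedf)), tedf$subfamily,
                         tedf$family, tedf$te_class)
  mcols(ann@loci)$divergence <- tedf$divergence

  genome <- DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  exons <- if (nrow(spec@exonPlan)) {
    GRanges(spec@exonPlan$chrom,
            IRanges(spec@exonPlan$start, spec@exonPlan$end))
  } else GRanges()
  new("TEGenome", genome = genome, annotation = ann, exons = exons,
      consensus = DNAStringSet(vapply(consensus, paste, "",
                                      collapse = "")),
      spec = spec)
}

#' Write the realized genome and its annotations to a directory
#'
#' Emits `genome.fa`, a RepeatMasker-format `te_annotation.out`, the
#' converted 9-column `te_annotation.bed`, and `exons.gtf` — the exact
#' file formats the quantifier consumes, so the simulated fixtures
#' exercise every parser.
#'
#' @param tegenome a [TEGenome-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeTEGenome <- function(tegenome, dir) {
  stopifnot(is(tegenome, "TEGenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  writeXStringSet(tegenome@genome, fa)
  rm_out <- file.path(dir, "te_annotation.out")
  writeRepeatMaskerOut(tegenome@annotation, rm_out)
  bed <- file.path(dir, "te_annotation.bed")
  writeTETable(tegenome@annotation, bed)
  gtf <- file.path(dir, "exons.gtf")
  writeExonGTF(tegenome@exons, gtf)
  invisible(c(genome = fa, rm_out = rm_out, bed = bed, gtf = gtf))
}

## RepeatMasker .out layout: 3 header lines then whitespace columns
writeRepeatMaskerOut <- function(annotation, path) {
  g <- annotation@loci
  div <- if ("divergence" %in% colnames(mcols(g))) {
    mcols(g)$divergence
  } else rep(0, length(g))
  hdr <- c(
    paste("   SW   perc perc perc  query     position in query    ",
          "matching  repeat         position in repeat"),
    paste("score   div. del. ins.  sequence  begin  end    (left) ",
          "repeat    class/family   begin  end  (left)  ID"),
    "")
  clsfam <- ifelse(nzchar(mcols(g)$family),
                   paste0(mcols(g)$te_class, "/", mcols(g)$family),
                   mcols(g)$te_class)
  rows <- sprintf(
    "%5d %6.1f %4.1f %4.1f  %s %d %d (%d) %s %s %s %d %d (%d) %d",
    1000L, div, 0, 0, as.character(seqnames(g)), start(g), end(g), 0L,
    ifelse(as.character(strand(g)) == "-", "C", "+"),
    mcols(g)$subfamily, clsfam, 1L, width(g), 0L, seq_along(g))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

writeExonGTF <- function(exons, path) {
  if (!length(exons)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  attrs <- sprintf('gene_id "g%d"; transcript_id "t%d";',
                   seq_along(exons), seq_along(exons))
  rows <- paste(as.character(seqnames(exons)), "synth", "exon",
                start(exons), end(exons), ".", "+", ".", attrs,
                sep = "\t")
  writeLines(rows, path)
  invisible(path)
}

#' Construct a per-spot read plan
#'
#' @param counts data.frame with columns `spot`, `locus_id`, `n_reads`.
#' @param readLength read length in bases (default 100).
#' @param errorRate per-base sequencing error probability (default 0).
#' @param seed integer seed for read drawing.
#' @return a [SpotPlan-class].
#' @export
spotPlan <- function(counts, readLength = 100L, errorRate = 0,
                     seed = 1L) {
  new("SpotPlan", counts = as.data.frame(counts),
      readLength = as.integer(readLength),
      errorRate = as.numeric(errorRate), seed = as.integer(seed))
}

#' Draw a random spot plan over planted loci
#'
#' Mirrors the validation design for spatial TE quantification: a small
#' number of spots, each assigned randomly selected loci of one TE class,
#' with a random number of reads per selected locus summing to a fixed
#' per-spot total. The defaults are two spots, `"11x5"` receiving 6420
#' LINE reads and `"10x10"` receiving 9593 LTR reads.
#'
#' @param annotation a [TEAnnotation-class] (typically from
#'   [simulateTEGenome()]).
#' @param spots character vector of spot labels.
#' @param classes character vector, the TE class drawn at each spot.
#' @param totalReads integer vector of per-spot read totals.
#' @param lociPerSpot how many distinct loci to select per spot (capped
#'   at the number available).
#' @param readLength,errorRate,seed see [spotPlan()].
#' @return a [SpotPlan-class].
#' @export
randomSpotPlan <- function(annotation, spots = c("11x5", "10x10"),
                           classes = c("LINE", "LTR"),
                           totalReads = c(6420L, 9593L),
                           lociPerSpot = 5L, readLength = 100L,
                           errorRate = 0, seed = 1L) {
  stopifnot(length(spots) == length(classes),
            length(spots) == length(totalReads))
  set.seed(seed)
  g <- annotation@loci
  rows <- list()
  for (i in seq_along(spots)) {
    cand <- mcols(g)$locus_id[mcols(g)$te_class == classes[i]]
    if (!length(cand))
      stop("no loci of class ", classes[i], " in the annotation")
    chosen <- sample(cand, min(lociPerSpot, length(cand)))
    draw <- table(sample(chosen, totalReads[i], replace = TRUE))
    rows[[i]] <- data.frame(spot = spots[i], locus_id = names(draw),
                            n_reads = as.integer(draw))
  }
  spotPlan(do.call(rbind, rows), readLength = readLength,
           errorRate = errorRate, seed = seed)
}

## concatenate locus sequences with N-run separators wide enough that no
## read can match across a boundary; returns subject plus locus offsets
lociSubject <- function(genomeChars, annotation, readLength) {
  g <- annotation@loci
  seqs <- vapply(seq_along(g), function(i) {
    ch <- as.character(seqnames(g))[i]
    paste(genomeChars[[ch]][start(g)[i]:end(g)[i]], collapse = "")
  }, "")
  sep <- strrep("N", readLength)
  offsets <- integer(length(g))
  pos <- 1L
  for (i in seq_along(seqs)) {
    offsets[i] <- pos
    pos <- pos + nchar(seqs[i]) + readLength
  }
  list(subject = DNAString(paste(seqs, collapse = sep)),
       offsets = offsets, lengths = nchar(seqs))
}

#' Simulate spot-barcoded TE reads with ground truth
#'
#' Draws `n_reads` reads per (spot, locus) from the planted locus
#' sequences, applying per-base substitution errors, and records every
#' read's true spot and source locus.
#'
#' Two output modes. `"aligned_sam"` (the aligner-free path) emits a SAM
#' file of alignment records directly: each read's reported alignment
#' locations, and hence its hit count, are determined by exhaustively
#' matching the read sequence against every planted locus at up to
#' `maxMismatch` mismatches — an explicit, testable stand-in for an
#' aligner. The true location is the primary record; other matching
#' locations become secondary records; all records carry the `NH` tag and
#' the spatial tags of the chosen dialect (`B1`/`B2` integer spot
#' coordinates for `original_st`, a `CB` barcode resolved through the
#' emitted barcode table for `tenx`). `"fastq_pairs"` emits the raw
#' spatial layout instead: read 1 carries the spot barcode plus a UMI
#' pad, read 2 the cDNA sequence.
#'
#' @param tegenome a [TEGenome-class].
#' @param plan a [SpotPlan-class]; every `locus_id` must exist in the
#'   genome's annotation and every locus must be at least one read long.
#' @param dir output directory.
#' @param mode `"aligned_sam"` or `"fastq_pairs"`.
#' @param dialect spatial dialect for the SAM tags / barcode table.
#' @param maxMismatch mismatch budget of the exhaustive matcher
#'   (default 3).
#' @param barcodeLength barcode length for generated spot barcodes.
#' @return list with elements `truth` (a [GroundTruth-class]) and `files`
#'   (named character vector of written paths: `sam` or `fastq1`/
#'   `fastq2`, plus `barcodes` and `truth`).
#' @export
simulateSpotReads <- function(tegenome, plan, dir,
                              mode = c("aligned_sam", "fastq_pairs"),
                              dialect = c("original_st", "tenx"),
                              maxMismatch = 3L, barcodeLength = 18L) {
  mode <- match.arg(mode)
  dialect <- match.arg(dialect)
  stopifnot(is(tegenome, "TEGenome"), is(plan, "SpotPlan"))
  validObject(plan)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- tegenome@annotation@loci
  lid <- mcols(g)$locus_id
  cc <- plan@counts
  missing_loci <- setdiff(cc$locus_id, lid)
  if (length(missing_loci))
    stop("plan references loci absent from the genome: ",
         paste(head(missing_loci, 3L), collapse = ", "))
  rl <- plan@readLength
  too_short <- width(g)[match(unique(cc$locus_id), lid)] < rl
  if (any(too_short))
    stop("locus shorter than the read length: ",
         paste(head(unique(cc$locus_id)[too_short], 3L), collapse = ", "))

  set.seed(plan@seed)
  genomeChars <- lapply(as.character(tegenome@genome), function(s)
    strsplit(s, "")[[1L]])

  ## draw reads
  cc <- cc[cc$n_reads > 0L, , drop = FALSE]
  reads <- vector("list", nrow(cc))
  for (i in seq_len(nrow(cc))) {
    li <- match(cc$locus_id[i], lid)
    ch <- as.character(seqnames(g))[li]
    len <- width(g)[li]
    starts <- sample.int(len - rl + 1L, cc$n_reads[i], replace = TRUE)
    seqs <- vapply(starts, function(s0) {
      gstart <- start(g)[li] + s0 - 1L
      chars <- genomeChars[[ch]][gstart:(gstart + rl - 1L)]
      paste(mutateSeq(chars, plan@errorRate), collapse = "")
    }, "")
    reads[[i]] <- data.frame(
      spot = cc$spot[i], locus_id = cc$locus_id[i],
      chrom = ch, gstart = start(g)[li] + starts - 1L, seq = seqs)
  }
  rd <- do.call(rbind, reads)
  rd$read_id <- sprintf("read%06d", seq_len(nrow(rd)))
  rd$subfamily <- mcols(g)$subfamily[match(rd$locus_id, lid)]
  rd$te_class <- mcols(g)$te_class[match(rd$locus_id, lid)]

  truth <- new("GroundTruth", reads = DataFrame(
    read_id = rd$read_id, spot = rd$spot, locus_id = rd$locus_id,
    subfamily = rd$subfamily, te_class = rd$te_class))
  truth_path <- file.path(dir, "truth_reads.tsv")
  write.table(as.data.frame(truth@reads), truth_path, sep = "\t",
              quote = FALSE, row.names = FALSE)

  xy <- parseSpotLabels(rd$spot)
  files <- c(truth = truth_path)

  ## spot barcode table (written in both modes; required by fastq mode)
  uspots <- sortSpotLabels(unique(rd$spot))
  repeat {
    bcs <- vapply(seq_along(uspots), function(.) randomDNA(barcodeLength),
                  "")
    if (!anyDuplicated(bcs)) break
  }
  uxy <- parseSpotLabels(uspots)
  bc_path <- file.path(dir, "barcodes.tsv")
  if (dialect == "original_st") {
    write.table(data.frame(bcs, uxy$x, uxy$y), bc_path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    write.table(data.frame(barcode = bcs, in_tissue = 1L,
                           array_row = uxy$x, array_col = uxy$y,
                           pxl_row = uxy$x * 100L, pxl_col = uxy$y * 100L),
                bc_path, sep = ",", quote = FALSE, row.names = FALSE)
  }
  files["barcodes"] <- bc_path
  spot_bc <- setNames(bcs, uspots)

  if (mode == "fastq_pairs") {
    umis <- vapply(seq_len(nrow(rd)), function(.) randomDNA(8L), "")
    r1seq <- paste0(spot_bc[rd$spot], umis)
    q <- function(s) strrep("I", nchar(s))
    f1 <- file.path(dir, "reads_R1.fastq")
    f2 <- file.path(dir, "reads_R2.fastq")
    writeLines(paste0("@", rd$read_id, "\n", r1seq, "\n+\n", q(r1seq)), f1)
    writeLines(paste0("@", rd$read_id, "\n", rd$seq, "\n+\n", q(rd$seq)), f2)
    files["fastq1"] <- f1
    files["fastq2"] <- f2
    return(list(truth = truth, files = files))
  }

  ## aligned_sam mode: exhaustive matching against all planted loci
  sub <- lociSubject(genomeChars, tegenome@annotation, rl)
  useq <- unique(rd$seq)
  locs_per_seq <- lapply(useq, function(s) {
    m <- matchPattern(DNAString(s), sub$subject,
                      max.mismatch = maxMismatch, with.indels = FALSE)
    st <- start(m)
    li <- findInterval(st, sub$offsets)
    keep <- st >= sub$offsets[li] &
      st + rl - 1L <= sub$offsets[li] + sub$lengths[li] - 1L
    cbind(locus = li[keep], off = st[keep] - sub$offsets[li][keep] + 1L)
  })
  names(locs_per_seq) <- useq

  sam_path <- file.path(dir, "reads.sam")
  chrlens <- nchar(as.character(tegenome@genome))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(tegenome@genome), chrlens),
           "@PG\tID:spotTE-sim\tPN:spotTE-sim")
  cigar <- paste0(rl, "M")
  qual <- strrep("I", rl)
  recs <- vector("list", nrow(rd))
  g_chrom <- as.character(seqnames(g))
  for (i in seq_len(nrow(rd))) {
    locs <- locs_per_seq[[rd$seq[i]]]
    gpos <- start(g)[locs[, "locus"]] + locs[, "off"] - 1L
    gchr <- g_chrom[locs[, "locus"]]
    is_true <- gchr == rd$chrom[i] & gpos == rd$gstart[i]
    if (!any(is_true)) {            # read mutated past the mismatch budget
      gchr <- c(rd$chrom[i], gchr)
      gpos <- c(rd$gstart[i], gpos)
      is_true <- c(TRUE, rep(FALSE, length(is_true)))
    }
    nh <- length(gpos)
    ord <- order(!is_true)          # primary (true location) first
    gchr <- gchr[ord]; gpos <- gpos[ord]
    flagv <- c(0L, rep(256L, nh - 1L))
    mapq <- if (nh == 1L) 255L else 3L
    tagsp <- if (dialect == "original_st") {
      sprintf("B1:i:%d\tB2:i:%d", xy$x[i], xy$y[i])
    } else {
      sprintf("CB:Z:%s", spot_bc[rd$spot[i]])
    }
    recs[[i]] <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d\t%s",
                         rd$read_id[i], flagv, gchr, gpos, mapq, cigar,
                         rd$seq[i], qual, nh, tagsp)
  }
  writeLines(c(hdr, unlist(recs)), sam_path)
  files["sam"] <- sam_path
  list(truth = truth, files = files)
}

#' Read a ground-truth table written by [simulateSpotReads()]
#'
#' @param path the `truth_reads.tsv` path.
#' @return a [GroundTruth-class].
#' @export
readGroundTruth <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  new("GroundTruth", reads = DataFrame(df))
}
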