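## TE annotation: RepeatMasker .out parsing, repeat-class taxonomy,
## BED-table conversion and exon intervals for the non-exonic filter.

#' Classify a RepeatMasker class/family string
#'
#' RepeatMasker annotates each repeat with a `class/family` string such as
#' `"LINE/L1"`, `"SINE/Alu"` or a bare class `"LINE"`; uncertain calls are
#' suffixed with `"?"`. The token before the `/` is mapped into the four
#' TE classes analyzed here (LINE, SINE, LTR, DNA); everything else —
#' including Retroposon/SVA-like classes — maps to `Other`.
#'
#' @param classFamily character vector of RepeatMasker class/family
#'   strings.
#' @return data.frame with columns `te_class` and `family` (empty string
#'   when the string has no family part).
#' @examples
#' classifyRepeat(c("LINE/L1", "LTR/ERVK", "DNA?", "Unknown"))
#' @export
classifyRepeat <- function(classFamily) {
  s <- gsub("?", "", as.character(classFamily), fixed = TRUE)
  parts <- strsplit(s, "/", fixed = TRUE)
  cls <- vapply(parts, function(p) if (length(p)) p[[1L]] else "", "")
  fam <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
  te_class <- ifelse(cls %in% c("LINE", "SINE", "LTR", "DNA"), cls, "Other")
  data.frame(te_class = te_class, family = fam, stringsAsFactors = FALSE)
}

makeLocusIds <- function(subfamily, chrom, start, end, strand) {
  ids <- sprintf("%s|%s:%d-%d(%s)", subfamily, chrom, start, end, strand)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "#")
  ids
}

newTEAnnotation <- function(chrom, start, end, strand, subfamily, family,
                            te_class, locus_id = NULL) {
  if (is.null(locus_id))
    locus_id <- makeLocusIds(subfamily, chrom, start, end, strand)
  g <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(g) <- DataFrame(locus_id = locus_id, subfamily = subfamily,
                        family = family, te_class = te_class)
  new("TEAnnotation", loci = g)
}

#' Parse a RepeatMasker .out annotation into TE loci
#'
#' Reads the standard RepeatMasker `.out` layout (3 header lines, then
#' whitespace-delimited columns: SW score, divergence, deletion,
#' insertion, query sequence, begin, end, (left), strand `+`/`C`, repeat
#' name, class/family, ...). Coordinates are 1-based inclusive and are
#' kept as such in the returned `GRanges`-backed annotation; strand `C`
#' (complement) becomes `-`. Rows whose repeat class is a non-TE repeat
#' (simple repeats, low complexity, satellites, structural RNAs) are
#' dropped by default; `"?"`-suffixed classes are normalized by stripping
#' the `"?"`.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @param excludeClasses character vector of repeat classes to drop
#'   (matched against the class token before any `/`). Set to
#'   `character(0)` to keep everything.
#' @param keepClasses optional character vector; when given, only rows
#'   whose TE class (after mapping) is in this set are kept, e.g.
#'   `c("LINE", "SINE", "LTR", "DNA")`.
#' @return a [TEAnnotation-class].
#' @export
readRepeatMasker <- function(path,
                             excludeClasses = DEFAULT_EXCLUDED_CLASSES,
                             keepClasses = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("not a RepeatMasker .out file (fewer than 3 header lines): ", path)
  body_idx <- seq_len(length(lines))[-(1:3)]
  body <- trimws(lines[body_idx])
  keep_line <- nzchar(body)
  body <- body[keep_line]
  lineno <- body_idx[keep_line]
  if (!length(body)) {
    warning("no annotation rows in ", path)
    return(newTEAnnotation(character(), integer(), integer(), character(),
                           character(), character(), character()))
  }
  fields <- strsplit(body, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed RepeatMasker row at line ", lineno[which(nf < 11L)[1L]],
         ": expected >= 11 whitespace-delimited fields")
  get <- function(i) vapply(fields, `[[`, "", i)
  begin <- suppressWarnings(as.integer(get(6L)))
  endp <- suppressWarnings(as.integer(get(7L)))
  strand_raw <- get(9L)
  bad <- which(is.na(begin) | is.na(endp) | begin > endp |
                 !(strand_raw %in% c("+", "C")))
  if (length(bad))
    stop("malformed RepeatMasker row at line ", lineno[bad[1L]],
         ": bad coordinates or strand field")
  chrom <- get(5L)
  subfam <- get(10L)
  clsfam <- get(11L)
  tax <- classifyRepeat(clsfam)
  cls_token <- gsub("?", "", vapply(strsplit(clsfam, "/", fixed = TRUE),
                                    `[[`, "", 1L), fixed = TRUE)
  drop <- cls_token %in% excludeClasses
  if (!is.null(keepClasses)) drop <- drop | !(tax$te_class %in% keepClasses)
  if (all(drop)) {
    warning("all rows excluded by repeat-class filter in ", path)
    return(newTEAnnotation(character(), integer(), integer(), character(),
                           character(), character(), character()))
  }
  keep <- !drop
  newTEAnnotation(chrom[keep], begin[keep], endp[keep],
                  ifelse(strand_raw[keep] == "C", "-", "+"),
                  subfam[keep], tax$family[keep], tax$te_class[keep])
}

#' Write / read the converted TE annotation table
#'
#' The converted table is BED6 plus three taxonomy columns: `chrom`,
#' `start` (0-based), `end` (exclusive), `locus_id`, `score` (0),
#' `strand`, `subfamily`, `family`, `te_class`, tab-separated with no
#' header. Re-reading reproduces every field of the annotation.
#'
#' @param annotation a [TEAnnotation-class].
#' @param path output (or input) file path.
#' @return `writeTETable` returns `path` invisibly; `readTETable` returns
#'   a [TEAnnotation-class].
#' @export
writeTETable <- function(annotation, path) {
  stopifnot(is(annotation, "TEAnnotation"))
  g <- annotation@loci
  df <- data.frame(
    chrom = as.character(seqnames(g)),
    start = start(g) - 1L,              # BED convention on disk
    end = end(g),
    locus_id = mcols(g)$locus_id,
    score = 0L,
    strand = as.character(strand(g)),
    subfamily = mcols(g)$subfamily,
    family = mcols(g)$family,
    te_class = mcols(g)$te_class)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeTETable
#' @export
readTETable <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "locus_id",
                                 "score", "strand", "subfamily", "family",
                                 "te_class"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character",
                                  "character", "character", "character"))
  newTEAnnotation(df$chrom, df$start + 1L, df$end, df$strand,
                  df$subfamily, df$family, df$te_class,
                  locus_id = df$locus_id)
}

#' Read a TE annotation, auto-detecting its format
#'
#' Dispatches on content: RepeatMasker `.out` files (detected by the
#' `.out` extension or the SW-score header) go through
#' [readRepeatMasker()]; anything else is read as the converted 9-column
#' table ([readTETable()]).
#'
#' @param path annotation file path.
#' @param ... passed to [readRepeatMasker()].
#' @return a [TEAnnotation-class].
#' @export
readTEAnnotation <- function(path, ...) {
  if (grepl("\\.out(\\.gz)?$", path))
    return(readRepeatMasker(path, ...))
  first <- readLines(path, n = 1L)
  if (grepl("SW", first) && grepl("score|perc", first))
    readRepeatMasker(path, ...)
  else
    readTETable(path)
}

#' Parse exon intervals from a GTF gene annotation
#'
#' Extracts all `exon` features and merges overlapping intervals per
#' chromosome, strand-agnostically: the result is the exonic portion of
#' the genome, against which reads are tested by the non-exonic filter.
#'
#' @param path a GTF file with `exon` feature rows.
#' @return a reduced, unstranded `GRanges` of exon intervals.
#' @export
readExonAnnotation <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[g$type == "exon"]
  if (!length(g))
    stop("no 'exon' features in ", path,
         "; the non-exonic filter requires exon annotation")
  reduce(granges(g), ignore.strand = TRUE)
}
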