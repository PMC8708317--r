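## Spot-resolved alignment streaming for the two spatial dialects:
## "original_st" (integer spot-coordinate tags, or a barcode tag plus a
## barcode/x/y table) and "tenx" (corrected cell-barcode tag plus a
## tissue-positions table).

#' Load a barcode-to-spot table
#'
#' Two dialects are supported. `original_st`: a whitespace-delimited
#' table with columns barcode, x, y (no header). `tenx`: a
#' tissue-positions CSV with columns barcode, in_tissue, array_row,
#' array_col, pixel row/col (header optional); out-of-tissue rows are
#' retained but flagged so in-tissue filtering remains a downstream
#' option. Spot labels are `"XxY"` for original_st and `"ROWxCOL"` for
#' tenx.
#'
#' @param path barcode table path.
#' @param dialect `"original_st"` or `"tenx"`.
#' @return a [BarcodeMap-class].
#' @export
readBarcodeMap <- function(path, dialect = c("original_st", "tenx")) {
  dialect <- match.arg(dialect)
  if (dialect == "original_st") {
    df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L)
      stop("original_st barcode file needs 3 columns (barcode, x, y): ",
           path)
    bc <- as.character(df[[1L]])
    x <- as.integer(df[[2L]]); y <- as.integer(df[[3L]])
    tissue <- rep(TRUE, nrow(df))
  } else {
    first <- readLines(path, n = 1L)
    has_header <- grepl("barcode", first, ignore.case = TRUE)
    df <- read.csv(path, header = has_header, stringsAsFactors = FALSE)
    if (ncol(df) < 4L)
      stop("tissue-positions file needs >= 4 columns: ", path)
    bc <- as.character(df[[1L]])
    tissue <- as.integer(df[[2L]]) == 1L
    x <- as.integer(df[[3L]]); y <- as.integer(df[[4L]])
  }
  if (anyNA(x) || anyNA(y))
    stop("non-integer spot coordinates in ", path)
  dup <- duplicated(bc)
  if (any(dup)) {
    idx <- match(bc[dup], bc)
    if (any(x[dup] != x[idx] | y[dup] != y[idx]))
      stop("duplicate barcode with conflicting coordinates in ", path)
    keep <- !dup
    bc <- bc[keep]; x <- x[keep]; y <- y[keep]; tissue <- tissue[keep]
  }
  new("BarcodeMap", barcode = bc, x = x, y = y,
      spot = sprintf("%dx%d", x, y), inTissue = tissue)
}

samToBam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  asBam(path, destination = dest, overwrite = TRUE, indexDestination = FALSE)
}

#' Stream spot-resolved reads from a spatial SAM/BAM file
#'
#' Reads every mapped record, resolves each read's spatial spot, and
#' folds the records belonging to one read (primary plus secondary /
#' supplementary alignments) into a single entry whose aligned blocks are
#' the union over all reported alignment locations. The number of
#' reported hits is taken from the hit-count tag (default `NH`) when
#' present, otherwise counted across records sharing the read name; a
#' read seen once with no hit-count tag is classified later through the
#' unique-MAPQ fallback (see [mappingStatus()]).
#'
#' Spot resolution per dialect: `original_st` uses two integer
#' spot-coordinate tags (default `B1` = x, `B2` = y), or a barcode tag
#' resolved through `barcodeMap` when the coordinate tags are absent;
#' `tenx` uses the corrected cell-barcode tag (default `CB`) resolved
#' through `barcodeMap`. Reads without resolvable spatial information are
#' skipped and tallied in the returned object's log.
#'
#' @param path SAM or BAM file (SAM is converted in a temporary
#'   directory).
#' @param dialect `"original_st"` or `"tenx"`.
#' @param barcodeMap a [BarcodeMap-class]; required for `tenx`, optional
#'   for `original_st`.
#' @param spotTags length-2 character, the x/y integer tag names for
#'   `original_st` (default `c("B1", "B2")`).
#' @param barcodeTag the cell/spot barcode tag (default `"CB"`).
#' @param nhTag the hit-count tag (default `"NH"`).
#' @param umiTag optional UMI tag name (e.g. `"UB"`); carried through for
#'   optional deduplication at assignment time.
#' @param uniqueMapq MAPQ value meaning "unique" when the hit-count tag
#'   is absent (default 255, the STAR convention).
#' @param inTissueOnly drop reads whose barcode is flagged out-of-tissue
#'   (default `FALSE`: out-of-tissue spots are kept).
#' @return a [SpotAlignments-class].
#' @export
readSpotAlignments <- function(path, dialect = c("original_st", "tenx"),
                               barcodeMap = NULL,
                               spotTags = c("B1", "B2"),
                               barcodeTag = "CB", nhTag = "NH",
                               umiTag = NULL, uniqueMapq = 255L,
                               inTissueOnly = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "tenx" && is.null(barcodeMap))
    stop("the tenx dialect requires a barcodeMap (tissue-positions table)")
  tags <- unique(c(nhTag, if (dialect == "original_st") spotTags,
                   barcodeTag, umiTag))
  bam <- samToBam(path)
  param <- ScanBamParam(what = c("qname", "flag", "mapq"), tag = tags)
  gal <- readGAlignments(bam, param = param)
  m <- mcols(gal)
  nrec <- length(gal)
  if (!nrec)
    stop("no mapped records in ", path)

  tagcol <- function(tag) {
    if (!is.null(tag) && tag %in% colnames(m)) m[[tag]] else rep(NA, nrec)
  }

  ## per-record spot resolution
  unknown_bc <- 0L
  if (dialect == "original_st") {
    b1 <- suppressWarnings(as.integer(tagcol(spotTags[1L])))
    b2 <- suppressWarnings(as.integer(tagcol(spotTags[2L])))
    spot_rec <- ifelse(!is.na(b1) & !is.na(b2),
                       sprintf("%dx%d", b1, b2), NA_character_)
    if (!is.null(barcodeMap)) {
      bc <- as.character(tagcol(barcodeTag))
      need <- is.na(spot_rec) & !is.na(bc)
      idx <- match(bc[need], barcodeMap@barcode)
      spot_rec[need] <- barcodeMap@spot[idx]
    }
  } else {
    bc <- as.character(tagcol(barcodeTag))
    idx <- match(bc, barcodeMap@barcode)
    spot_rec <- barcodeMap@spot[idx]
    if (inTissueOnly)
      spot_rec[!is.na(idx) & !barcodeMap@inTissue[idx]] <- NA_character_
  }

  ## dialect sanity check on the head of the file
  head_n <- min(nrec, 1000L)
  if (mean(is.na(spot_rec[seq_len(head_n)])) > 0.5)
    stop("more than half of the first ", head_n, " records carry no ",
         "resolvable spatial information under dialect '", dialect,
         "'; is the file in the other dialect?")

  nh <- suppressWarnings(as.integer(tagcol(nhTag)))
  umi_rec <- as.character(tagcol(umiTag))
  blocks <- grglist(gal)

  rec <- data.table(
    rec = seq_len(nrec), read_id = m$qname, flag = m$flag,
    mapq = as.integer(m$mapq), nh = nh, spot = spot_rec, umi = umi_rec,
    secondary = bitwAnd(m$flag, 256L) > 0L | bitwAnd(m$flag, 2048L) > 0L)

  per_read <- rec[, .(
    nh = if (all(is.na(nh))) {
      if (.N > 1L) .N else NA_integer_
    } else max(nh, na.rm = TRUE),
    mapq = max(mapq),
    spot = if (any(!is.na(spot))) spot[!is.na(spot)][1L] else NA_character_,
    umi = if (any(!is.na(umi))) umi[!is.na(umi)][1L] else NA_character_
  ), by = read_id]

  skipped <- sum(is.na(per_read$spot))
  kept <- per_read[!is.na(spot)]

  ## fold aligned blocks across each read's records (vectorized:
  ## unlist all blocks, regroup by read, merge overlaps)
  ubl <- unlist(blocks, use.names = FALSE)
  rec_of_block <- rep.int(seq_len(nrec), lengths(blocks))
  read_of_block <- match(rec$read_id[rec_of_block], kept$read_id)
  ok <- !is.na(read_of_block)
  grl <- reduce(
    S4Vectors::split(ubl[ok],
                     factor(read_of_block[ok],
                            levels = seq_len(nrow(kept)))),
    ignore.strand = TRUE)
  names(grl) <- NULL

  new("SpotAlignments",
      blocks = grl, readId = kept$read_id, nHits = kept$nh,
      mapq = kept$mapq, spot = kept$spot, umi = kept$umi,
      uniqueMapq = as.integer(uniqueMapq),
      log = list(records = nrec,
                 primaryRecords = sum(!rec$secondary),
                 readsEmitted = nrow(kept),
                 skippedNoSpot = skipped))
}
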