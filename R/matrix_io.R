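## Spot-matrix TSV serialization: feature ids as columns, spot
## coordinates as rows, tab-separated.

#' Write a spot matrix as TSV
#'
#' Tab-separated with the feature identifiers as columns and spot
#' coordinates as rows: the first header field is `spot`, each following
#' header field a feature id; each data row starts with the `"XxY"` spot
#' label. Rows are sorted by (x, y). Integer-valued matrices are written
#' without decimal points; real-valued (log-scaled) matrices with full
#' precision so that re-reading reproduces them to within 1e-9.
#'
#' @param mat a [SpotMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpotMatrix <- function(mat, path) {
  stopifnot(is(mat, "SpotMatrix"))
  m <- counts(mat)
  m <- m[sortSpotLabels(rownames(m)), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("spot", colnames(m)), collapse = "\t"), con)
  fmt <- function(v) {
    if (all(v == round(v))) format(as.integer(round(v)), trim = TRUE)
    else format(v, digits = 15, trim = TRUE, scientific = FALSE)
  }
  body <- if (ncol(m)) apply(m, 1L, function(v) paste(fmt(v), collapse = "\t"))
          else character(nrow(m))
  lines <- if (ncol(m)) paste(rownames(m), body, sep = "\t") else rownames(m)
  writeLines(lines, con)
  invisible(path)
}

#' Read a spot matrix written by [writeSpotMatrix()]
#'
#' Exact inverse of the writer: labels, order and values are reproduced
#' (bit-exact for integer matrices). Ragged rows and duplicate labels are
#' errors naming the offending line.
#'
#' @param path TSV path.
#' @param featureType feature resolution to record on the result.
#' @return a [SpotMatrix-class].
#' @export
readSpotMatrix <- function(path, featureType = c("locus", "subfamily",
                                                 "class")) {
  featureType <- match.arg(featureType)
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  features <- header[-1L]
  if (anyDuplicated(features))
    stop("duplicate feature labels in header of ", path)
  nfield <- length(header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != nfield)
  if (length(bad))
    stop("ragged row at line ", bad[1L] + 1L, " of ", path, ": expected ",
         nfield, " fields, found ", nf[bad[1L]])
  spots <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(spots)) {
    d <- which(duplicated(spots))[1L]
    stop("duplicate spot label at line ", d + 1L, " of ", path)
  }
  vals <- if (length(features)) {
    v <- vapply(rows, function(r) as.numeric(r[-1L]), numeric(nfield - 1L))
    if (nfield == 2L) matrix(v, ncol = 1L) else t(v)
  } else matrix(numeric(0), nrow = length(spots), ncol = 0L)
  dimnames(vals) <- list(spots, if (length(features)) features else NULL)
  new("SpotMatrix", counts = vals, featureType = featureType)
}
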