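#' Round half away from zero
#'
#' Integer copy numbers are obtained by conventional "half-up" rounding rather
#' than R's banker's rounding, so that e.g. a copy-number estimate of 2.5 is
#' always called 3.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
roundHalfUp <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Modified Z-score (median/MAD)
#'
#' Robust outlier score `0.6745 * (x - median(x)) / MAD(x)` with the unscaled
#' median absolute deviation. Used to flag segments whose read depth is
#' implausibly high (score above 3.5).
#'
#' @param x numeric vector.
#' @return numeric vector of modified Z-scores. A zero MAD (more than half the
#'   values tied at the median) falls back to the mean absolute deviation,
#'   `(x - median) / (1.253314 * meanAD)`, the standard Iglewicz-Hoaglin
#'   recipe; when that is zero too (all values equal) every score is 0 and a
#'   warning is raised.
#' @export
#' @examples
#' modifiedZScore(c(100, 100, 100, 100, 1000))
modifiedZScore <- function(x) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 > 0) {
    return(0.6745 * (x - med) / mad0)
  }
  meanAD <- mean(abs(x - med))
  if (meanAD == 0) {
    warning("MAD is zero; modified Z-scores undefined, returning zeros")
    return(rep(0, length(x)))
  }
  (x - med) / (1.253314 * meanAD)
}

## internal: assert a data.frame has the given columns
.assertColumns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

## internal: NULL-default operator
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a 0-based half-open segment/bin table to GRanges
#'
#' Bins and segments use 0-based half-open coordinates (the CNVkit dialect);
#' variants are 1-based inclusive. All conversions between the two conventions
#' go through this pair of helpers so the off-by-one logic lives in one place:
#' half-open `[start, end)` maps to the 1-based closed interval
#' `[start + 1, end]`.
#'
#' @param df data.frame with `chromosome`, `start`, `end` (0-based half-open).
#' @return a [GenomicRanges::GRanges] with 1-based closed ranges.
#' @export
segmentsToGRanges <- function(df) {
  .assertColumns(df, c("chromosome", "start", "end"), "segment/bin table")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chromosome,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  extra <- setdiff(names(df), c("chromosome", "start", "end"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[extra]
  gr
}

#' @rdname segmentsToGRanges
#' @param pos 1-based positions.
#' @param chromosome chromosome names matching `pos`.
#' @export
positionsToGRanges <- function(chromosome, pos) {
  GenomicRanges::GRanges(seqnames = chromosome,
                         ranges = IRanges::IRanges(start = pos, width = 1L))
}

#' Look up the segment copy number covering each position
#'
#' @param segments segment table (0-based half-open) carrying a `cn_int`
#'   column (see [repairUnreliableSegments()] / [cnFromLog2()]).
#' @param chromosome,pos 1-based variant coordinates.
#' @return integer vector of copy numbers; `NA` where no segment covers the
#'   position.
#' @export
segmentCnAtPositions <- function(segments, chromosome, pos) {
  .assertColumns(segments, c("chromosome", "start", "end", "cn_int"),
                 "segment table")
  segGr <- segmentsToGRanges(segments)
  varGr <- positionsToGRanges(chromosome, pos)
  hits <- GenomicRanges::findOverlaps(varGr, segGr, select = "first")
  out <- rep(NA_integer_, length(varGr))
  ok <- !is.na(hits)
  out[ok] <- as.integer(segments$cn_int[hits[ok]])
  out
}

## internal: 0-based start of the fixed-width bin containing a 1-based position
.binStart <- function(pos, binSize) {
  as.numeric(floor((pos - 1) / binSize) * binSize)
}

## internal: deterministic variant key
.variantKey <- function(chromosome, pos, ref, alt) {
  paste(chromosome, pos, ref, alt, sep = ":")
}
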