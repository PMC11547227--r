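## Purity-rescaled copy number, segment repair, LGA counting, gene
## amplification calls, inter-sample divergence, profile clustering and the
## paired region-density test.
##
## A bin or segment log2 copy ratio against a flat diploid reference mixes
## tumour and normal DNA: 2^log2r = (t*CN + 2(1-t)) / 2. Rescaling by the
## estimated tumour fraction t inverts that mixture:
##   CN = (2 * 2^log2r - 2(1-t)) / t, floored at 0.

#' Purity-rescaled copy number from a log2 ratio
#'
#' @param log2r log2 copy ratio(s) against a flat diploid reference.
#' @param t tumour fraction in `(0, 1]`.
#' @return continuous copy-number estimate `max(0, (2*2^log2r - 2(1-t))/t)`.
#' @export
#' @examples
#' cnFromLog2(0, 1)              # 2
#' cnFromLog2(log2(0.75), 0.5)   # 1
cnFromLog2 <- function(log2r, t) {
  if (any(t <= 0) || any(t > 1)) stop("purity t must lie in (0, 1]")
  pmax(0, (2 * 2^log2r - 2 * (1 - t)) / t)
}

#' Forward model: log2 ratio expected from a copy number
#'
#' Exact inverse of [cnFromLog2()]; the simulator generates bin log2 values
#' with it, so rescaling is exactly invertible at zero noise.
#'
#' @param cn true copy number(s).
#' @param t tumour fraction in `[0, 1]`.
#' @return `log2((t*cn + 2(1-t)) / 2)`.
#' @export
log2FromCn <- function(cn, t) {
  log2((t * cn + 2 * (1 - t)) / 2)
}

#' Attach copy-number estimates to a segment table
#'
#' Adds `cn_est` ([cnFromLog2()]) and `cn_int` (half-up rounding; LGA and
#' divergence compare integer copy numbers so that a "disparate copy number"
#' requires a whole-copy difference, robust to log2 noise).
#'
#' @param segments segment table with `log2`.
#' @param t tumour fraction of the sample.
#' @return the segment table with `cn_est` and `cn_int` columns.
#' @export
segmentCopyNumbers <- function(segments, t) {
  segments$cn_est <- cnFromLog2(segments$log2, t)
  segments$cn_int <- roundHalfUp(segments$cn_est)
  segments
}

#' Repair segments with outlying read depth
#'
#' Computes the modified Z-score of `mean_depth` over a sample's segments
#' ([modifiedZScore()]); segments scoring above 3.5 (one-sided, high — the
#' concern is collapsed repeats and capture artefacts inflating depth) are
#' unreliable: their `cn_est` is replaced by the mean of the flanking
#' segments' (pre-repair) estimates, a single flank at contig ends, and
#' `cn_int` is re-rounded. Segments at or below the cutoff are never changed.
#'
#' @param segments one sample's segment table with `chromosome`, `start`,
#'   `end`, `cn_est`, `cn_int` and `mean_depth` (or `depth`) columns, sorted.
#' @param zCutoff modified-Z cutoff (default 3.5).
#' @return segment table with repaired `cn_est`/`cn_int` and a logical
#'   `unreliable` column. Zero MAD flags nothing (with a warning).
#' @export
repairUnreliableSegments <- function(segments, zCutoff = 3.5) {
  depthCol <- if ("mean_depth" %in% names(segments)) "mean_depth" else "depth"
  .assertColumns(segments, c("chromosome", "start", "end", "cn_est", depthCol),
                 "segment table")
  z <- modifiedZScore(segments[[depthCol]])
  flag <- z > zCutoff
  segments$unreliable <- flag
  if (!any(flag)) {
    segments$cn_int <- roundHalfUp(segments$cn_est)
    return(segments)
  }
  pre <- segments$cn_est
  for (i in which(flag)) {
    chr <- segments$chromosome[i]
    left <- if (i > 1L && segments$chromosome[i - 1L] == chr &&
                !flag[i - 1L]) pre[i - 1L] else NA_real_
    right <- if (i < nrow(segments) && segments$chromosome[i + 1L] == chr &&
                 !flag[i + 1L]) pre[i + 1L] else NA_real_
    repl <- mean(c(left, right), na.rm = TRUE)
    if (!is.nan(repl)) segments$cn_est[i] <- repl
  }
  segments$cn_int <- roundHalfUp(segments$cn_est)
  segments
}

#' Count large-scale genomic alterations (LGAs)
#'
#' Per chromosome, the ordered subsequence of segments strictly longer than
#' `minLen` (10 Mb) is scanned; every boundary between consecutive qualifying
#' members whose integer copy numbers differ counts one LGA (shorter
#' interveners are skipped, the reading consistent with "adjacent to other
#' large segments"). `counting = "segment"` instead counts qualifying
#' segments whose copy number differs from the previous qualifying member —
#' the alternative reading, exposed as an option.
#'
#' @param segments repaired segment table with `cn_int`.
#' @param minLen minimum segment length in bp, strict (default 10 Mb).
#' @param counting `"boundary"` (default) or `"segment"`.
#' @return list with `lga_count` and a `breakpoints` data.frame
#'   (`chromosome`, `position` — the boundary coordinate between the two
#'   qualifying segments).
#' @export
countLga <- function(segments, minLen = 1e7,
                     counting = c("boundary", "segment")) {
  counting <- match.arg(counting)
  .assertColumns(segments, c("chromosome", "start", "end", "cn_int"),
                 "segment table")
  segments <- segments[order(segments$chromosome, segments$start), ,
                       drop = FALSE]
  bp <- list()
  count <- 0L
  for (chr in unique(segments$chromosome)) {
    q <- segments[segments$chromosome == chr &
                    (segments$end - segments$start) > minLen, , drop = FALSE]
    if (nrow(q) < 2L) next
    diffs <- which(q$cn_int[-1] != q$cn_int[-nrow(q)])
    count <- count + length(diffs)
    if (length(diffs)) {
      bp[[chr]] <- data.frame(chromosome = chr,
                              position = q$end[diffs],
                              stringsAsFactors = FALSE)
    }
  }
  breakpoints <- if (length(bp)) do.call(rbind, bp) else
    data.frame(chromosome = character(), position = numeric())
  rownames(breakpoints) <- NULL
  list(lga_count = count, breakpoints = breakpoints)
}

#' Call gene amplifications from segment copy numbers
#'
#' Each gene's copy number is the length-weighted mean of the `cn_est` of
#' overlapping segments; fold change is `cn_est / 2` and a gene is amplified
#' iff fold is strictly greater than `foldThreshold`.
#'
#' @param segments segment table with `cn_est`.
#' @param genes a `GRanges` of gene intervals with a `name` column (see
#'   [readBedGenes()]).
#' @param foldThreshold strict fold-change cutoff (default 2).
#' @return data.frame with `gene`, `cn_est`, `fold`, `amplified`. Genes with
#'   no overlapping segment get `NA` copy number and are not amplified.
#' @export
callGeneAmplifications <- function(segments, genes, foldThreshold = 2) {
  .assertColumns(segments, c("chromosome", "start", "end", "cn_est"),
                 "segment table")
  segGr <- segmentsToGRanges(segments)
  nm <- if (!is.null(genes$name)) genes$name else as.character(seq_along(genes))
  hits <- GenomicRanges::findOverlaps(genes, segGr)
  ovl <- GenomicRanges::pintersect(
    genes[S4Vectors::queryHits(hits)],
    segGr[S4Vectors::subjectHits(hits)]
  )
  w <- GenomicRanges::width(ovl)
  cnHit <- segments$cn_est[S4Vectors::subjectHits(hits)]
  cn <- rep(NA_real_, length(genes))
  agg <- tapply(seq_along(w), S4Vectors::queryHits(hits), function(idx)
    sum(w[idx] * cnHit[idx]) / sum(w[idx]))
  cn[as.integer(names(agg))] <- as.numeric(agg)
  fold <- cn / 2
  data.frame(gene = nm, cn_est = cn, fold = fold,
             amplified = !is.na(fold) & fold > foldThreshold,
             stringsAsFactors = FALSE)
}

## internal: integer CN of the segment covering each bin (by bin midpoint)
.binSegmentCn <- function(bins, segments) {
  mid <- floor((bins$start + bins$end) / 2) + 1  # 1-based midpoint
  segmentCnAtPositions(segments, bins$chromosome, mid)
}

#' Percent of bin sites with disparate copy number between two samples
#'
#' Assigns each bin the integer copy number of its covering segment in each
#' sample and reports the percentage of bins where the two assignments
#' differ. Bins not covered by a segment in both samples are excluded.
#'
#' @param binsA,binsB bin tables on an identical grid.
#' @param segmentsA,segmentsB the two samples' segment tables with `cn_int`.
#' @return percent of comparable bins with differing copy number (0-100).
#' @export
profileDivergence <- function(binsA, binsB, segmentsA, segmentsB) {
  if (nrow(binsA) != nrow(binsB) ||
      !all(binsA$chromosome == binsB$chromosome) ||
      !all(binsA$start == binsB$start) || !all(binsA$end == binsB$end)) {
    stop("bin grids differ between the two samples")
  }
  cnA <- .binSegmentCn(binsA, segmentsA)
  cnB <- .binSegmentCn(binsB, segmentsB)
  ok <- !is.na(cnA) & !is.na(cnB)
  if (!any(ok)) stop("no bin is covered by segments in both samples")
  100 * mean(cnA[ok] != cnB[ok])
}

#' Hierarchically cluster per-sample copy-ratio profiles
#'
#' Average-linkage hierarchical clustering on correlation distance
#' `1 - cor(profile_i, profile_j)` between per-sample bin log2 vectors.
#' Constant profiles have undefined correlation; such pairs are assigned
#' distance 1 with a warning.
#'
#' @param profiles numeric matrix, samples in rows (rownames = sample ids),
#'   bins in columns; all samples share one bin grid.
#' @param cutHeight distance at which flat clusters are cut (default 0.5).
#' @return list with `hclust` (the dendrogram) and `clusters` (named integer
#'   vector of flat cluster labels).
#' @export
clusterProfiles <- function(profiles, cutHeight = 0.5) {
  if (nrow(profiles) < 2L) stop("need at least 2 samples to cluster")
  sds <- apply(profiles, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("constant profile(s): ",
            paste(rownames(profiles)[sds == 0], collapse = ", "),
            "; correlation undefined, using distance 1")
  }
  cc <- suppressWarnings(stats::cor(t(profiles)))
  cc[is.na(cc)] <- 0  # constant profile => distance 1
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, clusters = stats::cutree(hc, h = cutHeight))
}

#' Paired region read-density test
#'
#' Classical two-sided paired t-test on per-sample reads-per-Mb differences
#' between two regions (used to corroborate a suspected regional deletion,
#' e.g. 17p13.1 against the similarly sized 17q21.31).
#'
#' @param regionA,regionB numeric vectors of reads per Mb, paired by sample.
#' @return list with `t`, `df`, `p`, `mean_diff`. With zero variance of the
#'   differences the test is undefined: `t` and `p` are `NA` and
#'   `undefined = TRUE`.
#' @export
regionDensityTest <- function(regionA, regionB) {
  if (length(regionA) != length(regionB)) stop("regions must be paired")
  if (length(regionA) < 2L) stop("need at least 2 pairs")
  d <- regionA - regionB
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_diff = mean(d), undefined = TRUE))
  }
  tt <- stats::t.test(regionA, regionB, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), undefined = FALSE)
}

#' Naive fallback segmentation of a bin table
#'
#' Plumbing for users without a segment file: merges consecutive bins of a
#' chromosome while the running segment mean and the next bin's log2 differ
#' by less than `gap`. Not a substitute for a principled segmentation; off by
#' default throughout the pipeline.
#'
#' @param bins bin table (`chromosome`, `start`, `end`, `log2`, optional
#'   `depth`).
#' @param gap |delta log2| merge threshold (default 0.3).
#' @return segment table with `chromosome`, `start`, `end`, `log2`
#'   (bin-mean), `n_bins`, `mean_depth`.
#' @export
naiveSegments <- function(bins, gap = 0.3) {
  .assertColumns(bins, c("chromosome", "start", "end", "log2"), "bin table")
  bins <- bins[order(bins$chromosome, bins$start), , drop = FALSE]
  res <- list()
  for (chr in unique(bins$chromosome)) {
    b <- bins[bins$chromosome == chr, , drop = FALSE]
    segStart <- 1L
    runMean <- b$log2[1]
    n <- 1L
    flush <- function(from, to) {
      idx <- from:to
      data.frame(chromosome = chr, start = b$start[from], end = b$end[to],
                 log2 = mean(b$log2[idx]), n_bins = length(idx),
                 mean_depth = if ("depth" %in% names(b))
                   mean(b$depth[idx]) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(b))[-1]) {
      if (abs(b$log2[i] - runMean) < gap) {
        n <- n + 1L
        runMean <- runMean + (b$log2[i] - runMean) / n
      } else {
        res[[length(res) + 1L]] <- flush(segStart, i - 1L)
        segStart <- i
        runMean <- b$log2[i]
        n <- 1L
      }
    }
    res[[length(res) + 1L]] <- flush(segStart, nrow(b))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
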