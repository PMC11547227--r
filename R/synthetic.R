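## Synthetic ascites cfDNA cohorts with full ground truth.
##
## The simulator emulates the study design this pipeline targets: serial
## ascites cfDNA samples per participant on a targeted panel, a truncal
## deleterious TP53 variant inside a 17p deletion (the double-hit anchor),
## subclones with per-sample cancer cell fractions, allele-specific
## copy-number segments (LOH tracts, planted large-segment boundaries, an
## optional focal amplification), germline het SNPs with population-AF
## annotations, (beta-)binomial read counts, and an FFPE-artifact noise mode.
## Every generative parameter is recorded in the truth slot so downstream
## estimates can be verified.
##
## Forward model for bin log2 ratios: log2((t*CN + 2(1-t))/2) + N(0, sd) -
## the exact inverse of cnFromLog2(), so rescaling is invertible at zero
## noise.

#' Expected VAF of a variant under admixture
#'
#' `v = (m*t*ccf + g*(1-t)) / (t*cn + 2*(1-t))`, clipped to `[0, 1]`:
#' a variant carried at multiplicity `m` by a fraction `ccf` of tumour cells
#' whose locus has tumour copy number `cn`, with `g` germline copies
#' (0 somatic, 1 germline het) in the diploid normal compartment, at tumour
#' fraction `t`.
#'
#' @param t tumour fraction in `[0, 1]`.
#' @param ccf cancer cell fraction in `[0, 1]` (1 for germline/truncal).
#' @param multiplicity copies per tumour cell carrying the variant
#'   (must not exceed `cnTumour` unless both are 0).
#' @param cnTumour locus copy number in tumour cells.
#' @param germlineCopies 0 (somatic) or 1 (germline heterozygous).
#' @return expected VAF in `[0, 1]`. A zero denominator (`t = 1`, `cn = 0`)
#'   returns 0 with a warning (the locus yields no DNA).
#' @export
#' @examples
#' expectedVaf(0.5, 1, 1, 1)                      # TP53 double-hit: 1/3
#' expectedVaf(0.5, 1, 1, 1, germlineCopies = 1)  # germline het on LOH: 2/3
expectedVaf <- function(t, ccf = 1, multiplicity = 1, cnTumour = 2,
                        germlineCopies = 0) {
  if (any(t < 0) || any(t > 1)) stop("t must lie in [0, 1]")
  if (any(ccf < 0) || any(ccf > 1)) stop("ccf must lie in [0, 1]")
  bad <- multiplicity > cnTumour & !(cnTumour == 0 & multiplicity == 0)
  if (any(bad)) stop("multiplicity must not exceed cnTumour")
  num <- multiplicity * t * ccf + germlineCopies * (1 - t)
  den <- t * cnTumour + 2 * (1 - t)
  v <- rep(0, length(num + den))
  zero <- den == 0
  if (any(zero)) warning("zero denominator (t = 1, cn = 0); VAF defined as 0")
  v[!zero] <- (num / den)[!zero]
  pmin(pmax(v, 0), 1)
}

#' Draw alt read counts from a (beta-)binomial
#'
#' `rho = 0` gives pure binomial sampling; `rho > 0` adds beta-binomial
#' overdispersion with the standard intra-class parameterisation
#' `a = p(1-rho)/rho`, `b = (1-p)(1-rho)/rho`.
#'
#' @param expVaf expected VAF(s) in `[0, 1]`.
#' @param depth read depth(s), >= 1.
#' @param rho overdispersion in `[0, 1)` (default 0).
#' @return integer vector of alt counts in `[0, depth]`.
#' @export
sampleReadCounts <- function(expVaf, depth, rho = 0) {
  if (any(depth < 1)) stop("depth must be >= 1")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  n <- max(length(expVaf), length(depth))
  p <- rep_len(expVaf, n)
  depth <- rep_len(depth, n)
  if (rho > 0) {
    inner <- p != 0 & p != 1
    if (any(inner)) {
      a <- p[inner] * (1 - rho) / rho
      b <- (1 - p[inner]) * (1 - rho) / rho
      p[inner] <- stats::rbeta(sum(inner), a, b)
    }
  }
  as.integer(stats::rbinom(n, depth, p))
}

#' Inject FFPE-like artefact variants
#'
#' Appends `nExtra` low-VAF noise variants at random loci with population AF
#' annotations of 0 — they pass the somatic triage, inflating the sample's
#' total variant count the way artefact-laden FFPE libraries do (and are then
#' caught by [flagVariantCountOutliers()]).
#'
#' @param variants one sample's variant table.
#' @param nExtra number of artefact variants to add (>= 0).
#' @param vafRange VAF range the artefacts are drawn from (default
#'   `c(0.01, 0.10)`).
#' @param genome a [GenomeModel-class] for locus placement.
#' @return the variant table with `nExtra` appended rows.
#' @export
injectFfpeArtifacts <- function(variants, nExtra, vafRange = c(0.01, 0.10),
                                genome = hg19Genome()) {
  if (nExtra < 0) stop("nExtra must be >= 0")
  if (nExtra == 0) return(variants)
  lens <- contigLengths(genome)
  chrom <- sample(names(lens), nExtra, replace = TRUE,
                  prob = lens / sum(lens))
  pos <- floor(stats::runif(nExtra, 1, lens[chrom]))
  depth <- if (nrow(variants) > 0)
    sample(variants$depth, nExtra, replace = TRUE) else rep(500L, nExtra)
  vaf <- stats::runif(nExtra, vafRange[1], vafRange[2])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nExtra, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  extra <- data.frame(
    chrom = chrom, pos = as.numeric(pos), ref = ref, alt = alt,
    alt_count = pmax(1L, as.integer(round(vaf * depth))),
    depth = as.integer(depth),
    af_gnomad_exome = 0, af_gnomad_genome = 0, af_1000g = 0,
    gene = NA_character_, effect = NA_character_,
    sample_id = if (nrow(variants) > 0) variants$sample_id[1] else NA_character_,
    participant_id = if (nrow(variants) > 0) variants$participant_id[1]
                     else NA_character_,
    stringsAsFactors = FALSE
  )
  extra$vaf <- extra$alt_count / extra$depth
  out <- rbind(variants[names(extra)], extra)
  rownames(out) <- NULL
  out
}

#' Default cohort configuration
#'
#' Defaults reflect the study design the pipeline targets: 15 participants
#' with 2 serial ascites cfDNA samples each, per-sample tumour purity drawn
#' uniformly in 0.23-0.93, mean variant depth 900x, an hg19-autosome genome
#' with 100-kb bins and a 1.94-Mb callable footprint, 13 planted large-
#' segment (>10 Mb) copy-number boundaries, 30% of the genome in LOH tracts,
#' three clones carrying (4, 3, 2) somatic variants (TMB near 4.6/Mb), bin
#' log2 noise sd 0.1, beta-binomial overdispersion 0.01, and 15% of the
#' genome changing copy number between serial samples.
#'
#' @param nParticipants,samplesPerParticipant cohort layout.
#' @param purityRange range tumour purities are drawn from.
#' @param purities optional named list (participant id -> numeric vector of
#'   per-sample purities) overriding the draw.
#' @param genome a [GenomeModel-class].
#' @param meanDepth mean variant read depth.
#' @param depthSdLog lognormal sd of per-variant depth.
#' @param rho beta-binomial overdispersion of read counts.
#' @param nGermlineSnps heterozygous germline SNPs per participant.
#' @param snpsPerBin if set, SNPs are planted in clusters of exactly this
#'   many per occupied 100-kb bin (controls the LOH statistic's per-bin
#'   evidence); `NULL` places them uniformly.
#' @param rareGermlineFraction fraction of germline SNPs annotated with
#'   population AFs below the somatic-triage thresholds (the expected
#'   germline leak-through of the filter).
#' @param variantsPerClone somatic variants per clone; the first clone is
#'   truncal (CCF 1 in every sample).
#' @param cloneCcfs optional named list (participant id -> matrix clones x
#'   samples) of cancer cell fractions; drawn at random when `NULL`.
#' @param nLgaBoundaries planted qualifying (>10 Mb) copy-number boundaries,
#'   including the one flanking the TP53 deletion.
#' @param lohFraction target fraction of the genome inside LOH tracts.
#' @param altCnChoices copy numbers used for altered large segments.
#' @param tp53Deletion plant the 17p deletion carrying the truncal
#'   deleterious TP53 variant (the double-hit purity anchor).
#' @param focalAmp plant a focal (0.8 Mb) copy-number-29 amplification on
#'   chr8 (a MYC-like event).
#' @param log2NoiseSd Gaussian sd added to bin log2 values.
#' @param binDepth mean per-bin read depth of the copy-ratio profile.
#' @param binDepthSdLog lognormal sd of per-bin depth.
#' @param cnChangeFraction fraction of the genome whose copy number changes
#'   in each later serial sample (tumour evolution); 0 for technical
#'   replicates.
#' @param intervalDays days between serial samples in the manifest.
#' @param unreliableSegment if `TRUE`, one segment per sample gets 8x depth
#'   and corrupted log2 (exercises the modified-Z repair).
#' @param ffpeArtifacts list(`samples`, `nExtra`, `vafRange`): sample ids to
#'   contaminate with artefact variants.
#' @return a configuration list for [simulateCohort()].
#' @export
cohortConfig <- function(nParticipants = 15, samplesPerParticipant = 2,
                         purityRange = c(0.23, 0.93), purities = NULL,
                         genome = hg19Genome(), meanDepth = 900,
                         depthSdLog = 0.25, rho = 0.01,
                         nGermlineSnps = 1500, snpsPerBin = NULL,
                         rareGermlineFraction = 0.02,
                         variantsPerClone = c(4, 3, 2), cloneCcfs = NULL,
                         nLgaBoundaries = 13, lohFraction = 0.3,
                         altCnChoices = c(1, 3), tp53Deletion = TRUE,
                         focalAmp = TRUE, log2NoiseSd = 0.1, binDepth = 300,
                         binDepthSdLog = 0.25, cnChangeFraction = 0.15,
                         intervalDays = 132, unreliableSegment = FALSE,
                         ffpeArtifacts = list(samples = character(),
                                              nExtra = 200,
                                              vafRange = c(0.01, 0.10))) {
  as.list(environment())
}

## ---- internal planning helpers -------------------------------------------

## first covering truth-segment row index per position (1-based positions)
.segmentIndexAtPositions <- function(segments, chromosome, pos) {
  segGr <- segmentsToGRanges(segments)
  varGr <- positionsToGRanges(chromosome, pos)
  GenomicRanges::findOverlaps(varGr, segGr, select = "first")
}

## Plan one participant's allele-specific truth segments. Boundaries are
## snapped to the bin grid so the forward bin model is exactly piecewise.
.planSegments <- function(genome, nBoundaries, lohFraction, altCnChoices,
                          tp53Deletion, focalAmp) {
  bs <- binSize(genome)
  lens <- contigLengths(genome)
  segs <- list()
  remaining <- nBoundaries
  tp53Chrom <- NULL
  if (tp53Deletion) {
    tp53Chrom <- if ("chr17" %in% names(lens)) "chr17" else names(lens)[1]
    L <- lens[[tp53Chrom]]
    cut <- min(22e6, floor(L / 2 / bs) * bs)
    if (cut <= 1e7 || (L - cut) <= 1e7) {
      stop("infeasible config: contig too short to host the TP53 deletion")
    }
    segs[[tp53Chrom]] <- data.frame(
      chromosome = tp53Chrom, start = c(0, cut), end = c(cut, L),
      total_cn = c(1L, 2L), allele_a = c(1L, 1L), allele_b = c(0L, 1L),
      stringsAsFactors = FALSE
    )
    remaining <- remaining - 1L
    if (remaining < 0L) {
      stop("nLgaBoundaries must be >= 1 when tp53Deletion is TRUE")
    }
  }
  others <- setdiff(names(lens), tp53Chrom)
  cap <- pmax(floor(lens[others] / 1.01e7) - 1L, 0L)
  alloc <- stats::setNames(rep(0L, length(others)), others)
  while (remaining > 0L) {
    open <- others[alloc[others] < cap[others]]
    if (length(open) == 0L) {
      stop("infeasible config: too many LGA boundaries for this genome")
    }
    pick <- open[which.min(alloc[open])]
    alloc[pick] <- alloc[pick] + 1L
    remaining <- remaining - 1L
  }
  alleleFor <- function(cn) {
    a <- pmax(cn - 1L, ifelse(cn >= 2L, 1L, cn))
    cbind(a = a, b = cn - a)
  }
  for (chr in others) {
    b <- alloc[[chr]]
    L <- lens[[chr]]
    if (b == 0L) {
      segs[[chr]] <- data.frame(chromosome = chr, start = 0, end = L,
                                total_cn = 2L, allele_a = 1L, allele_b = 1L,
                                stringsAsFactors = FALSE)
      next
    }
    w <- floor(L / (b + 1) / bs) * bs
    starts <- (0:b) * w
    ends <- c(starts[-1], L)
    cns <- rep(2L, b + 1L)
    even <- seq(2L, b + 1L, by = 2L)
    cns[even] <- as.integer(sample(altCnChoices, length(even), replace = TRUE))
    al <- alleleFor(cns)
    segs[[chr]] <- data.frame(chromosome = chr, start = starts, end = ends,
                              total_cn = cns, allele_a = al[, "a"],
                              allele_b = al[, "b"], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs[names(lens)[names(lens) %in% names(segs)]])
  rownames(out) <- NULL

  ## top up LOH tracts with copy-neutral LOH (2,0) splits: same total copy
  ## number, so no new LGA boundary is created
  lohLen <- function(df) sum((df$end - df$start)[df$allele_b == 0 &
                                                   df$total_cn >= 1])
  target <- lohFraction * sum(lens)
  cand0 <- which(out$total_cn == 2L & out$allele_b == 1L)
  candidates <- cand0[sample.int(length(cand0))]
  for (i in candidates) {
    deficit <- target - lohLen(out)
    if (deficit <= 0) break
    segLen <- out$end[i] - out$start[i]
    piece <- min(segLen, max(bs, floor(deficit / bs) * bs))
    if (piece >= segLen) {
      out$allele_a[i] <- 2L
      out$allele_b[i] <- 0L
    } else {
      newRow <- out[i, , drop = FALSE]
      newRow$start <- out$start[i] + piece
      out$end[i] <- out$start[i] + piece
      out$allele_a[i] <- 2L
      out$allele_b[i] <- 0L
      out <- rbind(out, newRow)
    }
  }

  if (focalAmp) {
    host <- if ("chr8" %in% names(lens) && lens[["chr8"]] > 1.29e8) {
      list(chrom = "chr8", start = 1.28e8, end = 1.288e8)
    } else {
      lenv <- out$end - out$start
      j <- which.max(ifelse(out$total_cn == 2L, lenv, -1))
      mid <- floor((out$start[j] + out$end[j]) / 2 / bs) * bs
      list(chrom = out$chromosome[j], start = mid, end = mid + 8 * bs)
    }
    idx <- .segmentIndexAtPositions(
      transform(out, cn_int = total_cn), host$chrom, host$start + 1
    )
    hostRow <- out[idx, , drop = FALSE]
    pieces <- list()
    if (hostRow$start < host$start) {
      left <- hostRow
      left$end <- host$start
      pieces <- c(pieces, list(left))
    }
    amp <- hostRow
    amp$start <- host$start
    amp$end <- host$end
    amp$total_cn <- 29L
    amp$allele_a <- 28L
    amp$allele_b <- 1L
    pieces <- c(pieces, list(amp))
    if (hostRow$end > host$end) {
      right <- hostRow
      right$start <- host$end
      pieces <- c(pieces, list(right))
    }
    out <- rbind(out[-idx, , drop = FALSE], do.call(rbind, pieces))
    attr(out, "amp") <- data.frame(chromosome = host$chrom,
                                   start = host$start, end = host$end,
                                   total_cn = 29L)
  }
  bad <- out$allele_a + out$allele_b != out$total_cn
  if (any(bad)) stop("infeasible config: allele_cn inconsistent with total_cn")
  ampAttr <- attr(out, "amp")
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$loh <- out$allele_b == 0L & out$total_cn >= 1L
  attr(out, "amp") <- ampAttr
  out
}

## Evolve copy numbers for a later serial sample: shift total_cn by +/-1 on
## random segments until ~`fraction` of the genome is altered (floor 1 copy).
.evolveSegments <- function(segs, fraction, protect = integer()) {
  if (fraction <= 0) return(segs)
  target <- fraction * sum(segs$end - segs$start)
  changed <- 0
  for (i in sample(nrow(segs))) {
    if (changed >= target) break
    if (i %in% protect) next  # the purity-anchor segment keeps its double hit
    delta <- sample(c(-1L, 1L), 1)
    newCn <- segs$total_cn[i] + delta
    if (newCn < 1L) newCn <- segs$total_cn[i] + 1L
    segs$total_cn[i] <- newCn
    segs$allele_a[i] <- newCn - segs$allele_b[i]
    if (segs$allele_a[i] < 0L) {  # lost copies come off the major allele
      segs$allele_b[i] <- segs$allele_b[i] + segs$allele_a[i]
      segs$allele_a[i] <- 0L
    }
    segs$loh[i] <- min(segs$allele_a[i], segs$allele_b[i]) == 0L &
      segs$total_cn[i] >= 1L
    changed <- changed + (segs$end[i] - segs$start[i])
  }
  segs
}

#' Simulate a copy-ratio profile from truth segments
#'
#' Generates the chromosome-limited bin grid, assigns each bin its truth
#' copy number, and emits bin log2 values from the forward admixture model
#' `log2((t*CN + 2(1-t))/2)` plus Gaussian noise, with lognormal per-bin
#' depth. The emitted segment table carries the mean log2/depth of its
#' member bins (what a segmentation of these bins would report).
#'
#' @param truthSegments truth segment table (`chromosome`, `start`, `end`,
#'   `total_cn`), tiling the genome on the bin grid.
#' @param genome a [GenomeModel-class].
#' @param purity tumour fraction in `[0, 1]`.
#' @param noiseSd Gaussian sd of bin log2 noise (default 0.1).
#' @param binDepth mean per-bin depth (default 300).
#' @param binDepthSdLog lognormal sd of per-bin depth (default 0.25).
#' @param unreliableSegment if `TRUE`, one segment is corrupted with 8x depth
#'   and +1.5 log2 (a collapsed-repeat-like artefact for the modified-Z
#'   repair); its index is attached as attribute `unreliable_segment`.
#' @return list with `bins` (.cnr dialect: `chromosome, start, end, log2,
#'   depth`) and `segments` (.cns dialect plus `n_bins`, `mean_depth`).
#' @export
simulateBinProfile <- function(truthSegments, genome, purity, noiseSd = 0.1,
                               binDepth = 300, binDepthSdLog = 0.25,
                               unreliableSegment = FALSE) {
  bins <- genomeBins(genome)
  mid <- floor((bins$start + bins$end) / 2) + 1
  segIdx <- .segmentIndexAtPositions(
    transform(truthSegments, cn_int = total_cn), bins$chromosome, mid
  )
  if (anyNA(segIdx)) {
    stop("infeasible config: truth segments do not tile the genome")
  }
  cn <- truthSegments$total_cn[segIdx]
  mixture <- pmax((purity * cn + 2 * (1 - purity)) / 2, 2^-10)
  bins$log2 <- log2(mixture) + stats::rnorm(nrow(bins), 0, noiseSd)
  bins$depth <- binDepth * stats::rlnorm(nrow(bins),
                                         -binDepthSdLog^2 / 2, binDepthSdLog)
  unrelIdx <- NA_integer_
  if (unreliableSegment) {
    lenv <- truthSegments$end - truthSegments$start
    unrelIdx <- order(lenv)[ceiling(nrow(truthSegments) / 2)]
    hit <- segIdx == unrelIdx
    bins$depth[hit] <- bins$depth[hit] * 8
    bins$log2[hit] <- bins$log2[hit] + 1.5
  }
  segs <- data.frame(
    chromosome = truthSegments$chromosome,
    start = truthSegments$start,
    end = truthSegments$end,
    log2 = as.numeric(tapply(bins$log2, segIdx, mean)[as.character(
      seq_len(nrow(truthSegments)))]),
    n_bins = as.integer(table(factor(segIdx,
                                     levels = seq_len(nrow(truthSegments))))),
    mean_depth = as.numeric(tapply(bins$depth, segIdx, mean)[as.character(
      seq_len(nrow(truthSegments)))]),
    stringsAsFactors = FALSE
  )
  attr(segs, "unreliable_segment") <- unrelIdx
  list(bins = bins, segments = segs)
}

## ---- cohort assembly ------------------------------------------------------

.BASES <- c("A", "C", "G", "T")

.randomAlleles <- function(n) {
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1), character(1))
  list(ref = ref, alt = alt)
}

.drawDepth <- function(n, meanDepth, sdlog) {
  pmax(30L, as.integer(round(meanDepth *
                               stats::rlnorm(n, -sdlog^2 / 2, sdlog))))
}

#' Simulate a full cohort with ground truth
#'
#' Deterministic given `seed`. See [cohortConfig()] for the generative
#' parameters; the returned [SyntheticCohort-class] carries per-sample
#' variant/bin/segment tables in the package's table dialects, the manifest,
#' and a `truth` list with per-sample purity, per-sample truth segments,
#' clone CCF matrices, variant provenance (germline / somatic / artifact,
#' clone, expected VAF, multiplicity, locus copy number), the realized
#' fraction of occupied bins inside LOH tracts, true LGA counts, and the
#' config echo.
#'
#' @param config a [cohortConfig()] list.
#' @param seed integer RNG seed.
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1) {
  set.seed(seed)
  cfg <- config
  genome <- cfg$genome
  lens <- contigLengths(genome)
  bs <- binSize(genome)
  nP <- cfg$nParticipants
  nS <- cfg$samplesPerParticipant
  pids <- sprintf("ASC%02d", seq_len(nP))

  manifest <- list()
  variants <- list()
  binsL <- list()
  segsL <- list()
  truthPurity <- list()
  truthSegs <- list()
  truthVars <- list()
  truthClones <- list()
  truthLga <- list()
  truthLohFrac <- list()
  truthUnrel <- list()

  for (p in seq_len(nP)) {
    pid <- pids[p]
    sids <- sprintf("%s_cf%d", pid, seq_len(nS))
    tvec <- if (!is.null(cfg$purities) && !is.null(cfg$purities[[pid]])) {
      rep_len(cfg$purities[[pid]], nS)
    } else {
      stats::runif(nS, cfg$purityRange[1], cfg$purityRange[2])
    }

    baseSegs <- .planSegments(genome, cfg$nLgaBoundaries, cfg$lohFraction,
                              cfg$altCnChoices, cfg$tp53Deletion,
                              cfg$focalAmp)
    tpChrom <- tpPos <- NULL
    protect <- integer()
    if (cfg$tp53Deletion) {
      tpChrom <- if ("chr17" %in% names(lens)) "chr17" else names(lens)[1]
      tpPos <- min(7577539,
                   floor(min(baseSegs$end[baseSegs$chromosome == tpChrom]) / 2))
      protect <- .segmentIndexAtPositions(baseSegs, tpChrom, tpPos)
    }
    segsBySample <- list(baseSegs)
    if (nS > 1) {
      for (s in 2:nS) {
        segsBySample[[s]] <- .evolveSegments(baseSegs, cfg$cnChangeFraction,
                                             protect)
      }
    }
    names(segsBySample) <- sids

    ## --- germline het SNPs (positions and per-bin haplotype phase are
    ## participant-level; within one 100-kb bin SNPs are treated as a single
    ## haplotype block in perfect LD, so their alt alleles co-segregate)
    nG <- cfg$nGermlineSnps
    if (!is.null(cfg$snpsPerBin)) {
      allBins <- genomeBins(genome)
      nBins <- ceiling(nG / cfg$snpsPerBin)
      pick <- allBins[sample(nrow(allBins), min(nBins, nrow(allBins))), ,
                      drop = FALSE]
      gChrom <- rep(pick$chromosome, each = cfg$snpsPerBin)[seq_len(nG)]
      gPos <- floor(rep(pick$start, each = cfg$snpsPerBin)[seq_len(nG)] +
                      stats::runif(nG, 1, bs))
      gPos <- pmin(gPos, rep(pick$end, each = cfg$snpsPerBin)[seq_len(nG)])
    } else {
      gChrom <- sample(names(lens), nG, replace = TRUE,
                       prob = lens / sum(lens))
      gPos <- floor(stats::runif(nG, 1, lens[gChrom]))
    }
    gAll <- .randomAlleles(nG)
    binKey <- paste(gChrom, .binStart(gPos, bs))
    blockHapByBin <- stats::setNames(
      sample(1:2, length(unique(binKey)), replace = TRUE), unique(binKey))
    gHap <- blockHapByBin[binKey]
    nRare <- round(cfg$rareGermlineFraction * nG)
    isRare <- seq_len(nG) %in% sample(nG, nRare)
    afG <- data.frame(
      af_1000g = ifelse(isRare, stats::runif(nG, 0, 0.019),
                        stats::runif(nG, 0.05, 0.5)),
      af_gnomad_genome = NA_real_, af_gnomad_exome = NA_real_
    )
    afG$af_gnomad_genome <- ifelse(isRare, stats::runif(nG, 0, 0.004),
                                   pmin(afG$af_1000g *
                                          stats::runif(nG, 0.8, 1.2), 0.5))
    afG$af_gnomad_exome <- ifelse(isRare, stats::runif(nG, 0, 0.0004),
                                  pmin(afG$af_1000g *
                                         stats::runif(nG, 0.8, 1.2), 0.5))

    ## --- somatic variants and clone CCFs
    K <- length(cfg$variantsPerClone)
    ccf <- matrix(1, K, nS)
    if (K > 1) {
      if (!is.null(cfg$cloneCcfs) && !is.null(cfg$cloneCcfs[[pid]])) {
        ccf <- cfg$cloneCcfs[[pid]]
        if (!all(dim(ccf) == c(K, nS)) || any(ccf < 0) || any(ccf > 1) ||
            any(ccf[1, ] != 1)) {
          stop("infeasible config: cloneCcfs must be K x nSamples in [0,1] ",
               "with a truncal first row of 1s")
        }
      } else {
        for (k in 2:K) {
          ccf[k, 1] <- stats::runif(1, 0.15, 0.85)
          for (s in seq_len(nS)[-1]) {
            ccf[k, s] <- min(max(ccf[k, s - 1] +
                                   stats::runif(1, -0.35, 0.35), 0.02), 1)
          }
        }
      }
    }
    nSom <- sum(cfg$variantsPerClone)
    cloneOf <- rep(seq_len(K), cfg$variantsPerClone)
    ## placement: segments with copy number >= 1 in every sample, weighted
    ## by length
    minCn <- Reduce(pmin, lapply(segsBySample, function(s) s$total_cn))
    elig <- which(minCn >= 1L)
    segPick <- elig[sample.int(length(elig), nSom, replace = TRUE,
                               prob = (baseSegs$end - baseSegs$start)[elig])]
    sChrom <- baseSegs$chromosome[segPick]
    sPos <- floor(stats::runif(nSom, baseSegs$start[segPick] + 1,
                               baseSegs$end[segPick]))
    sAll <- .randomAlleles(nSom)
    sGene <- sprintf("G%03d", seq_len(nSom))
    sEffect <- rep("VUS", nSom)
    ## truncal deleterious TP53 anchor inside the 17p deletion
    if (cfg$tp53Deletion) {
      sChrom <- c(tpChrom, sChrom)
      sPos <- c(tpPos, sPos)
      sAll$ref <- c("G", sAll$ref)
      sAll$alt <- c("A", sAll$alt)
      sGene <- c("TP53", sGene)
      sEffect <- c("deleterious", sEffect)
      cloneOf <- c(1L, cloneOf)
      nSom <- nSom + 1L
    }

    truthClones[[pid]] <- list(ccf = ccf,
                               variants = data.frame(
                                 key = .variantKey(sChrom, sPos, sAll$ref,
                                                   sAll$alt),
                                 clone = cloneOf, stringsAsFactors = FALSE))

    ## --- emit per-sample tables
    for (s in seq_len(nS)) {
      sid <- sids[s]
      t <- tvec[s]
      segsS <- segsBySample[[s]]
      lookup <- transform(segsS, cn_int = total_cn)

      gIdx <- .segmentIndexAtPositions(lookup, gChrom, gPos)
      gCn <- segsS$total_cn[gIdx]
      gM <- ifelse(gHap == 1L, segsS$allele_a[gIdx], segsS$allele_b[gIdx])
      gVaf <- expectedVaf(t, 1, gM, gCn, germlineCopies = 1)

      sIdx <- .segmentIndexAtPositions(lookup, sChrom, sPos)
      sCn <- segsS$total_cn[sIdx]
      sM <- pmin(1L, sCn)
      sVaf <- expectedVaf(t, ccf[cloneOf, s], sM, sCn, germlineCopies = 0)

      n <- nG + nSom
      depth <- .drawDepth(n, cfg$meanDepth, cfg$depthSdLog)
      ev <- c(gVaf, sVaf)
      alt <- sampleReadCounts(ev, depth, cfg$rho)
      tab <- data.frame(
        chrom = c(gChrom, sChrom), pos = as.numeric(c(gPos, sPos)),
        ref = c(gAll$ref, sAll$ref), alt = c(gAll$alt, sAll$alt),
        alt_count = alt, depth = depth,
        af_gnomad_exome = c(afG$af_gnomad_exome, rep(NA_real_, nSom)),
        af_gnomad_genome = c(afG$af_gnomad_genome, rep(NA_real_, nSom)),
        af_1000g = c(afG$af_1000g, rep(NA_real_, nSom)),
        gene = c(rep(NA_character_, nG), sGene),
        effect = c(rep(NA_character_, nG), sEffect),
        sample_id = sid, participant_id = pid,
        stringsAsFactors = FALSE
      )
      tab$vaf <- tab$alt_count / tab$depth
      truthTab <- data.frame(
        key = .variantKey(tab$chrom, tab$pos, tab$ref, tab$alt),
        class = c(rep("germline", nG), rep("somatic", nSom)),
        rare_germline = c(isRare, rep(NA, nSom)),
        clone = c(rep(NA_integer_, nG), cloneOf),
        expected_vaf = ev, multiplicity = c(gM, sM), cn = c(gCn, sCn),
        stringsAsFactors = FALSE
      )
      if (sid %in% cfg$ffpeArtifacts$samples) {
        before <- nrow(tab)
        tab <- injectFfpeArtifacts(tab, cfg$ffpeArtifacts$nExtra,
                                   cfg$ffpeArtifacts$vafRange, genome)
        added <- tab[seq(before + 1, nrow(tab)), , drop = FALSE]
        truthTab <- rbind(truthTab, data.frame(
          key = .variantKey(added$chrom, added$pos, added$ref, added$alt),
          class = "artifact", rare_germline = NA, clone = NA_integer_,
          expected_vaf = added$vaf, multiplicity = NA_integer_,
          cn = NA_integer_, stringsAsFactors = FALSE))
      }
      variants[[sid]] <- tab
      truthVars[[sid]] <- truthTab

      prof <- simulateBinProfile(segsS, genome, t, cfg$log2NoiseSd,
                                 cfg$binDepth, cfg$binDepthSdLog,
                                 cfg$unreliableSegment)
      binsL[[sid]] <- prof$bins
      segsL[[sid]] <- prof$segments
      truthUnrel[[sid]] <- attr(prof$segments, "unreliable_segment")
      truthSegs[[sid]] <- segsS
      truthPurity[[sid]] <- data.frame(sample_id = sid, participant_id = pid,
                                       t = t, stringsAsFactors = FALSE)
      truthLga[[sid]] <- countLga(lookup)$lga_count

      occBin <- unique(paste(gChrom, .binStart(gPos, bs)))
      occChrom <- sub(" .*", "", occBin)
      occMid <- as.numeric(sub(".* ", "", occBin)) + bs / 2
      occIdx <- .segmentIndexAtPositions(lookup, occChrom, pmin(
        floor(occMid), lens[occChrom] - 1) + 1)
      truthLohFrac[[sid]] <- mean(segsS$loh[occIdx], na.rm = TRUE)

      manifest[[sid]] <- data.frame(
        participant_id = pid, sample_id = sid, specimen = "cfDNA",
        timepoint_days = (s - 1) * cfg$intervalDays,
        purity_hint = NA_real_, stringsAsFactors = FALSE
      )
    }
  }

  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  truth <- list(
    seed = seed,
    purity = do.call(rbind, truthPurity),
    segments = truthSegs,
    variants = truthVars,
    clones = truthClones,
    lga = truthLga,
    loh_occupied_fraction = truthLohFrac,
    unreliable_segment = truthUnrel,
    config = cfg[setdiff(names(cfg), "genome")]
  )
  rownames(truth$purity) <- NULL
  methods::new("SyntheticCohort", genome = genome, manifest = man,
               variants = variants, bins = binsL, segments = segsL,
               truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits `manifest.tsv`, per-sample `<sample>.variants.tsv`, `<sample>.cnr`
#' and `<sample>.cns` in the package's table dialects, plus `truth.json`.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeManifest(manifest(cohort), file.path(dir, "manifest.tsv"))
  for (sid in manifest(cohort)$sample_id) {
    writeVariants(variantTables(cohort)[[sid]],
                  file.path(dir, paste0(sid, ".variants.tsv")))
    writeBins(binTables(cohort)[[sid]], file.path(dir, paste0(sid, ".cnr")))
    writeSegments(segmentTables(cohort)[[sid]],
                  file.path(dir, paste0(sid, ".cns")))
  }
  jsonlite::write_json(cohortTruth(cohort), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
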