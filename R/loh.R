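## Binned loss-of-heterozygosity percentage.
##
## Heterozygous sites sit at VAF 0.5 in diploid balanced regions; allelic
## imbalance (LOH, with or without copy loss) pushes them away from 0.5 in
## proportion to tumour purity. The statistic: tile each chromosome with
## 100-kb bins (chromosome-limited); a bin is "occupied" when it holds at
## least one non-homozygous variant (VAF within a window, default
## [0.05, 0.95]); a bin shows LOH when the mean VAF of its eligible variants
## falls strictly outside [0.4, 0.6]. LOH% is the percentage of occupied bins
## showing LOH. All detected variants (germline and somatic) feed the
## statistic - panel germline SNPs are the signal carriers - so the somatic
## triage is NOT applied first.

#' LOH reliability guards
#'
#' The binned statistic is meaningless at low coverage or when the VAF
#' distribution collapses: a sample is reliable only when the mean read depth
#' over its eligible variants is at least 150x and their median VAF is at
#' least 0.1.
#'
#' @param meanDepth mean read depth over the sample's eligible variants.
#' @param medianVaf median VAF of the same set.
#' @param minDepth,minMedianVaf guard values (defaults 150, 0.1).
#' @return list with logical `reliable` and `reason` (`NA` when reliable,
#'   otherwise the failing guard(s)).
#' @export
lohReliability <- function(meanDepth, medianVaf, minDepth = 150,
                           minMedianVaf = 0.1) {
  reasons <- character()
  if (is.na(meanDepth) || meanDepth < minDepth) reasons <- c(reasons, "low depth")
  if (is.na(medianVaf) || medianVaf < minMedianVaf)
    reasons <- c(reasons, "low median VAF")
  list(reliable = length(reasons) == 0L,
       reason = if (length(reasons)) paste(reasons, collapse = "; ")
                else NA_character_)
}

#' Binned LOH percentage of one sample
#'
#' @param variants one sample's variant table (all detected variants, not
#'   just somatic) with `chrom`, `pos`, `vaf`, `depth`.
#' @param genome a [GenomeModel-class] supplying the chromosome-limited bin
#'   grid.
#' @param band closed VAF band whose strict exterior defines LOH
#'   (default `c(0.4, 0.6)`).
#' @param vafWindow eligibility window for "non-homozygous" variants
#'   (default `c(0.05, 0.95)`, inclusive), keeping allele-imbalanced LOH
#'   heterozygotes while excluding fixed homozygotes.
#' @param minVariantsPerBin minimum eligible variants for a bin to count as
#'   occupied (default 1).
#' @param colemanCutoff LOH percentage above which (strictly) the
#'   `exceeds_coleman_cutoff` HRD flag is set (default 16).
#' @return list with `loh_percent`, `occupied_bins`, `loh_bins`, `reliable`,
#'   `reason`, `exceeds_coleman_cutoff`, `mean_depth`, `median_vaf`. With no
#'   occupied bin, `loh_percent` is `NA` and the result is unreliable.
#' @export
#' @examples
#' g <- GenomeModel(c(chr1 = 3e5))
#' v <- data.frame(chrom = "chr1", pos = c(5e4, 15e4, 25e4),
#'                 vaf = c(0.50, 0.35, 0.62), depth = 500)
#' lohPercent(v, g)$loh_percent  # 2 of 3 occupied bins deviate -> 66.7
lohPercent <- function(variants, genome, band = c(0.4, 0.6),
                       vafWindow = c(0.05, 0.95), minVariantsPerBin = 1L,
                       colemanCutoff = 16) {
  .assertColumns(variants, c("chrom", "pos", "vaf", "depth"), "variant table")
  stopifnot(methods::is(genome, "GenomeModel"))
  known <- variants$chrom %in% names(contigLengths(genome))
  v <- variants[known, , drop = FALSE]
  eligible <- v[v$vaf >= vafWindow[1] & v$vaf <= vafWindow[2], , drop = FALSE]
  empty <- list(loh_percent = NA_real_, occupied_bins = 0L, loh_bins = 0L,
                reliable = FALSE, reason = "no occupied bins",
                exceeds_coleman_cutoff = FALSE,
                mean_depth = NA_real_, median_vaf = NA_real_)
  if (nrow(eligible) == 0L) return(empty)
  bin <- paste(eligible$chrom, .binStart(eligible$pos, binSize(genome)))
  nPer <- tapply(eligible$vaf, bin, length)
  meanVaf <- tapply(eligible$vaf, bin, mean)
  occupied <- nPer >= minVariantsPerBin
  nOcc <- sum(occupied)
  if (nOcc == 0L) return(empty)
  isLoh <- occupied & (meanVaf < band[1] | meanVaf > band[2])
  pct <- 100 * sum(isLoh) / nOcc
  guard <- lohReliability(mean(eligible$depth), stats::median(eligible$vaf))
  list(loh_percent = pct,
       occupied_bins = as.integer(nOcc),
       loh_bins = as.integer(sum(isLoh)),
       reliable = guard$reliable,
       reason = guard$reason,
       exceeds_coleman_cutoff = pct > colemanCutoff,
       mean_depth = mean(eligible$depth),
       median_vaf = stats::median(eligible$vaf))
}
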