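## Somatic triage for panels without a matched germline sample.
##
## With no germline reference, a variant is treated as likely somatic when it
## is rare in every population database with an annotation (strictly below
## 0.05% gnomAD exomes, 0.5% gnomAD genomes and 2% 1000 Genomes). Unique
## variants are additionally "verifiable" only with VAF > 0.05 and depth >
## 150x (or observation in more than one sample of the participant), and
## samples whose total variant count is a cohort outlier (|Z| > 3 against a
## mean computed after excluding the single most extreme sample) are flagged
## as likely artefact-laden (the FFPE failure mode).

#' Somatic-triage thresholds
#'
#' @param max_af_exome,max_af_genome,max_af_1000g strict upper bounds on the
#'   population allele frequency in gnomAD exomes, gnomAD genomes and
#'   1000 Genomes (defaults 0.0005, 0.005, 0.02).
#' @param max_allele_count strict upper bound on the population minor allele
#'   count, applied only when count annotations are supplied (default 100).
#' @param verify_min_vaf,verify_min_depth strict lower bounds for verifying a
#'   variant seen in only one sample of a participant (defaults 0.05, 150).
#' @param outlier_z |Z| bound for the total-variant-count outlier flag
#'   (default 3).
#' @return a named list of class `FilterThresholds`.
#' @export
filterThresholds <- function(max_af_exome = 0.0005, max_af_genome = 0.005,
                             max_af_1000g = 0.02, max_allele_count = 100,
                             verify_min_vaf = 0.05, verify_min_depth = 150,
                             outlier_z = 3) {
  th <- list(max_af_exome = max_af_exome, max_af_genome = max_af_genome,
             max_af_1000g = max_af_1000g, max_allele_count = max_allele_count,
             verify_min_vaf = verify_min_vaf,
             verify_min_depth = verify_min_depth, outlier_z = outlier_z)
  if (any(unlist(th) <= 0)) stop("all thresholds must be > 0")
  class(th) <- "FilterThresholds"
  th
}

#' Likely-somatic call against population allele frequencies
#'
#' A record is likely somatic iff its allele frequency is strictly below the
#' threshold in every database for which an annotation is present. A variant
#' absent from all three databases passes (absence from population databases
#' is itself somatic evidence) with reason `"no population evidence"` for
#' auditability. Population allele *counts*, when supplied as columns
#' `ac_gnomad_exome` / `ac_gnomad_genome` / `ac_1000g`, are checked against
#' `max_allele_count` the same way.
#'
#' @param variants variant table; population AF columns (`af_gnomad_exome`,
#'   `af_gnomad_genome`, `af_1000g`) are optional and may contain `NA`.
#' @param thresholds a [filterThresholds()] object.
#' @return data.frame with logical `somatic` and character `reason` (failing
#'   database names, or `"no population evidence"`), one row per input row.
#' @export
isLikelySomatic <- function(variants, thresholds = filterThresholds()) {
  n <- nrow(variants)
  checks <- list(
    gnomad_exome = c("af_gnomad_exome", "max_af_exome"),
    gnomad_genome = c("af_gnomad_genome", "max_af_genome"),
    `1000g` = c("af_1000g", "max_af_1000g"),
    ac_gnomad_exome = c("ac_gnomad_exome", "max_allele_count"),
    ac_gnomad_genome = c("ac_gnomad_genome", "max_allele_count"),
    ac_1000g = c("ac_1000g", "max_allele_count")
  )
  fail <- matrix(FALSE, n, length(checks),
                 dimnames = list(NULL, names(checks)))
  seen <- rep(FALSE, n)
  for (db in names(checks)) {
    col <- checks[[db]][1]
    if (!col %in% names(variants)) next
    x <- variants[[col]]
    present <- !is.na(x)
    seen <- seen | present
    fail[present, db] <- x[present] >= thresholds[[checks[[db]][2]]]
  }
  somatic <- rowSums(fail) == 0L
  reason <- apply(fail, 1L, function(f)
    paste(colnames(fail)[f], collapse = ","))
  reason[somatic & !seen] <- "no population evidence"
  reason[somatic & seen] <- ""
  data.frame(somatic = somatic, reason = reason, stringsAsFactors = FALSE)
}

#' Verification rule for triaged variants
#'
#' A variant is verifiable when reported (detected, VAF > 0) in more than one
#' sample of its participant, or — when unique to one sample — when its VAF
#' exceeds 0.05 and its read depth exceeds 150x (both strict). Rows with zero
#' alt reads (placeholders of a shared variant universe) are observations of
#' absence: they are never verifiable themselves and do not count towards
#' recurrence.
#'
#' @param variants variant table with `chrom, pos, ref, alt, vaf, depth,
#'   sample_id, participant_id`.
#' @param thresholds a [filterThresholds()] object.
#' @return logical vector, one entry per row.
#' @export
isVerifiable <- function(variants, thresholds = filterThresholds()) {
  .assertColumns(variants, c("chrom", "pos", "ref", "alt", "vaf", "depth",
                             "sample_id", "participant_id"), "variant table")
  key <- paste(variants$participant_id,
               .variantKey(variants$chrom, variants$pos, variants$ref,
                           variants$alt))
  sampleIfDetected <- ifelse(variants$vaf > 0,
                             as.integer(factor(variants$sample_id)),
                             NA_integer_)
  nSamples <- stats::ave(sampleIfDetected, key,
                         FUN = function(s) length(unique(s[!is.na(s)])))
  variants$vaf > 0 &
    (nSamples > 1L |
       (variants$vaf > thresholds$verify_min_vaf &
          variants$depth > thresholds$verify_min_depth))
}

#' Flag samples with outlying total variant counts
#'
#' Excludes the single sample deviating most from the cohort median (ties
#' broken towards the larger count), computes mean and SD of the remainder,
#' and flags every sample — including the excluded one — with
#' `|count - mean| / sd` above `outlier_z`. When the remainder has zero SD,
#' only samples differing from that mean are flagged. Inflated totals are the
#' signature of artefact-laden (e.g. FFPE) libraries.
#'
#' @param counts named numeric vector of per-sample total variant counts
#'   (names are sample ids), length >= 3.
#' @param outlier_z |Z| bound (default 3).
#' @return character vector of flagged sample ids.
#' @export
#' @examples
#' flagVariantCountOutliers(c(a = 50, b = 52, c = 48, d = 51, e = 400))
flagVariantCountOutliers <- function(counts, outlier_z = 3) {
  if (length(counts) < 3L) stop("need at least 3 samples")
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  dev <- abs(counts - stats::median(counts))
  drop <- order(-dev, -counts)[1]
  rest <- counts[-drop]
  mu <- mean(rest)
  sdv <- stats::sd(rest)
  if (sdv == 0) {
    return(names(counts)[counts != mu])
  }
  z <- (counts - mu) / sdv
  names(counts)[abs(z) > outlier_z]
}

#' Tumour mutation burden
#'
#' Verified somatic variants per callable megabase, reported to one decimal.
#'
#' @param nSomaticVerified number of verified, likely-somatic variants.
#' @param callableMb callable panel footprint in Mb (default 1.94).
#' @return TMB in variants/Mb, rounded to 1 decimal.
#' @export
calcTmb <- function(nSomaticVerified, callableMb = 1.94) {
  if (any(callableMb <= 0)) stop("callableMb must be > 0")
  round(nSomaticVerified / callableMb, 1)
}

#' Full somatic triage of a cohort variant table
#'
#' Applies [isLikelySomatic()] and [isVerifiable()] and summarises per-sample
#' totals plus the count-outlier flags.
#'
#' @param variants cohort variant table (all samples).
#' @param thresholds a [filterThresholds()] object.
#' @param callableMb callable panel footprint in Mb for the per-sample TMB.
#' @return list with `variants` (input plus `somatic`, `reason`,
#'   `verifiable` columns), `somatic` (the rows passing both rules), and
#'   `report` (per-sample totals, somatic counts, TMB, outlier flag).
#' @export
filterSomaticVariants <- function(variants, thresholds = filterThresholds(),
                                  callableMb = 1.94) {
  call <- isLikelySomatic(variants, thresholds)
  variants$somatic <- call$somatic
  variants$reason <- call$reason
  variants$verifiable <- isVerifiable(variants, thresholds)
  keep <- variants$somatic & variants$verifiable
  # totals count detected variants; zero-VAF placeholder rows are absences
  counts <- tapply(variants$vaf > 0, variants$sample_id, sum)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  flagged <- if (length(counts) >= 3L) {
    flagVariantCountOutliers(counts, thresholds$outlier_z)
  } else character()
  nSom <- tapply(keep, variants$sample_id, sum)
  report <- data.frame(
    sample_id = names(counts),
    total_variants = as.numeric(counts),
    somatic_verified = as.numeric(nSom[names(counts)]),
    tmb = calcTmb(as.numeric(nSom[names(counts)]), callableMb),
    count_outlier = names(counts) %in% flagged,
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(variants = variants,
       somatic = variants[keep, , drop = FALSE],
       report = report)
}
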