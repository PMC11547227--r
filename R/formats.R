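## Readers and writers for the flat table formats the pipeline exchanges:
## variant tables (TSV dialect or VCF 4.x), CNVkit-style .cnr/.cns copy-ratio
## tables, BED gene intervals, the cohort manifest, and the clonal-inference
## (PyClone-VI dialect) export.
##
## Conventions: variants are 1-based inclusive; bins and segments are 0-based
## half-open. Conversion between the two is centralized in utils.R.

.VARIANT_REQUIRED <- c("chrom", "pos", "ref", "alt", "alt_count", "depth")
.VARIANT_OPTIONAL <- c("af_gnomad_exome", "af_gnomad_genome", "af_1000g",
                       "gene", "effect", "sample_id", "participant_id")

#' Read a per-sample variant table (TSV dialect or VCF)
#'
#' The TSV dialect carries one row per (variant, sample) with columns
#' `chrom, pos, ref, alt, alt_count, depth` and optionally population
#' allele-frequency annotations (`af_gnomad_exome`, `af_gnomad_genome`,
#' `af_1000g`), `gene`, `effect`, `sample_id` and `participant_id`. VCF input
#' is parsed with \pkg{VariantAnnotation}; per-sample alt/total read counts
#' are taken from `AD`/`DP` (or `AF` + `DP` when `AD` is absent) and
#' population AFs from the INFO fields `AF_GNOMAD_EXOME`, `AF_GNOMAD_GENOME`
#' and `AF_1000G` when present. Multi-allelic VCF records contribute their
#' first ALT allele.
#'
#' VAF is computed as `alt_count / depth`. Records with zero depth are
#' dropped; the number dropped is reported via a message and attached as
#' attribute `n_dropped`.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @param sampleId,participantId identifiers to attach when the file itself
#'   does not carry them.
#' @param stripChr if `TRUE`, a leading `"chr"` is removed from contig names
#'   (harmonization flag; by default contig names are kept verbatim).
#' @return data.frame of variant records, one row per (variant, sample), with
#'   a computed `vaf` column. Positions are 1-based inclusive.
#' @export
readVariants <- function(path, dialect = c("auto", "tsv", "vcf"),
                         sampleId = NULL, participantId = NULL,
                         stripChr = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (dialect == "vcf") .readVariantsVcf(path) else .readVariantsTsv(path)
  if (!is.null(sampleId)) df$sample_id <- sampleId
  if (!is.null(participantId)) df$participant_id <- participantId
  if (stripChr) df$chrom <- sub("^chr", "", df$chrom)
  n0 <- sum(df$depth == 0)
  if (n0 > 0) {
    message(sprintf("dropping %d record(s) with zero depth", n0))
    df <- df[df$depth > 0, , drop = FALSE]
    rownames(df) <- NULL
  }
  df$vaf <- df$alt_count / df$depth
  attr(df, "n_dropped") <- n0
  df
}

.readVariantsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  .assertColumns(df, .VARIANT_REQUIRED, sprintf("variant table '%s'", path))
  bad <- which(is.na(df$chrom) | is.na(df$pos) | is.na(df$ref) |
                 is.na(df$alt) | is.na(df$alt_count) | is.na(df$depth) |
                 df$pos < 1 | df$alt_count < 0 | df$depth < 0 |
                 (df$depth > 0 & df$alt_count > df$depth))
  if (length(bad) > 0L) {
    stop(sprintf("malformed variant row at line %d of %s",
                 bad[1] + 1L, path))  # +1 for the header line
  }
  df
}

.readVariantsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  nVar <- length(rr)
  samples <- colnames(vcf)
  if (length(samples) == 0L) stop("VCF has no sample columns: ", path)
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) as.character(a)[1], character(1))
  base <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = alt,
    stringsAsFactors = FALSE
  )
  info <- VariantAnnotation::info(vcf)
  infoMap <- c(af_gnomad_exome = "AF_GNOMAD_EXOME",
               af_gnomad_genome = "AF_GNOMAD_GENOME",
               af_1000g = "AF_1000G",
               gene = "GENE", effect = "EFFECT")
  for (k in names(infoMap)) {
    if (infoMap[[k]] %in% names(info)) {
      v <- info[[infoMap[[k]]]]
      base[[k]] <- if (k %in% c("gene", "effect")) as.character(v)
                   else as.numeric(v)
    }
  }
  g <- VariantAnnotation::geno(vcf)
  out <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    rows <- base
    if ("AD" %in% names(g)) {
      ad <- g$AD[, j]
      rows$alt_count <- vapply(ad, function(a)
        if (length(a) >= 2) as.integer(a[2]) else NA_integer_, integer(1))
      dp <- if ("DP" %in% names(g)) as.integer(g$DP[, j]) else
        vapply(ad, function(a) as.integer(sum(a)), integer(1))
      rows$depth <- ifelse(is.na(dp),
                           vapply(ad, function(a) as.integer(sum(a)),
                                  integer(1)),
                           dp)
    } else if (all(c("AF", "DP") %in% names(g))) {
      dp <- as.integer(g$DP[, j])
      af <- as.numeric(g$AF[, j])
      rows$alt_count <- as.integer(round(af * dp))
      rows$depth <- dp
    } else {
      stop("VCF must carry per-sample AD/DP (or AF and DP): ", path)
    }
    rows$sample_id <- samples[j]
    out[[j]] <- rows
  }
  res <- do.call(rbind, out)
  res$depth[is.na(res$depth)] <- 0L
  res$alt_count[is.na(res$alt_count)] <- 0L
  rownames(res) <- NULL
  res
}

#' Write a variant table in the TSV dialect
#'
#' @param variants variant table as returned by [readVariants()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(variants, path) {
  .assertColumns(variants, .VARIANT_REQUIRED, "variant table")
  keep <- intersect(c(.VARIANT_REQUIRED, "vaf", .VARIANT_OPTIONAL),
                    names(variants))
  utils::write.table(variants[keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## shared reader for the CNVkit-style .cnr/.cns dialect:
## chromosome, start, end, log2 [, depth, weight, cn, ...]
.readCnTable <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .assertColumns(df, c("chromosome", "start", "end", "log2"),
                 sprintf("%s table '%s'", what, path))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start >= df$end)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s row at line %d of %s (need start < end)",
                 what, bad[1] + 1L, path))
  }
  ord <- order(df$chromosome, df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning(sprintf("%s table '%s' was not sorted; sorting by (chromosome, start)",
                    what, path))
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  for (chr in unique(df$chromosome)) {
    sub <- df[df$chromosome == chr, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop(sprintf("%s table '%s': intervals overlap on %s", what, path, chr))
    }
  }
  df
}

#' Read bin-level log2 copy ratios (.cnr dialect)
#'
#' CNVkit-style tab-separated table with columns
#' `chromosome, start, end, log2` and optionally `depth`, `weight`.
#' Intervals are 0-based half-open and are returned sorted by
#' (chromosome, start); unsorted input is sorted with a warning and
#' overlapping intervals on one chromosome are an error.
#'
#' @param path file path.
#' @return data.frame of bins.
#' @export
readBins <- function(path) .readCnTable(path, "bin")

#' Read segment tables (.cns dialect)
#'
#' Same dialect and contracts as [readBins()]; segment tables may carry
#' additional columns (e.g. `cn`, `probes`).
#'
#' @param path file path.
#' @return data.frame of segments.
#' @export
readSegments <- function(path) .readCnTable(path, "segment")

.writeCnTable <- function(df, path) {
  .assertColumns(df, c("chromosome", "start", "end", "log2"), "table")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readBins
#' @param bins bin table to write.
#' @export
writeBins <- function(bins, path) .writeCnTable(bins, path)

#' @rdname readSegments
#' @param segments segment table to write.
#' @export
writeSegments <- function(segments, path) .writeCnTable(segments, path)

.SPECIMENS <- c("cfDNA", "sphDNA", "FFPE")

#' Read and validate the cohort manifest
#'
#' Tab-separated table with columns `participant_id`, `sample_id`,
#' `specimen` (one of cfDNA, sphDNA, FFPE), `timepoint_days` (days from the
#' participant's first sample, 0 for the initial sample) and optionally
#' `purity_hint` (a supplied tumour fraction in `[0, 1]`).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readManifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateManifest(df)
}

#' @rdname readManifest
#' @param m manifest data.frame to validate in place.
#' @export
validateManifest <- function(m) {
  .assertColumns(m, c("participant_id", "sample_id", "specimen",
                      "timepoint_days"), "manifest")
  if (anyDuplicated(m$sample_id))
    stop("manifest: sample_id values must be unique")
  if (!all(m$specimen %in% .SPECIMENS))
    stop("manifest: specimen must be one of ", paste(.SPECIMENS, collapse = ", "))
  if (any(is.na(m$timepoint_days)) || any(m$timepoint_days < 0))
    stop("manifest: timepoint_days must be >= 0")
  if (!"purity_hint" %in% names(m)) m$purity_hint <- NA_real_
  ok <- is.na(m$purity_hint) | (m$purity_hint >= 0 & m$purity_hint <= 1)
  if (!all(ok)) stop("manifest: purity_hint must lie in [0, 1]")
  m
}

#' @rdname readManifest
#' @export
writeManifest <- function(m, path) {
  validateManifest(m)
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene/region intervals from BED
#'
#' Thin wrapper over [rtracklayer::import()]; BED is 0-based half-open on
#' disk and is returned as a 1-based `GRanges` (rtracklayer performs the
#' conversion).
#'
#' @param path BED file (3+ columns; column 4 supplies gene names).
#' @return a `GRanges`, with `name` metadata when present.
#' @export
readBedGenes <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Export clonal-inference input (PyClone-VI dialect)
#'
#' Writes one row per (variant, sample) with columns `mutation_id`,
#' `sample_id`, `ref_counts`, `alt_counts`, `normal_cn` (always 2, the
#' expected diploid normal copy), `major_cn`, `minor_cn` and
#' `tumour_content`. Panel data cannot phase alleles, so allele-specific
#' copy number is approximated from the total: `major_cn = max(cn - 1, 1)`
#' and `minor_cn = cn - major_cn` for `cn >= 1` (a documented
#' simplification).
#'
#' @param variants variant table (one row per variant x sample) with
#'   `chrom, pos, ref, alt, alt_count, depth, sample_id`.
#' @param purities data.frame with `sample_id` and `t` (tumour fraction).
#' @param segments named list (by sample_id) of segment tables carrying
#'   `cn_int`, used to look up the local copy number of each variant.
#' @param path output TSV path.
#' @return the exported data.frame, invisibly.
#' @export
writePycloneInput <- function(variants, purities, segments, path) {
  .assertColumns(variants, c(.VARIANT_REQUIRED, "sample_id"), "variant table")
  .assertColumns(purities, c("sample_id", "t"), "purity table")
  missingPurity <- setdiff(unique(variants$sample_id), purities$sample_id)
  if (length(missingPurity) > 0L) {
    stop("missing purity for sample(s): ", paste(missingPurity, collapse = ", "))
  }
  cn <- rep(NA_integer_, nrow(variants))
  for (sid in unique(variants$sample_id)) {
    idx <- variants$sample_id == sid
    seg <- segments[[sid]]
    if (is.null(seg)) stop("missing segments for sample: ", sid)
    cn[idx] <- segmentCnAtPositions(seg, variants$chrom[idx],
                                    variants$pos[idx])
  }
  if (anyNA(cn)) {
    stop(sum(is.na(cn)), " variant(s) fall outside every segment; ",
         "every exported variant needs a local copy number")
  }
  if (any(cn < 1)) {
    stop(sum(cn < 1), " variant(s) lie on copy-number-0 segments; ",
         "exclude them first (see prepareClonalInputs)")
  }
  major <- pmax(cn - 1L, 1L)
  out <- data.frame(
    mutation_id = .variantKey(variants$chrom, variants$pos, variants$ref,
                              variants$alt),
    sample_id = variants$sample_id,
    ref_counts = variants$depth - variants$alt_count,
    alt_counts = variants$alt_count,
    normal_cn = 2L,
    major_cn = major,
    minor_cn = cn - major,
    tumour_content = purities$t[match(variants$sample_id,
                                      purities$sample_id)],
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
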