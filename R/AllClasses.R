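#' GenomeModel: contigs, bin grid and callable footprint
#'
#' Describes the reference the pipeline operates on: contig names and lengths,
#' the fixed bin width used for the binned LOH statistic and simulated
#' copy-ratio profiles (100 kb by default, chromosome-limited: the last bin of
#' each contig is truncated at the contig end), and the callable panel
#' footprint in megabases used as the TMB denominator (1.94 Mb by default, the
#' coding footprint of a 523-gene targeted oncology panel).
#'
#' @slot contigs named numeric vector of contig lengths in bp.
#' @slot binSize bin width in bp.
#' @slot callableMb callable megabases for TMB.
#'
#' @export
setClass("GenomeModel",
  representation(contigs = "numeric", binSize = "numeric",
                 callableMb = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@contigs) == 0L || is.null(names(object@contigs)) ||
        any(!nzchar(names(object@contigs))))
      msg <- c(msg, "contigs must be a named vector of lengths")
    if (any(object@contigs <= 0)) msg <- c(msg, "contig lengths must be > 0")
    if (anyDuplicated(names(object@contigs)))
      msg <- c(msg, "contig names must be unique")
    if (length(object@binSize) != 1L || object@binSize <= 0)
      msg <- c(msg, "binSize must be a single positive number")
    if (length(object@callableMb) != 1L || object@callableMb <= 0)
      msg <- c(msg, "callableMb must be a single positive number")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GenomeModel
#'
#' @param contigs named numeric vector of contig lengths (bp).
#' @param binSize bin width in bp (default 100 kb).
#' @param callableMb callable megabases used as the TMB denominator
#'   (default 1.94).
#' @return a [GenomeModel-class] object.
#' @export
#' @examples
#' GenomeModel(c(chr1 = 50e6, chr2 = 40e6))
GenomeModel <- function(contigs, binSize = 1e5, callableMb = 1.94) {
  methods::new("GenomeModel", contigs = contigs, binSize = binSize,
               callableMb = callableMb)
}

#' hg19 autosome genome model
#'
#' The 22 autosomes of GRCh37/hg19 at their standard lengths, with the default
#' 100-kb bin grid and 1.94-Mb callable footprint.
#'
#' @inheritParams GenomeModel
#' @return a [GenomeModel-class].
#' @export
hg19Genome <- function(binSize = 1e5, callableMb = 1.94) {
  lens <- c(
    chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566
  )
  GenomeModel(lens, binSize = binSize, callableMb = callableMb)
}

#' @describeIn GenomeModel-class contig lengths (named numeric, bp).
#' @param object,x a `GenomeModel`.
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @rdname GenomeModel-class
#' @export
setMethod("contigLengths", "GenomeModel", function(x) x@contigs)

#' @rdname GenomeModel-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname GenomeModel-class
#' @export
setMethod("binSize", "GenomeModel", function(x) x@binSize)

#' @rdname GenomeModel-class
#' @export
setGeneric("callableMb", function(x) standardGeneric("callableMb"))

#' @rdname GenomeModel-class
#' @export
setMethod("callableMb", "GenomeModel", function(x) x@callableMb)

setMethod("show", "GenomeModel", function(object) {
  cat(sprintf("GenomeModel: %d contigs, %.1f Mb total\n",
              length(object@contigs), sum(object@contigs) / 1e6))
  cat(sprintf("  bin size: %g bp; callable footprint: %g Mb\n",
              object@binSize, object@callableMb))
})

#' Chromosome-limited bin grid of a genome model
#'
#' Tiles every contig with fixed-width bins anchored at position 0, truncating
#' the final bin at the contig end (bins never cross contigs).
#'
#' @param genome a [GenomeModel-class].
#' @return data.frame with `chromosome`, `start`, `end` (0-based half-open),
#'   sorted by (contig order, start).
#' @export
genomeBins <- function(genome) {
  stopifnot(methods::is(genome, "GenomeModel"))
  tiles <- GenomicRanges::tileGenome(contigLengths(genome),
                                     tilewidth = binSize(genome),
                                     cut.last.tile.in.chrom = TRUE)
  df <- data.frame(
    chromosome = as.character(GenomeInfoDb::seqnames(tiles)),
    start = GenomicRanges::start(tiles) - 1,
    end = as.numeric(GenomicRanges::end(tiles)),
    stringsAsFactors = FALSE
  )
  ## lexicographic (chromosome, start) is the canonical row order of every
  ## bin/segment table in the package (it is what the readers enforce)
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' SyntheticCohort: a simulated ascites cfDNA cohort with ground truth
#'
#' Container returned by [simulateCohort()]. Holds one variant table, one
#' copy-ratio bin table and one segment table per sample (in the same table
#' dialects the readers in this package consume), the cohort manifest, the
#' genome model, and a `truth` list recording every generative parameter
#' (per-sample purity, clone CCFs, truth segments with allele-specific copy
#' number, variant provenance) so downstream estimates can be checked against
#' known values.
#'
#' @slot genome the [GenomeModel-class] used.
#' @slot manifest data.frame with columns `participant_id`, `sample_id`,
#'   `specimen`, `timepoint_days`, `purity_hint`.
#' @slot variants named list (by sample_id) of variant tables.
#' @slot bins named list of bin-level log2 copy-ratio tables.
#' @slot segments named list of segment tables.
#' @slot truth list of ground-truth records.
#'
#' @export
setClass("SyntheticCohort",
  representation(genome = "GenomeModel", manifest = "data.frame",
                 variants = "list", bins = "list", segments = "list",
                 truth = "list"),
  validity = function(object) {
    msg <- character()
    ids <- object@manifest$sample_id
    if (anyDuplicated(ids)) msg <- c(msg, "sample_id must be unique")
    for (slot in c("variants", "bins", "segments")) {
      if (!identical(sort(names(methods::slot(object, slot))), sort(ids)))
        msg <- c(msg, sprintf("names of @%s must match manifest sample_id", slot))
    }
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn SyntheticCohort-class the cohort manifest.
#' @param x,object a `SyntheticCohort`.
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("manifest", "SyntheticCohort", function(x) x@manifest)

#' @rdname SyntheticCohort-class
#' @export
setGeneric("variantTables", function(x) standardGeneric("variantTables"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("variantTables", "SyntheticCohort", function(x) x@variants)

#' @rdname SyntheticCohort-class
#' @export
setGeneric("binTables", function(x) standardGeneric("binTables"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("binTables", "SyntheticCohort", function(x) x@bins)

#' @rdname SyntheticCohort-class
#' @export
setGeneric("segmentTables", function(x) standardGeneric("segmentTables"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("segmentTables", "SyntheticCohort", function(x) x@segments)

#' @rdname SyntheticCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

#' @rdname SyntheticCohort-class
#' @export
setGeneric("genomeModel", function(x) standardGeneric("genomeModel"))

#' @rdname SyntheticCohort-class
#' @export
setMethod("genomeModel", "SyntheticCohort", function(x) x@genome)

setMethod("show", "SyntheticCohort", function(object) {
  m <- object@manifest
  cat(sprintf("SyntheticCohort: %d participants, %d samples\n",
              length(unique(m$participant_id)), nrow(m)))
  cat(sprintf("  specimens: %s\n",
              paste(sprintf("%s=%d", names(table(m$specimen)),
                            as.integer(table(m$specimen))), collapse = ", ")))
  nv <- vapply(object@variants, nrow, integer(1))
  cat(sprintf("  variants per sample: %d-%d; purity: %.2f-%.2f\n",
              min(nv), max(nv),
              min(object@truth$purity$t), max(object@truth$purity$t)))
})
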