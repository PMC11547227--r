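## Genomic-instability consensus scoring.
##
## LGA count, LOH% and TMB are three imperfect surrogates of homologous
## recombination deficiency; rather than trusting any single one, each sample
## scores one point per marker strictly above the cohort median, giving a
## 0-3 consensus. Medians are computed over each participant's initial
## sample only (serial samples are scored against the same medians, so a
## participant sampled repeatedly does not drag the reference).

#' Genomic-instability consensus score (0-3)
#'
#' @param markers data.frame with one row per sample: `sample_id`,
#'   `participant_id`, `lga`, `loh_percent`, `loh_reliable` (logical),
#'   `tmb`, and logical `initial` marking each participant's first sample
#'   (if absent, every sample is treated as initial).
#' @param recomputeMedians kept for completeness: if `TRUE`, medians are
#'   computed over all samples rather than initial ones only.
#' @return the input with a `gi_score` column (strictly-above-median marker
#'   count; an unreliable LOH is excluded from the LOH median and contributes
#'   0 to its sample's score) plus per-marker logical columns
#'   `lga_above`, `loh_above`, `tmb_above`. The medians used are attached as
#'   attribute `medians`.
#' @export
#' @examples
#' m <- data.frame(sample_id = c("a", "b", "c"),
#'                 participant_id = c("p1", "p2", "p3"),
#'                 lga = c(17, 10, 3), loh_percent = c(64, 40, 20),
#'                 loh_reliable = TRUE, tmb = c(3.9, 4.0, 4.1))
#' giConsensus(m)$gi_score
giConsensus <- function(markers, recomputeMedians = FALSE) {
  .assertColumns(markers, c("sample_id", "lga", "loh_percent",
                            "loh_reliable", "tmb"), "marker table")
  if (nrow(markers) < 2L) stop("need at least 2 samples")
  init <- if ("initial" %in% names(markers) && !recomputeMedians)
    markers$initial else rep(TRUE, nrow(markers))
  medianOf <- function(x, ok) {
    x <- x[ok & !is.na(x)]
    if (length(x) == 0L) stop("no usable values for a marker median")
    stats::median(x)
  }
  medians <- c(
    lga = medianOf(markers$lga, init),
    loh_percent = medianOf(markers$loh_percent, init & markers$loh_reliable),
    tmb = medianOf(markers$tmb, init)
  )
  markers$lga_above <- !is.na(markers$lga) & markers$lga > medians["lga"]
  markers$loh_above <- markers$loh_reliable & !is.na(markers$loh_percent) &
    markers$loh_percent > medians["loh_percent"]
  markers$tmb_above <- !is.na(markers$tmb) & markers$tmb > medians["tmb"]
  markers$gi_score <- markers$lga_above + markers$loh_above + markers$tmb_above
  attr(markers, "medians") <- medians
  markers
}

#' Annotate fixed HRD thresholds
#'
#' Literature cut-offs, independent of the cohort medians: `lga_ge_20`
#' (LGA count of 20 or more indicates HRD) and `loh_gt_16` (LOH strictly
#' above 16% of the assessed genome).
#'
#' @param report data.frame with `lga` and `loh_percent` columns.
#' @return the input with logical `lga_ge_20` and `loh_gt_16` columns.
#' @export
annotateHrdThresholds <- function(report) {
  .assertColumns(report, c("lga", "loh_percent"), "report")
  report$lga_ge_20 <- !is.na(report$lga) & report$lga >= 20
  report$loh_gt_16 <- !is.na(report$loh_percent) & report$loh_percent > 16
  report
}
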