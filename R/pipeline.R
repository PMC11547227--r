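## End-to-end orchestration: triage -> purity -> copy number -> LOH ->
## clonal -> genomic-instability consensus, with per-stage TSV outputs and a
## cohort JSON report.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full profiling pipeline on a cohort directory
#'
#' Expects `manifest.tsv` plus, per sample, `<sample>.variants.tsv`,
#' `<sample>.cnr` and `<sample>.cns` (the layout [writeCohort()] emits).
#' Executes somatic triage, purity estimation, purity-rescaled copy number
#' with modified-Z repair and LGA counting, binned LOH, clonal CCF clustering
#' with temporal shift detection (per participant with >= 2 samples), and the
#' 0-3 genomic-instability consensus. Writes per-stage TSVs
#' (`somatic.tsv`, `purity.tsv`, `cnv_report.tsv`, `loh.tsv`,
#' `clusters.tsv`, `shifts.tsv`), a cohort `report.json` and `run_log.json`
#' (package version, parameters, seed). Output is deterministic for fixed
#' inputs and parameters (no timestamps).
#'
#' @param inputDir directory with the cohort files.
#' @param outDir output directory (created). Partial outputs are retained if
#'   a later stage fails.
#' @param genome a [GenomeModel-class] (bin grid + callable Mb).
#' @param thresholds a [filterThresholds()] object.
#' @param anchorGene purity anchor gene (default TP53).
#' @param genes optional `GRanges` of gene intervals for amplification calls.
#' @param clusterSeed seed for the clonal clustering (default 1).
#' @return (invisibly) a list with all stage tables: `somatic`, `filter`,
#'   `purity`, `segments` (repaired, per sample), `cnv` (per-sample LGA),
#'   `loh`, `clones` (per participant), `shifts`, `report`.
#' @export
runPipeline <- function(inputDir, outDir, genome = hg19Genome(),
                        thresholds = filterThresholds(),
                        anchorGene = "TP53", genes = NULL, clusterSeed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  man <- .stage("manifest", readManifest(file.path(inputDir, "manifest.tsv")))

  allVars <- .stage("read-variants", {
    do.call(rbind, lapply(man$sample_id, function(sid) {
      f <- file.path(inputDir, paste0(sid, ".variants.tsv"))
      if (!file.exists(f)) stop("missing variant file for sample ", sid)
      readVariants(f, sampleId = sid,
                   participantId = man$participant_id[man$sample_id == sid])
    }))
  })

  filt <- .stage("filter", filterSomaticVariants(allVars, thresholds,
                                                 callableMb(genome)))
  writeVariants(filt$somatic, file.path(outDir, "somatic.tsv"))

  pur <- .stage("purity", estimatePurity(filt$somatic, man, anchorGene))
  utils::write.table(pur, file.path(outDir, "purity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  segsBySample <- list()
  cnvRows <- list()
  ampRows <- list()
  for (sid in man$sample_id) {
    segsBySample[[sid]] <- .stage(paste0("cnv:", sid), {
      f <- file.path(inputDir, paste0(sid, ".cns"))
      if (!file.exists(f)) stop("missing segments file for sample ", sid)
      seg <- readSegments(f)
      t <- pur$t[pur$sample_id == sid]
      seg <- segmentCopyNumbers(seg, max(t, 1e-3))
      repairUnreliableSegments(seg)
    })
    lga <- countLga(segsBySample[[sid]])
    cnvRows[[sid]] <- data.frame(sample_id = sid, lga = lga$lga_count,
                                 stringsAsFactors = FALSE)
    if (!is.null(genes)) {
      amp <- callGeneAmplifications(segsBySample[[sid]], genes)
      amp$sample_id <- sid
      ampRows[[sid]] <- amp
    }
  }
  cnv <- do.call(rbind, cnvRows)
  rownames(cnv) <- NULL
  utils::write.table(cnv, file.path(outDir, "cnv_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(ampRows) > 0) {
    utils::write.table(do.call(rbind, ampRows),
                       file.path(outDir, "amplifications.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  lohRows <- lapply(man$sample_id, function(sid) {
    r <- .stage(paste0("loh:", sid),
                lohPercent(allVars[allVars$sample_id == sid, , drop = FALSE],
                           genome))
    data.frame(sample_id = sid, loh_percent = r$loh_percent,
               occupied_bins = r$occupied_bins, loh_bins = r$loh_bins,
               loh_reliable = r$reliable,
               reason = r$reason %||% NA_character_,
               exceeds_coleman_cutoff = r$exceeds_coleman_cutoff,
               stringsAsFactors = FALSE)
  })
  loh <- do.call(rbind, lohRows)
  utils::write.table(loh, file.path(outDir, "loh.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## clonal analysis per participant with >= 2 samples
  clonesOut <- list()
  shiftsOut <- list()
  for (pid in unique(man$participant_id)) {
    sub <- man[man$participant_id == pid, , drop = FALSE]
    sub <- sub[order(sub$timepoint_days), , drop = FALSE]
    if (nrow(sub) < 2L) next
    pv <- filt$somatic[filt$somatic$participant_id == pid, , drop = FALSE]
    if (nrow(pv) == 0L) next
    runClones <- function() {
      prep <- prepareClonalInputs(pv, pur[pur$sample_id %in% sub$sample_id, ],
                                  segsBySample[sub$sample_id])
      if (nrow(prep$rows) == 0L) return(NULL)
      X <- ccfMatrix(prep$rows, sub$sample_id)
      if (nrow(X) == 0L) return(NULL)
      cl <- clusterCcf(X, seed = clusterSeed)
      shifts <- detectPrevalenceShifts(cl$clusters, sub$sample_id)
      list(clusters = cl$clusters,
           shifts = cbind(participant_id = pid, shifts))
    }
    res <- .stage(paste0("clones:", pid), runClones())
    if (!is.null(res)) {
      ## sample-specific ccf_ columns differ between participants; keep long
      cc <- res$clusters
      long <- do.call(rbind, lapply(sub$sample_id, function(sid)
        data.frame(participant_id = pid, cluster_id = cc$cluster_id,
                   n_variants = cc$n_variants, sample_id = sid,
                   ccf = cc[[paste0("ccf_", sid)]],
                   stringsAsFactors = FALSE)))
      clonesOut[[pid]] <- long
      shiftsOut[[pid]] <- res$shifts
    }
  }
  clones <- if (length(clonesOut)) do.call(rbind, clonesOut) else
    data.frame()
  shifts <- if (length(shiftsOut)) do.call(rbind, shiftsOut) else
    data.frame()
  if (nrow(clones)) {
    rownames(clones) <- NULL
    utils::write.table(clones, file.path(outDir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (nrow(shifts)) {
    rownames(shifts) <- NULL
    utils::write.table(shifts, file.path(outDir, "shifts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  markers <- .stage("score", {
    m <- merge(merge(cnv, loh, by = "sample_id"),
               filt$report[c("sample_id", "tmb", "total_variants",
                             "count_outlier")], by = "sample_id")
    m <- merge(m, man[c("sample_id", "participant_id", "timepoint_days")],
               by = "sample_id")
    first <- stats::ave(m$timepoint_days, m$participant_id, FUN = min)
    m$initial <- m$timepoint_days == first
    m <- giConsensus(m)
    annotateHrdThresholds(m)
  })
  medians <- attr(markers, "medians")
  markers <- merge(markers, pur[c("sample_id", "t", "method")],
                   by = "sample_id")
  markers <- markers[order(markers$participant_id, markers$timepoint_days), ]
  rownames(markers) <- NULL
  utils::write.table(markers, file.path(outDir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  report <- list(
    n_participants = length(unique(man$participant_id)),
    n_samples = nrow(man),
    medians = as.list(medians),
    samples = markers,
    flagged_count_outliers =
      filt$report$sample_id[filt$report$count_outlier]
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  jsonlite::write_json(
    list(package = "ascitesProfiler",
         version = as.character(utils::packageVersion("ascitesProfiler")),
         cluster_seed = clusterSeed,
         thresholds = unclass(thresholds),
         callable_mb = callableMb(genome)),
    file.path(outDir, "run_log.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(somatic = filt$somatic, filter = filt$report, purity = pur,
                 segments = segsBySample, cnv = cnv, loh = loh,
                 clones = clones, shifts = shifts, report = markers))
}
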