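## Tumour-fraction estimation.
##
## In high-grade serous ovarian carcinoma the canonical trajectory is a
## deleterious TP53 point mutation followed by deletion of the competing
## wild-type allele (the double-hit model). Tumour cells then carry one mutant
## TP53 copy and zero wild-type copies while admixed normal cells carry two
## wild-type copies, so the mutant VAF is a direct purity readout:
##
##   v = t / (t + 2(1 - t))  =>  t = v / ((1 - v)/2 + v) = 2v / (1 + v)

#' Tumour fraction from the deleterious TP53 VAF (double-hit model)
#'
#' Inverts the double-hit relationship `v = t / (2 - t)`: a tumour cell
#' contributes one mutant allele against the two wild-type alleles of each
#' admixed normal cell, giving `t = 2v / (1 + v)`.
#'
#' @param v VAF of the deleterious TP53 variant, in `[0, 1]`.
#' @return tumour fraction `t` in `[0, 1]`, monotone increasing in `v` and
#'   always `>= v`.
#' @seealso [vafFromPurity()] for the inverse, [proportionalPurity()] for the
#'   fallback used when TP53 itself is deleted.
#' @export
#' @examples
#' purityFromTp53Vaf(1 / 3)  # 0.5
#' purityFromTp53Vaf(0.88)   # ~0.936
purityFromTp53Vaf <- function(v) {
  if (any(is.na(v)) || any(v < 0) || any(v > 1)) {
    stop("VAF must lie in [0, 1]")
  }
  2 * v / (1 + v)
}

#' Expected deleterious TP53 VAF at a given tumour fraction
#'
#' @param t tumour fraction in `[0, 1]`.
#' @return expected VAF `v = t / (2 - t)`. Round-trips with
#'   [purityFromTp53Vaf()] to machine precision.
#' @export
vafFromPurity <- function(t) {
  if (any(is.na(t)) || any(t < 0) || any(t > 1)) {
    stop("tumour fraction must lie in [0, 1]")
  }
  t / (2 - t)
}

#' Proportional purity against a reference sample
#'
#' Fallback for samples whose TP53 VAF cannot anchor purity (e.g. the TP53
#' locus itself is deleted in later samples): scale a shared deleterious
#' variant's VAF against a reference sample with known purity,
#' `t = t_ref * v_sample / v_ref`, clipped to `[0, 1]`.
#'
#' @param vSample VAF of the shared anchor variant in the query sample.
#' @param vRef VAF of the same variant in the reference sample (> 0).
#' @param tRef tumour fraction of the reference sample, in `[0, 1]`.
#' @return estimated tumour fraction in `[0, 1]`.
#' @export
proportionalPurity <- function(vSample, vRef, tRef) {
  if (any(vRef <= 0)) stop("reference VAF must be > 0")
  if (any(tRef < 0) || any(tRef > 1)) stop("reference purity must lie in [0, 1]")
  pmin(pmax(tRef * vSample / vRef, 0), 1)
}

#' Select the purity anchor variant of a sample
#'
#' The anchor is the deleterious variant of `gene` with the highest VAF
#' (under the gatekeeper assumption the clonal TP53 hit carries the largest
#' VAF when several deleterious calls coexist).
#'
#' @param variants variant table of one sample with `gene`, `effect` and
#'   `vaf` columns; deleterious calls are rows with `effect == "deleterious"`.
#' @param gene anchor gene symbol (default `"TP53"`).
#' @return the anchor row (single-row data.frame), or `NULL` when the sample
#'   carries no usable (VAF > 0) deleterious variant in `gene`.
#' @export
selectAnchorVariant <- function(variants, gene = "TP53") {
  if (nrow(variants) == 0L || !all(c("gene", "effect") %in% names(variants))) {
    return(NULL)
  }
  hits <- variants[!is.na(variants$gene) & variants$gene == gene &
                     !is.na(variants$effect) &
                     variants$effect == "deleterious" &
                     variants$vaf > 0, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits[which.max(hits$vaf), , drop = FALSE]
}

#' Estimate tumour purity for every sample of a cohort
#'
#' Per sample, in order of preference: (1) the double-hit estimate
#' [purityFromTp53Vaf()] from the highest-VAF deleterious variant of
#' `anchorGene`; (2) the proportional method against `refSample` using a
#' shared deleterious `refGene` variant ([proportionalPurity()]); (3) the
#' manifest's `purity_hint` (method `"supplied"`). A sample with none of the
#' three is an error.
#'
#' @param variants cohort variant table (all samples) with `sample_id`,
#'   `gene`, `effect`, `vaf`.
#' @param manifest cohort manifest (see [readManifest()]).
#' @param anchorGene gene anchoring the double-hit estimate (default TP53).
#' @param refSample,refGene reference sample id and shared gene for the
#'   proportional fallback; the reference sample must itself have an
#'   `anchorGene` (or supplied) purity.
#' @return data.frame with `sample_id`, `t`, `method`
#'   (`tp53_double_hit` / `proportional` / `supplied`) and `anchor_variant`
#'   (variant key or `NA`).
#' @export
estimatePurity <- function(variants, manifest, anchorGene = "TP53",
                           refSample = NULL, refGene = "PIK3CA") {
  manifest <- validateManifest(manifest)
  out <- data.frame(sample_id = manifest$sample_id, t = NA_real_,
                    method = NA_character_, anchor_variant = NA_character_,
                    stringsAsFactors = FALSE)
  anchors <- list()
  for (i in seq_len(nrow(out))) {
    sid <- out$sample_id[i]
    sv <- variants[variants$sample_id == sid, , drop = FALSE]
    anchors[[sid]] <- selectAnchorVariant(sv, anchorGene)
    if (!is.null(anchors[[sid]])) {
      a <- anchors[[sid]]
      out$t[i] <- purityFromTp53Vaf(a$vaf)
      out$method[i] <- "tp53_double_hit"
      out$anchor_variant[i] <- .variantKey(a$chrom, a$pos, a$ref, a$alt)
    }
  }
  for (i in which(is.na(out$t))) {
    sid <- out$sample_id[i]
    done <- FALSE
    if (!is.null(refSample) && refSample %in% out$sample_id &&
        !is.na(out$t[out$sample_id == refSample])) {
      tRef <- out$t[out$sample_id == refSample]
      refVars <- variants[variants$sample_id == refSample, , drop = FALSE]
      refAnchor <- selectAnchorVariant(refVars, refGene)
      if (!is.null(refAnchor)) {
        sv <- variants[variants$sample_id == sid, , drop = FALSE]
        key <- .variantKey(refAnchor$chrom, refAnchor$pos, refAnchor$ref,
                           refAnchor$alt)
        hit <- sv[.variantKey(sv$chrom, sv$pos, sv$ref, sv$alt) == key, ,
                  drop = FALSE]
        if (nrow(hit) == 1L) {
          out$t[i] <- proportionalPurity(hit$vaf, refAnchor$vaf, tRef)
          out$method[i] <- "proportional"
          out$anchor_variant[i] <- key
          done <- TRUE
        }
      }
    }
    if (!done) {
      hint <- manifest$purity_hint[manifest$sample_id == sid]
      if (length(hint) == 1L && !is.na(hint)) {
        out$t[i] <- hint
        out$method[i] <- "supplied"
      } else {
        stop("purity undeterminable for sample ", sid,
             ": no deleterious ", anchorGene,
             " anchor, no proportional reference, no purity hint")
      }
    }
  }
  out
}
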