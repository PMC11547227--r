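## Clonal analysis: cancer-cell-fraction estimation, exclusion rules,
## a transparent mixture-clustering stand-in, and temporal prevalence shifts.

#' Cancer cell fraction of a variant
#'
#' Standard CCF identity: the expected VAF of a somatic variant present in a
#' fraction `ccf` of tumour cells at multiplicity `m` on local tumour copy
#' number `cn` is `v = ccf * t * m / (t*cn + 2(1-t))`. Multiplicity is not
#' observable from unphased panel data, so it is estimated per variant by the
#' rounding rule `m_hat = clip(round(v * (t*cn + 2(1-t)) / t), 1, cn)` and
#' the identity inverted:
#' `ccf = clip(v * (t*cn + 2(1-t)) / (t * m_hat), 0, 1)`.
#'
#' @param v observed VAF(s).
#' @param t tumour fraction in `(0, 1]`.
#' @param cn local tumour copy number (integer >= 1).
#' @param m multiplicity; `NULL` (default) estimates it by the rounding rule.
#' @return list with `ccf` and `m` (the multiplicity used).
#' @export
#' @examples
#' ccfEstimate(0.25, 0.5, 2)$ccf  # 1.0
ccfEstimate <- function(v, t, cn, m = NULL) {
  if (any(t <= 0) || any(t > 1)) stop("t must lie in (0, 1]")
  if (any(cn < 1)) stop("cn must be >= 1 (copy-0 loci cannot carry a CCF)")
  denom <- t * cn + 2 * (1 - t)
  if (is.null(m)) m <- pmin(pmax(roundHalfUp(v * denom / t), 1L), cn)
  list(ccf = pmin(pmax(v * denom / (t * m), 0), 1), m = m)
}

#' Prepare clonal-inference inputs with the panel exclusion rules
#'
#' All samples of a participant share one variant universe (a variant absent
#' from a sample is an observation with zero alt reads). Two exclusion rules
#' apply before clustering: (1) a variant whose locus has integer copy number
#' 0 in ANY matched sample cannot be modelled and is dropped (`"cn0"`);
#' (2) when any sample of the participant has tumour purity below
#' `minPurity`, variants reaching `vafCap` or more in that sample are dropped
#' (`"low-purity-vaf"`) — at low purity a high VAF is germline evidence, not
#' clonal signal. The exclusion log partitions the variant universe.
#'
#' When the purity anchor variant itself is cn0-excluded, the participant
#' carries a high-frequency clone the clustering cannot represent; this is
#' reported in `unrepresented_clone`.
#'
#' @param variants one participant's variant table (all samples, shared
#'   universe) with `chrom, pos, ref, alt, alt_count, depth, vaf, sample_id`.
#' @param purities data.frame `sample_id`, `t` (plus optional
#'   `anchor_variant`).
#' @param segments named list (by sample_id) of segment tables with `cn_int`.
#' @param minPurity purity below which the VAF cap applies (default 0.30).
#' @param vafCap VAF at or above which variants are dropped in low-purity
#'   samples (default 0.30).
#' @return list with `rows` (retained rows plus `cn` and `ccf` columns),
#'   `exclusions` (data.frame variant key -> reason), and
#'   `unrepresented_clone` (`NULL`, or the anchor key that was cn0-excluded).
#' @export
prepareClonalInputs <- function(variants, purities, segments,
                                minPurity = 0.30, vafCap = 0.30) {
  .assertColumns(variants, c("chrom", "pos", "ref", "alt", "alt_count",
                             "depth", "vaf", "sample_id"), "variant table")
  .assertColumns(purities, c("sample_id", "t"), "purity table")
  sampleIds <- unique(variants$sample_id)
  for (sid in sampleIds) {
    if (is.null(segments[[sid]]))
      stop("sample without segments: ", sid)
  }
  variants$key <- .variantKey(variants$chrom, variants$pos, variants$ref,
                              variants$alt)
  variants$t <- purities$t[match(variants$sample_id, purities$sample_id)]
  if (anyNA(variants$t))
    stop("missing purity for sample(s): ",
         paste(unique(variants$sample_id[is.na(variants$t)]), collapse = ", "))
  cn <- rep(NA_integer_, nrow(variants))
  for (sid in sampleIds) {
    idx <- variants$sample_id == sid
    cn[idx] <- segmentCnAtPositions(segments[[sid]], variants$chrom[idx],
                                    variants$pos[idx])
  }
  variants$cn <- cn

  keys <- unique(variants$key)
  cn0Keys <- unique(variants$key[!is.na(cn) & cn == 0L])
  lowPuritySamples <- purities$sample_id[purities$t < minPurity]
  capKeys <- unique(variants$key[variants$sample_id %in% lowPuritySamples &
                                   variants$vaf >= vafCap])
  capKeys <- setdiff(capKeys, cn0Keys)  # cn0 takes precedence in the log
  excl <- data.frame(
    key = c(cn0Keys, capKeys),
    reason = c(rep("cn0", length(cn0Keys)),
               rep("low-purity-vaf", length(capKeys))),
    stringsAsFactors = FALSE
  )
  keep <- !(variants$key %in% excl$key)
  rows <- variants[keep, , drop = FALSE]
  if (nrow(rows) > 0L) {
    est <- ccfEstimate(rows$vaf, rows$t, pmax(rows$cn, 1L))
    rows$multiplicity <- est$m
    rows$ccf <- est$ccf
  }
  rownames(rows) <- NULL

  unrep <- NULL
  if ("anchor_variant" %in% names(purities)) {
    anchors <- stats::na.omit(unique(purities$anchor_variant))
    hit <- intersect(anchors, cn0Keys)
    if (length(hit) > 0L) {
      warning("purity anchor variant ", paste(hit, collapse = ", "),
              " excluded as cn0: a high-frequency clone is unrepresented ",
              "in the clustering")
      unrep <- hit
    }
  }
  list(rows = rows, exclusions = excl, unrepresented_clone = unrep)
}

#' Cluster variants into clones by their CCF vectors
#'
#' Transparent stand-in for full Bayesian clonal deconvolution: k-means on
#' per-variant CCF vectors (variants x samples) for `k = 1..kMax`, each with
#' `nRestarts` random restarts, choosing `k` by BIC under a spherical
#' Gaussian profile with pooled variance,
#' `BIC = -2*logLik + (k*d + k)*log(n)`. The pooled variance is floored at
#' `varFloor`: CCFs are estimated from read counts, so within-clone spread
#' can never genuinely fall below counting noise (and truncal CCFs pile up at
#' the 1.0 clip); without the floor, degenerate tight clusters would make
#' ever-larger `k` look free. Deterministic given `seed`. The exporter
#' [writePycloneInput()] produces input for users who want full variational
#' inference instead.
#'
#' @param ccfMatrix numeric matrix, variants in rows (rownames = variant
#'   keys), samples in columns, entries in `[0, 1]`.
#' @param kMax maximum number of clones tried (default 8; capped at the
#'   number of distinct CCF vectors).
#' @param nRestarts random restarts per k (default 10).
#' @param seed RNG seed (default 1).
#' @param varFloor variance floor for the pooled Gaussian profile (default
#'   `0.075^2`): the clone-resolution scale. CCF differences below ~0.075 are
#'   not resolvable at typical panel depths once counting noise and
#'   multiplicity misassignment are accounted for, so structure finer than
#'   this is treated as noise.
#' @return list with `clusters` (data.frame `cluster_id`, one `ccf_<sample>`
#'   column per sample, `n_variants`), `assignment` (named integer vector,
#'   variant key -> cluster), and `k`.
#' @export
clusterCcf <- function(ccfMatrix, kMax = 8, nRestarts = 10, seed = 1,
                       varFloor = 0.075^2) {
  X <- as.matrix(ccfMatrix)
  if (nrow(X) < 1L) stop("need at least one variant with a CCF in every sample")
  if (is.null(rownames(X))) rownames(X) <- as.character(seq_len(nrow(X)))
  n <- nrow(X)
  d <- ncol(X)
  kCap <- min(kMax, nrow(unique(X)))
  set.seed(seed)
  best <- NULL
  bestBic <- Inf
  for (k in seq_len(kCap)) {
    km <- if (k == 1L) {
      centre <- matrix(colMeans(X), 1L, d)
      list(cluster = rep(1L, n), centers = centre,
           tot.withinss = sum(sweep(X, 2L, centre)^2))
    } else {
      suppressWarnings(
        stats::kmeans(X, centers = k, nstart = nRestarts, iter.max = 100L)
      )
    }
    sigma2 <- max(km$tot.withinss / (n * d), varFloor)
    logLik <- -n * d / 2 * log(2 * pi * sigma2) -
      km$tot.withinss / (2 * sigma2)
    bic <- -2 * logLik + (k * d + k) * log(n)
    if (bic < bestBic) {
      bestBic <- bic
      best <- list(k = k, km = km)
    }
  }
  centres <- pmin(pmax(best$km$centers, 0), 1)
  sampleNames <- colnames(X) %||% paste0("s", seq_len(d))
  clusters <- data.frame(cluster_id = seq_len(best$k),
                         n_variants = as.integer(table(best$km$cluster)),
                         stringsAsFactors = FALSE)
  for (j in seq_len(d)) {
    clusters[[paste0("ccf_", sampleNames[j])]] <- centres[, j]
  }
  assignment <- stats::setNames(as.integer(best$km$cluster), rownames(X))
  list(clusters = clusters, assignment = assignment, k = best$k)
}

#' Build the variant x sample CCF matrix from prepared clonal rows
#'
#' @param rows the `rows` element of [prepareClonalInputs()].
#' @param sampleOrder sample ids in temporal order (columns of the result).
#' @return numeric matrix (variant keys x samples); variants missing a CCF in
#'   any requested sample are dropped.
#' @export
ccfMatrix <- function(rows, sampleOrder) {
  m <- matrix(NA_real_, length(unique(rows$key)), length(sampleOrder),
              dimnames = list(unique(rows$key), sampleOrder))
  idx <- cbind(match(rows$key, rownames(m)),
               match(rows$sample_id, sampleOrder))
  ok <- !is.na(idx[, 2])
  m[idx[ok, , drop = FALSE]] <- rows$ccf[ok]
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Detect clonal prevalence shifts between consecutive samples
#'
#' For each clone and each consecutive sample pair in `sampleOrder`,
#' `delta = ccf(later) - ccf(earlier)`; the shift is flagged when
#' `|delta|` strictly exceeds `threshold` (absolute CCF points).
#'
#' @param clusters the `clusters` data.frame of [clusterCcf()] (with
#'   `ccf_<sample>` columns).
#' @param sampleOrder sample ids in temporal order (>= 2).
#' @param threshold strict absolute shift cutoff (default 0.10).
#' @return data.frame with `cluster_id`, `from`, `to`, `delta_ccf`,
#'   `flagged`.
#' @export
detectPrevalenceShifts <- function(clusters, sampleOrder, threshold = 0.10) {
  if (length(sampleOrder) < 2L) stop("need at least 2 samples")
  cols <- paste0("ccf_", sampleOrder)
  .assertColumns(clusters, cols, "cluster table")
  out <- list()
  for (i in seq_len(length(sampleOrder) - 1L)) {
    delta <- clusters[[cols[i + 1L]]] - clusters[[cols[i]]]
    out[[i]] <- data.frame(
      cluster_id = clusters$cluster_id,
      from = sampleOrder[i], to = sampleOrder[i + 1L],
      delta_ccf = delta,
      flagged = abs(delta) > threshold,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
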