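test_that("CCF identity and multiplicity rounding behave at the anchors", {
  expect_equal(ccfEstimate(0.25, 0.5, 2)$ccf, 1.0)
  expect_equal(ccfEstimate(0.25, 0.5, 2)$m, 1L)
  expect_equal(ccfEstimate(0, 0.7, 3)$ccf, 0)
  # the TP53 double-hit point: v = t/(2-t) on a single-copy locus is clonal
  for (t in c(0.3, 0.6, 0.9)) {
    expect_equal(ccfEstimate(vafFromPurity(t), t, 1)$ccf, 1.0,
                 tolerance = 1e-12)
  }
  # a double-copy variant at full CCF is assigned multiplicity 2
  v2 <- expectedVaf(0.6, 1, 2, 2)
  expect_equal(ccfEstimate(v2, 0.6, 2)$m, 2L)
  expect_equal(ccfEstimate(v2, 0.6, 2)$ccf, 1.0, tolerance = 1e-12)
  expect_error(ccfEstimate(0.2, 0, 2), "\\(0, 1\\]")
  expect_error(ccfEstimate(0.2, 0.5, 0), "cn")
})

test_that("clonal input preparation applies cn0 and low-purity exclusions", {
  mk <- function(pos, sid, vaf) {
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
               alt_count = round(vaf * 100), depth = 100L, vaf = vaf,
               sample_id = sid, stringsAsFactors = FALSE)
  }
  # variant universe: pos 100 (cn0 in s2), pos 200 (high VAF in low-purity
  # s2), pos 300 (clean)
  v <- rbind(mk(100, "s1", 0.4), mk(100, "s2", 0.01),
             mk(200, "s1", 0.2), mk(200, "s2", 0.35),
             mk(300, "s1", 0.1), mk(300, "s2", 0.1))
  segs <- list(
    s1 = data.frame(chromosome = "chr1", start = 0, end = 1000, cn_int = 2L),
    s2 = data.frame(chromosome = "chr1", start = c(0, 150),
                    end = c(150, 1000), cn_int = c(0L, 2L))
  )
  pur <- data.frame(sample_id = c("s1", "s2"), t = c(0.8, 0.25))
  prep <- prepareClonalInputs(v, pur, segs)
  expect_setequal(unique(prep$rows$key), "chr1:300:A:T")
  expect_equal(prep$exclusions$reason[prep$exclusions$key == "chr1:100:A:T"],
               "cn0")
  expect_equal(prep$exclusions$reason[prep$exclusions$key == "chr1:200:A:T"],
               "low-purity-vaf")
  # the exclusion log partitions the universe
  expect_equal(length(unique(v$chrom)) * 3,
               length(unique(prep$rows$key)) + nrow(prep$exclusions))
  expect_true(all(c("cn", "ccf", "multiplicity") %in% names(prep$rows)))
  expect_error(prepareClonalInputs(v, pur, segs["s1"]), "without segments")
})

test_that("a cn0-excluded purity anchor is reported as an unrepresented clone", {
  v <- data.frame(chrom = "chr17", pos = c(7577539, 7577539), ref = "G",
                  alt = "A", alt_count = c(40L, 0L), depth = 100L,
                  vaf = c(0.4, 0), sample_id = c("s1", "s2"))
  segs <- list(
    s1 = data.frame(chromosome = "chr17", start = 0, end = 1e7, cn_int = 1L),
    s2 = data.frame(chromosome = "chr17", start = 0, end = 1e7, cn_int = 0L)
  )
  pur <- data.frame(sample_id = c("s1", "s2"), t = c(0.6, 0.6),
                    anchor_variant = "chr17:7577539:G:A")
  expect_warning(prep <- prepareClonalInputs(v, pur, segs),
                 "unrepresented")
  expect_equal(prep$unrepresented_clone, "chr17:7577539:G:A")
  expect_equal(nrow(prep$rows), 0L)
})

test_that("CCF clustering separates well-spaced clones and is deterministic", {
  X <- rbind(matrix(rep(c(1, 1), each = 10), 10) +
               matrix(rnorm(20, 0, 0.02), 10),
             matrix(rep(c(0.2, 0.5), each = 10), 10) +
               matrix(rnorm(20, 0, 0.02), 10))
  X <- pmin(pmax(X, 0), 1)
  rownames(X) <- paste0("v", 1:20)
  colnames(X) <- c("s1", "s2")
  r <- clusterCcf(X, seed = 3)
  expect_equal(r$k, 2L)
  expect_identical(r$assignment, clusterCcf(X, seed = 3)$assignment)
  centres <- sort(r$clusters$ccf_s1)
  expect_equal(centres, c(0.2, 1), tolerance = 0.05)

  same <- matrix(0.4, 12, 2,
                 dimnames = list(paste0("v", 1:12), c("s1", "s2")))
  expect_equal(clusterCcf(same, seed = 1)$k, 1L)
  expect_error(clusterCcf(same[0, , drop = FALSE]), "at least one")
})

test_that("prevalence shifts are flagged strictly above 10 points", {
  cl <- data.frame(cluster_id = 1:3,
                   ccf_s1 = c(0.40, 0.40, 0.80),
                   ccf_s2 = c(0.55, 0.50, 0.65))
  r <- detectPrevalenceShifts(cl, c("s1", "s2"))
  expect_equal(r$delta_ccf, c(0.15, 0.10, -0.15))
  expect_equal(r$flagged, c(TRUE, FALSE, TRUE))  # +0.10 exactly: not flagged
  expect_error(detectPrevalenceShifts(cl, "s1"), "at least 2")
  # three timepoints produce consecutive-pair rows
  cl$ccf_s3 <- c(0.55, 0.50, 0.65)
  r3 <- detectPrevalenceShifts(cl, c("s1", "s2", "s3"))
  expect_equal(nrow(r3), 6L)
  expect_false(any(r3$flagged[r3$from == "s2"]))
})

test_that("ccfMatrix assembles complete variant x sample vectors", {
  rows <- data.frame(key = c("a", "a", "b"), sample_id = c("s1", "s2", "s1"),
                     ccf = c(1, 0.8, 0.5))
  m <- ccfMatrix(rows, c("s1", "s2"))
  expect_equal(dim(m), c(1L, 2L))   # "b" lacks s2 and is dropped
  expect_equal(m["a", ], c(s1 = 1, s2 = 0.8))
})
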