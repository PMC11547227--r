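test_that("purity rescaling inverts the admixture mixture", {
  expect_equal(cnFromLog2(0, 1), 2)
  expect_equal(cnFromLog2(-1, 1), 1)
  expect_equal(cnFromLog2(log2(0.75), 0.5), 1)
  expect_error(cnFromLog2(0, 0), "\\(0, 1\\]")
  for (t in c(0.1, 0.4, 0.7, 1)) {
    cn <- 0:6
    expect_equal(cnFromLog2(log2FromCn(cn, t), t), cn, tolerance = 1e-12)
  }
  # deep deletions floor at 0 rather than going negative
  expect_equal(cnFromLog2(-8, 0.5), 0)
})

test_that("modified-Z repair replaces only high-depth outliers", {
  seg <- makeSegs(rep("chr1", 5), rep(20, 5), c(2, 2, 2, 2, 30),
                  depth = c(100, 100, 100, 100, 1000))
  r <- repairUnreliableSegments(seg)
  expect_equal(r$unreliable, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(r$cn_est[5], 2)   # single left flank at the contig end
  expect_equal(r$cn_int[5], 2L)

  flat <- makeSegs(rep("chr1", 4), rep(20, 4), c(2, 1, 3, 2), depth = 100)
  expect_warning(r2 <- repairUnreliableSegments(flat), "MAD")
  expect_equal(r2$cn_est, flat$cn_est)
  expect_false(any(r2$unreliable))

  mid <- makeSegs(rep("chr2", 5), rep(20, 5), c(1, 1, 9, 3, 3),
                  depth = c(100, 101, 900, 99, 100))
  r3 <- repairUnreliableSegments(mid)
  expect_equal(r3$cn_est[3], 2)  # mean of flanking 1 and 3
  expect_equal(r3$cn_int[3], 2L)
})

test_that("repair never touches segments at or below the depth cutoff", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    seg <- makeSegs(rep("chr1", n), runif(n, 11, 30),
                    sample(1:4, n, replace = TRUE),
                    depth = rlnorm(n, log(200), 0.2))
    z <- suppressWarnings(modifiedZScore(seg$mean_depth))
    r <- suppressWarnings(repairUnreliableSegments(seg))
    keep <- z <= 3.5
    expect_equal(r$cn_est[keep], seg$cn_est[keep])
  }
})

test_that("LGA counting follows the >10 Mb adjacency rule", {
  s1 <- makeSegs(rep("chr1", 4), c(12, 15, 11, 14), c(2, 1, 1, 3))
  expect_equal(countLga(s1)$lga_count, 2L)
  s2 <- makeSegs(rep("chr1", 3), c(8, 9, 5), c(1, 3, 1))
  expect_equal(countLga(s2)$lga_count, 0L)
  # short interveners are skipped: 12 Mb cn2 | 4 Mb cn5 | 15 Mb cn1 -> one LGA
  s3 <- makeSegs(rep("chr1", 3), c(12, 4, 15), c(2, 5, 1))
  expect_equal(countLga(s3)$lga_count, 1L)
  # exactly 10 Mb does not qualify (strict)
  s4 <- makeSegs(rep("chr1", 2), c(10, 15), c(1, 2))
  expect_equal(countLga(s4)$lga_count, 0L)
  expect_equal(nrow(countLga(s1)$breakpoints), 2L)
  # per-segment counting variant
  expect_equal(countLga(s1, counting = "segment")$lga_count, 2L)
})

test_that("LGA counting matches brute-force enumeration on random layouts", {
  set.seed(14)
  for (i in 1:300) {
    seg <- randomSegLayout()
    expect_equal(countLga(seg)$lga_count, bruteLga(seg),
                 label = paste("layout", i))
  }
})

test_that("planted LGA boundaries are recovered through the noisy bin model", {
  g <- smallGenome()
  set.seed(41)
  for (k in c(0, 4, 9)) {
    lens <- rep(15, k + 1)
    cns <- rep(c(2, 3), length.out = k + 1)
    truth <- makeSegs(rep("chr8", k + 1), lens, cns)
    names(truth)[names(truth) == "cn_int"] <- "total_cn"
    gk <- GenomeModel(c(chr8 = sum(lens) * 1e6))
    for (t in c(0.5, 0.8)) {
      prof <- simulateBinProfile(truth[c("chromosome", "start", "end",
                                         "total_cn")], gk, t, noiseSd = 0.1)
      seg <- suppressWarnings(  # k = 0 has a single segment (zero MAD)
        repairUnreliableSegments(segmentCopyNumbers(prof$segments, t)))
      expect_equal(countLga(seg)$lga_count, k,
                   label = sprintf("k=%d t=%.1f", k, t))
    }
  }
})

test_that("gene amplification calls use length-weighted segment CN", {
  seg <- data.frame(chromosome = "chr8", start = c(0, 10e6, 20e6),
                    end = c(10e6, 20e6, 30e6), cn_est = c(2, 29, 6))
  genes <- GenomicRanges::GRanges(
    "chr8", IRanges::IRanges(start = c(12e6, 1e6, 9e6 + 1) ,
                             end = c(13e6, 2e6, 11e6)),
    name = c("MYC", "NEUTRAL", "SPLIT"))
  r <- callGeneAmplifications(seg, genes)
  expect_equal(r$fold[r$gene == "MYC"], 14.5)
  expect_true(r$amplified[r$gene == "MYC"])
  expect_false(r$amplified[r$gene == "NEUTRAL"])
  # half in cn 2, half in cn 29... use an even split across cn 2 / cn 6:
  genes2 <- GenomicRanges::GRanges(
    "chr8", IRanges::IRanges(start = 19e6 + 1, end = 21e6), name = "EDGE")
  r2 <- callGeneAmplifications(seg, genes2)
  expect_equal(r2$cn_est, (29 + 6) / 2)
  # strictly-greater rule: fold exactly 2 is NOT amplified
  seg3 <- data.frame(chromosome = "chr1", start = c(0, 10), end = c(10, 20),
                     cn_est = c(2, 6))
  gene3 <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = 6, end = 15),
                                  name = "g")
  r3 <- callGeneAmplifications(seg3, gene3)
  expect_equal(r3$fold, 2)
  expect_false(r3$amplified)
  # no overlapping segment: NA, not amplified
  far <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10), name = "x")
  r4 <- suppressWarnings(callGeneAmplifications(seg, far))  # disjoint contigs
  expect_true(is.na(r4$cn_est))
  expect_false(r4$amplified)
})

test_that("profile divergence counts disparate bin assignments", {
  bins <- data.frame(chromosome = "chr1", start = seq(0, 9e6, 1e6),
                     end = seq(1e6, 10e6, 1e6), log2 = 0)
  segA <- data.frame(chromosome = "chr1", start = 0, end = 10e6, cn_int = 2L)
  segB <- data.frame(chromosome = "chr1", start = c(0, 7e6),
                     end = c(7e6, 10e6), cn_int = c(2L, 3L))
  expect_equal(profileDivergence(bins, bins, segA, segA), 0)
  expect_equal(profileDivergence(bins, bins, segA, segB), 30)
  shifted <- bins
  shifted$start <- shifted$start + 1
  expect_error(profileDivergence(bins, shifted, segA, segB), "grids differ")
})

test_that("profile clustering pairs duplicates first, bounds distances", {
  set.seed(5)
  base <- rnorm(300)
  prof <- rbind(a1 = base + rnorm(300, 0, 0.05),
                a2 = base + rnorm(300, 0, 0.05),
                b1 = rnorm(300))
  cl <- clusterProfiles(prof)
  expect_equal(cl$clusters[["a1"]], cl$clusters[["a2"]])
  expect_false(cl$clusters[["b1"]] == cl$clusters[["a1"]])

  dup <- rbind(x = base, y = base, z = rnorm(300))
  expect_equal(unname(clusterProfiles(dup)$hclust$height[1]), 0,
               tolerance = 1e-12)
  anti <- rbind(p = c(1, 2, 3, 4), q = c(4, 3, 2, 1))
  expect_equal(max(1 - cor(t(anti))), 2)
  expect_warning(clusterProfiles(rbind(c1 = rep(1, 4), r = c(1, 2, 1, 3))),
                 "constant")
})

test_that("patient-matched simulated samples cluster together", {
  cfg <- cohortConfig(nParticipants = 3, samplesPerParticipant = 2,
                      genome = smallGenome(), nGermlineSnps = 50,
                      cnChangeFraction = 0.05)
  co <- simulateCohort(cfg, seed = 23)
  prof <- t(sapply(manifest(co)$sample_id,
                   function(s) binTables(co)[[s]]$log2))
  cl <- clusterProfiles(prof, cutHeight = 0.4)
  for (pid in unique(manifest(co)$participant_id)) {
    sids <- manifest(co)$sample_id[manifest(co)$participant_id == pid]
    expect_equal(cl$clusters[[sids[1]]], cl$clusters[[sids[2]]])
  }
  expect_equal(length(unique(cl$clusters)), 3L)
})

test_that("paired region test matches the closed-form t statistic", {
  r <- regionDensityTest(c(10, 12, 11), c(8, 9, 7))
  expect_equal(r$t, 3 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-abs(r$t), 2), tolerance = 1e-9)
  sw <- regionDensityTest(c(8, 9, 7), c(10, 12, 11))
  expect_equal(sw$t, -r$t, tolerance = 1e-12)
  expect_equal(sw$p, r$p, tolerance = 1e-12)
  same <- regionDensityTest(c(5, 6), c(4, 5))
  expect_true(same$undefined)
  expect_true(is.na(same$p))
})

test_that("naive fallback segmentation merges like bins", {
  bins <- data.frame(chromosome = "chr1",
                     start = seq(0, 5e6, 1e6), end = seq(1e6, 6e6, 1e6),
                     log2 = c(0.01, -0.02, 0.0, 0.9, 0.95, 0.88),
                     depth = 100)
  s <- naiveSegments(bins)
  expect_equal(nrow(s), 2L)
  expect_equal(s$n_bins, c(3L, 3L))
  expect_equal(s$end[1], 3e6)
})
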