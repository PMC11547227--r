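test_that("expectedVaf matches the admixture arithmetic", {
  # germline het in a copy-neutral region sits at 0.5 for any purity
  for (t in seq(0, 1, by = 0.1)) {
    expect_equal(expectedVaf(t, 1, 1, 2, germlineCopies = 1), 0.5)
  }
  # somatic, clonal, on a single-copy locus at t = 0.88
  expect_equal(expectedVaf(0.88, 1, 1, 1), 0.88 / (0.88 + 0.24),
               tolerance = 1e-12)
  # germline het on the retained allele of an LOH tract, t = 0.5
  expect_equal(expectedVaf(0.5, 1, 1, 1, germlineCopies = 1), 1 / 1.5,
               tolerance = 1e-12)
  # purity 0: somatic signal vanishes
  expect_equal(expectedVaf(0, 1, 1, 2), 0)
  # the TP53 double-hit point reproduces the purity formula
  for (t in c(0.25, 0.5, 0.93)) {
    expect_equal(expectedVaf(t, 1, 1, 1), vafFromPurity(t), tolerance = 1e-12)
  }
  expect_warning(v <- expectedVaf(1, 1, 0, 0), "zero denominator")
  expect_equal(v, 0)
  expect_error(expectedVaf(0.5, 1, 3, 2), "multiplicity")
})

test_that("read-count sampling respects limits and binomial mean", {
  expect_equal(sampleReadCounts(0, rep(500, 10)), rep(0L, 10))
  expect_equal(sampleReadCounts(1, rep(500, 10)), rep(500L, 10))
  set.seed(7)
  alt <- sampleReadCounts(rep(0.5, 10000), 1000, rho = 0)
  expect_true(mean(alt / 1000) > 0.49 && mean(alt / 1000) < 0.51)
  # overdispersion widens the spread but keeps the mean
  set.seed(7)
  altBb <- sampleReadCounts(rep(0.5, 10000), 1000, rho = 0.05)
  expect_gt(sd(altBb), 2 * sd(alt))
  expect_true(abs(mean(altBb / 1000) - 0.5) < 0.01)
  expect_error(sampleReadCounts(0.5, 0), "depth")
})

test_that("the simulator is deterministic and conserves its truth variants", {
  cfg <- cohortConfig(nParticipants = 2, samplesPerParticipant = 2,
                      genome = smallGenome(), nGermlineSnps = 200,
                      nLgaBoundaries = 3, meanDepth = 400)
  a <- simulateCohort(cfg, seed = 11)
  b <- simulateCohort(cfg, seed = 11)
  expect_identical(variantTables(a), variantTables(b))
  expect_identical(binTables(a), binTables(b))
  expect_identical(segmentTables(a), segmentTables(b))
  c2 <- simulateCohort(cfg, seed = 12)
  expect_false(identical(variantTables(a), variantTables(c2)))

  # conservation: each truth variant appears exactly once per sample table
  tr <- cohortTruth(a)
  for (sid in manifest(a)$sample_id) {
    tab <- variantTables(a)[[sid]]
    keys <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
    expect_setequal(keys, tr$variants[[sid]]$key)
    expect_equal(anyDuplicated(keys), 0L)
  }
})

test_that("simulated anchor VAF encodes the planted purity", {
  cfg <- cohortConfig(nParticipants = 1, samplesPerParticipant = 1,
                      genome = smallGenome(), purities = list(ASC01 = 0.5),
                      nGermlineSnps = 100, meanDepth = 5000, rho = 0)
  co <- simulateCohort(cfg, seed = 5)
  v <- variantTables(co)[[1]]
  anchor <- v[!is.na(v$gene) & v$gene == "TP53", ]
  # closed form: v = m*t*ccf / (t*cn + 2(1-t)) = 0.5/1.5 at cn 1
  expect_lt(abs(anchor$vaf - 1 / 3), 0.025)
})

test_that("bin model inverts exactly at zero noise", {
  g <- smallGenome()
  truth <- cohortTruth(simulateCohort(
    cohortConfig(nParticipants = 1, samplesPerParticipant = 1, genome = g,
                 nGermlineSnps = 10), seed = 2))$segments[[1]]
  set.seed(1)
  for (t in c(0.25, 0.6, 1)) {
    prof <- simulateBinProfile(truth, g, t, noiseSd = 0)
    cn <- cnFromLog2(prof$segments$log2, t)
    expect_equal(cn, truth$total_cn, tolerance = 1e-9)
  }
})

test_that("FFPE artefact injection inflates counts and trips the outlier flag", {
  v <- data.frame(chrom = "chr1", pos = 1:50, ref = "A", alt = "T",
                  alt_count = 50L, depth = 500L,
                  af_gnomad_exome = NA_real_, af_gnomad_genome = NA_real_,
                  af_1000g = NA_real_, gene = NA_character_,
                  effect = NA_character_, sample_id = "s1",
                  participant_id = "p1", vaf = 0.1)
  expect_identical(injectFfpeArtifacts(v, 0), v)
  set.seed(3)
  out <- injectFfpeArtifacts(v, 200, genome = smallGenome())
  expect_equal(nrow(out), 250L)
  added <- out[51:250, ]
  expect_true(all(added$vaf >= 0.005 & added$vaf <= 0.12))
  expect_true(all(added$af_gnomad_exome == 0))
  # all artefacts pass the somatic triage
  expect_true(all(isLikelySomatic(added)$somatic))

  counts <- c(s1 = 250, s2 = 52, s3 = 48, s4 = 50, s5 = 51, s6 = 49)
  expect_equal(flagVariantCountOutliers(counts), "s1")
})

test_that("infeasible configurations are rejected", {
  g <- smallGenome()
  expect_error(simulateCohort(cohortConfig(
    nParticipants = 1, genome = g, nGermlineSnps = 50,
    cloneCcfs = list(ASC01 = matrix(0.5, 3, 2))), seed = 1),
    "truncal")
  expect_error(simulateCohort(cohortConfig(
    nParticipants = 1, genome = GenomeModel(c(chr1 = 25e6)),
    nGermlineSnps = 50, nLgaBoundaries = 40), seed = 1),
    "infeasible|boundaries")
})

test_that("cohort round-trips to disk through the format readers", {
  cfg <- cohortConfig(nParticipants = 1, samplesPerParticipant = 2,
                      genome = smallGenome(), nGermlineSnps = 100,
                      meanDepth = 400)
  co <- simulateCohort(cfg, seed = 4)
  d <- tempfile()
  writeCohort(co, d)
  man <- readManifest(file.path(d, "manifest.tsv"))
  expect_equal(man$sample_id, manifest(co)$sample_id)
  sid <- man$sample_id[1]
  suppressMessages(
    v <- readVariants(file.path(d, paste0(sid, ".variants.tsv"))))
  expect_equal(nrow(v), nrow(variantTables(co)[[sid]]))
  expect_equal(readSegments(file.path(d, paste0(sid, ".cns")))$log2,
               segmentTables(co)[[sid]]$log2)
  expect_true(file.exists(file.path(d, "truth.json")))
})
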