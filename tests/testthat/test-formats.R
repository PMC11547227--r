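test_that("TSV variant reading computes VAF and drops zero-depth records", {
  f <- tmpTsv(data.frame(chrom = c("chr17", "chr1"), pos = c(7577539, 100),
                         ref = c("G", "A"), alt = c("A", "T"),
                         alt_count = c(120, 5), depth = c(400, 0)))
  expect_message(v <- readVariants(f), "zero depth")
  expect_equal(nrow(v), 1L)
  expect_equal(v$vaf, 0.30)
  expect_equal(attr(v, "n_dropped"), 1L)
})

test_that("malformed variant rows are rejected with the offending line", {
  f <- tmpTsv(data.frame(chrom = "chr1", pos = c(100, -5), ref = "A",
                         alt = "T", alt_count = 10, depth = 100))
  expect_error(readVariants(f), "line 3")
  f2 <- tmpTsv(data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "T",
                          alt_count = 150, depth = 100))
  expect_error(readVariants(f2), "malformed")
})

test_that("VCF reading extracts AD/DP, INFO AFs and annotations", {
  f <- system.file("extdata", "example_variants.vcf",
                   package = "ascitesProfiler")
  suppressMessages(v <- readVariants(f))
  tp53 <- v[v$pos == 7577539, ]
  expect_equal(tp53$vaf, 0.30)
  expect_equal(tp53$depth, 100L)
  expect_equal(tp53$gene, "TP53")
  expect_true(is.na(tp53$af_gnomad_exome))
  rare <- v[v$pos == 128750540, ]
  expect_equal(rare$af_gnomad_exome, 1e-4)
  expect_equal(attr(v, "n_dropped"), 1L)  # the 0,0:0 record
})

test_that("bin/segment tables parse the CNVkit dialect with contracts", {
  f <- tmpTsv(data.frame(chromosome = "chr8", start = 1000, end = 101000,
                         log2 = 0.58, depth = 610, weight = 0.9), ".cnr")
  b <- readBins(f)
  expect_equal(b$end - b$start, 100000)
  expect_equal(b$log2, 0.58)

  unsorted <- data.frame(chromosome = "chr1", start = c(5000, 0),
                         end = c(6000, 1000), log2 = c(0.1, 0.2))
  expect_warning(s <- readBins(tmpTsv(unsorted, ".cnr")), "not sorted")
  expect_equal(s$start, c(0, 5000))

  overlapping <- data.frame(chromosome = "chr1", start = c(0, 5),
                            end = c(10, 20), log2 = 0)
  expect_error(readSegments(tmpTsv(overlapping, ".cns")), "overlap")

  badrow <- data.frame(chromosome = "chr1", start = 10, end = 10, log2 = 0)
  expect_error(readBins(tmpTsv(badrow, ".cnr")), "start < end")
})

test_that("tables round-trip through write/read at full precision", {
  set.seed(42)
  v <- data.frame(chrom = "chr2", pos = c(11, 999983), ref = c("A", "C"),
                  alt = c("G", "T"), alt_count = c(13L, 977L),
                  depth = c(400L, 1531L),
                  af_gnomad_exome = c(NA, 1 / 3), af_gnomad_genome = c(NA, 0.25),
                  af_1000g = c(NA, 0.125), gene = c("TP53", NA),
                  effect = c("deleterious", NA), sample_id = "s1",
                  participant_id = "p1")
  v$vaf <- v$alt_count / v$depth
  f <- tempfile()
  writeVariants(v, f)
  v2 <- readVariants(f)
  expect_equal(v2$vaf, v$vaf)
  expect_equal(v2$af_gnomad_exome, v$af_gnomad_exome)
  expect_equal(v2$pos, v$pos)

  seg <- data.frame(chromosome = c("chr1", "chr1"), start = c(0, 2e7),
                    end = c(2e7, 81e6), log2 = rnorm(2), n_bins = c(200L, 610L),
                    mean_depth = runif(2, 100, 1000))
  f2 <- tempfile()
  writeSegments(seg, f2)
  expect_equal(readSegments(f2)$log2, seg$log2)

  m <- data.frame(participant_id = "p1", sample_id = c("a", "b"),
                  specimen = "cfDNA", timepoint_days = c(0L, 132L),
                  purity_hint = c(NA, 0.5))
  f3 <- tempfile()
  writeManifest(m, f3)
  expect_equal(readManifest(f3)$purity_hint, m$purity_hint)
})

test_that("manifest validation enforces its invariants", {
  base <- data.frame(participant_id = "p1", sample_id = c("a", "b"),
                     specimen = "cfDNA", timepoint_days = c(0, 10))
  expect_silent(validateManifest(base))
  dup <- base; dup$sample_id <- "a"
  expect_error(validateManifest(dup), "unique")
  bad <- base; bad$specimen <- "plasma"
  expect_error(validateManifest(bad), "specimen")
  neg <- base; neg$timepoint_days <- c(-1, 0)
  expect_error(validateManifest(neg), "timepoint")
})

test_that("coordinate conventions are centralized and consistent", {
  # segments are 0-based half-open [0, 10); variants 1-based inclusive 1..10
  seg <- data.frame(chromosome = "chr1", start = c(0, 10), end = c(10, 20),
                    cn_int = c(1L, 2L))
  expect_equal(segmentCnAtPositions(seg, rep("chr1", 3), c(1, 10, 11)),
               c(1L, 1L, 2L))
  g <- GenomeModel(c(chr1 = 250001), binSize = 1e5)
  b <- genomeBins(g)
  expect_equal(nrow(b), 3L)          # chromosome-limited: last bin truncated
  expect_equal(b$end[3], 250001)
  expect_equal(b$start, c(0, 1e5, 2e5))
})

test_that("clonal export writes one diploid-normal row per variant x sample", {
  v <- expand.grid(pos = c(100, 5e6, 15e6), sample_id = c("s1", "s2"),
                   stringsAsFactors = FALSE)
  v$chrom <- "chr1"
  v$ref <- "A"
  v$alt <- "T"
  v$alt_count <- 30L
  v$depth <- 100L
  segs <- list(
    s1 = data.frame(chromosome = "chr1", start = 0, end = 60e6, cn_int = 3L),
    s2 = data.frame(chromosome = "chr1", start = 0, end = 60e6, cn_int = 1L)
  )
  pur <- data.frame(sample_id = c("s1", "s2"), t = c(0.8, 0.5))
  f <- tempfile()
  out <- writePycloneInput(v, pur, segs, f)
  expect_equal(nrow(out), 6L)
  expect_true(all(out$normal_cn == 2L))
  expect_true(all(out$ref_counts == 70L))
  # unphased approximation: major = max(cn-1, 1), minor = cn - major
  expect_equal(unique(out$major_cn[out$sample_id == "s1"]), 2L)
  expect_equal(unique(out$minor_cn[out$sample_id == "s1"]), 1L)
  expect_equal(unique(out$major_cn[out$sample_id == "s2"]), 1L)
  expect_equal(unique(out$minor_cn[out$sample_id == "s2"]), 0L)
  expect_equal(out$tumour_content[out$sample_id == "s2"][1], 0.5)

  expect_error(writePycloneInput(v, pur[1, ], segs, f), "missing purity")
  segs$s2$cn_int <- 0L
  expect_error(writePycloneInput(v, pur, segs, f), "copy-number-0")
})
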