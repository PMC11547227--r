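# Independent brute-force oracles and small fixture builders shared across
# test files. These deliberately re-derive results from first principles,
# without calling the implementation paths they check.

smallGenome <- function(binSize = 1e5) {
  GenomeModel(c(chr1 = 60e6, chr8 = 146e6, chr17 = 81e6), binSize = binSize)
}

# build a one-sample segment table from (chrom, length-Mb, cn) triples,
# laid end to end per chromosome
makeSegs <- function(chrom, lenMb, cn, depth = 100) {
  df <- do.call(rbind, lapply(unique(chrom), function(ch) {
    i <- chrom == ch
    ends <- cumsum(lenMb[i]) * 1e6
    data.frame(chromosome = ch, start = c(0, ends[-length(ends)]),
               end = ends, cn_int = as.integer(cn[i]),
               cn_est = as.numeric(cn[i]),
               mean_depth = rep_len(depth, sum(i)),
               stringsAsFactors = FALSE)
  }))
  df$log2 <- log2(pmax(df$cn_est, 0.01) / 2)
  rownames(df) <- NULL
  df
}

# brute-force LGA enumeration: literal restatement of the rule
bruteLga <- function(segments, minLen = 1e7) {
  total <- 0L
  for (ch in unique(segments$chromosome)) {
    s <- segments[segments$chromosome == ch, ]
    s <- s[order(s$start), ]
    q <- s[(s$end - s$start) > minLen, ]
    if (nrow(q) >= 2L) {
      for (i in 2:nrow(q)) {
        if (q$cn_int[i] != q$cn_int[i - 1L]) total <- total + 1L
      }
    }
  }
  total
}

randomSegLayout <- function(rng_n = 12) {
  n <- sample(2:rng_n, 1)
  lens <- sample(c(2e6, 5e6, 9e6, 1e7, 1.05e7, 2e7, 4e7), n, replace = TRUE)
  chrom <- sort(sample(paste0("chr", 1:3), n, replace = TRUE))
  makeSegs(chrom, lens / 1e6, sample(0:4, n, replace = TRUE))
}

# brute-force total-variant-count outlier rule
bruteOutliers <- function(counts, z = 3) {
  dev <- abs(counts - median(counts))
  worst <- which(dev == max(dev))
  if (length(worst) > 1) worst <- worst[which.max(counts[worst])]
  rest <- counts[-worst]
  mu <- mean(rest)
  s <- sd(rest)
  if (s == 0) return(names(counts)[counts != mu])
  names(counts)[abs((counts - mu) / s) > z]
}

# brute-force genomic-instability consensus
bruteGi <- function(m) {
  init <- if ("initial" %in% names(m)) m$initial else rep(TRUE, nrow(m))
  medLga <- median(m$lga[init])
  medLoh <- median(m$loh_percent[init & m$loh_reliable])
  medTmb <- median(m$tmb[init])
  (m$lga > medLga) +
    (m$loh_reliable & m$loh_percent > medLoh) +
    (m$tmb > medTmb)
}

# write a throwaway TSV and return its path
tmpTsv <- function(df, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
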