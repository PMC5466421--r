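test_that("signal regions are centered on peak midpoints and clamped", {
  peak <- bedToGRanges(data.frame(chrom = "chr1", start = 10000, end = 10400))
  r <- buildSignalRegions(peak, 1000L)
  expect_equal(start(r), 9201L)   # bed [9200, 11200)
  expect_equal(end(r), 11200L)

  edge <- bedToGRanges(data.frame(chrom = "chr1", start = 0, end = 100))
  rEdge <- buildSignalRegions(edge, 1000L)
  expect_equal(start(rEdge), 1L)  # clamped at the chromosome start
  expect_equal(end(rEdge), 1050L)

  many <- bedToGRanges(randomIntervals(162, maxPos = 50000))
  expect_length(buildSignalRegions(many), 162)
})

test_that("control regions sit 4-6 kb out and avoid peaks and the origin", {
  peak <- bedToGRanges(data.frame(chrom = "chr1", start = 10000, end = 11000))
  ctrl <- buildControlRegions(peak)
  expect_length(ctrl, 2)
  expect_equal(start(ctrl), c(4001L, 15001L))  # bed [4000,6000) and [15000,17000)
  expect_equal(end(ctrl), c(6000L, 17000L))

  # two peaks 5 kb apart: the two inter-peak controls reach into a neighbor
  pair <- bedToGRanges(data.frame(chrom = "chr1",
                                  start = c(20000, 26000),
                                  end = c(21000, 27000)))
  ctrlPair <- buildControlRegions(pair)
  expect_length(ctrlPair, 2)  # only the two outermost controls survive
  expect_true(all(countOverlaps(ctrlPair, pair) == 0))

  # a peak close to the origin loses its left control
  nearStart <- bedToGRanges(data.frame(chrom = "chr1", start = 3000, end = 3400))
  expect_length(buildControlRegions(nearStart), 1)

  # isolated peaks: exactly 2n controls
  iso <- bedToGRanges(data.frame(chrom = "chr1",
                                 start = seq(50000, by = 20000, length.out = 5),
                                 end = seq(50400, by = 20000, length.out = 5)))
  expect_length(buildControlRegions(iso), 10)
})

test_that("log2 RPM follows its closed form and scaling law", {
  region <- bedToGRanges(data.frame(chrom = "chr1", start = 1000, end = 2000))
  expect_equal(regionRpm(GRanges(), region, totalReads = 1e6), 0)
  reads <- GRanges("chr1", IRanges(rep(1500, 49), width = 30))
  expect_equal(regionRpm(reads, region, totalReads = 1e6), log2(50))
  v1 <- regionRpm(reads, region, totalReads = 1e6)
  v2 <- regionRpm(reads, region, totalReads = 2e6)
  expect_equal(v1 - v2, 1)
  expect_error(regionRpm(reads, region, totalReads = 0), "positive")
})

test_that("control centering uses the lower median and is translation invariant", {
  res <- normalizeDeltas(c(1, 2), c(-1, 0.5, 2))
  expect_equal(res$shift, 0.5)
  expect_equal(res$controlDeltas, c(-1.5, 0, 1.5))
  expect_equal(sum(res$controlDeltas > 0), 1)
  expect_equal(sum(res$controlDeltas < 0), 1)

  sym <- normalizeDeltas(c(3), c(-2, -1, 1, 2))
  expect_equal(sym$shift, -1)  # lower median for an even count

  a <- normalizeDeltas(c(1, 2, 3), c(-1, 0, 2, 5))
  b <- normalizeDeltas(c(1, 2, 3) + 10, c(-1, 0, 2, 5) + 10)
  expect_equal(a$deltas, b$deltas)
  expect_error(normalizeDeltas(1, numeric()), "non-empty")
})

test_that("direction statistics match exact big-integer arithmetic", {
  # exhaustive-arithmetic oracle on the headline case and random ones
  cases <- rbind(c(162, 135), c(162, 88), c(162, 103), c(2, 2), c(10, 5))
  set.seed(19)
  cases <- rbind(cases, cbind(n <- sample(3:200, 10),
                              vapply(n, function(x) sample(0:x, 1), 1L)))
  for (i in seq_len(nrow(cases))) {
    n <- cases[i, 1]; k <- cases[i, 2]
    expect_equal(dbinom(k, n, 0.5), bigBinomHalfPointMass(k, n),
                 tolerance = 1e-12, label = sprintf("n=%d k=%d", n, k))
  }
  ds <- directionStats(c(rep(1, 2)))
  expect_equal(ds$pUp, 0.25)
  expect_equal(ds$tailUp, 0.25)
  dsz <- directionStats(c(1, -1, 0))
  expect_equal(dsz$kUp + dsz$kDown, 2)  # zeros excluded from both counts
  expect_equal(dsz$n, 3)
})

test_that("a planted coverage increase is detected end to end", {
  sizes <- c(chr1 = 200000L)
  starts <- seq(20000, by = 15000, length.out = 12)
  peaks <- bedToGRanges(data.frame(chrom = "chr1", start = starts,
                                   end = starts + 400))
  names(peaks) <- sprintf("pk%02d", seq_along(peaks))
  regions <- buildSignalRegions(peaks)
  effect <- rep(c(TRUE, FALSE), c(10, 2))
  hits <- 0L
  for (seed in 1:5) {
    rd <- generateHistoneReads(regions, effect, seed, depth = 50, fold = 4,
                               genomeSizes = sizes)
    hd <- histoneDynamics(peaks, rd$t0, rd$t48)
    if (hd$stats$fracUp >= 0.75) hits <- hits + 1L
  }
  expect_gte(hits, 4)
})

test_that("without a planted effect the up fraction is near one half", {
  sizes <- c(chr1 = 200000L)
  starts <- seq(20000, by = 15000, length.out = 12)
  peaks <- bedToGRanges(data.frame(chrom = "chr1", start = starts,
                                   end = starts + 400))
  names(peaks) <- sprintf("pk%02d", seq_along(peaks))
  regions <- buildSignalRegions(peaks)
  kUp <- 0L; nTot <- 0L
  for (seed in 1:10) {
    rd <- generateHistoneReads(regions, rep(FALSE, 12), seed + 100,
                               depth = 50, fold = 1, genomeSizes = sizes)
    hd <- histoneDynamics(peaks, rd$t0, rd$t48)
    kUp <- kUp + hd$stats$kUp
    nTot <- nTot + hd$stats$n
  }
  expect_lt(abs(kUp / nTot - 0.5), 3 * sqrt(0.25 / nTot) + 0.05)
})

test_that("binned coverage matrices have the region x bin shape", {
  peaks <- bedToGRanges(data.frame(chrom = "chr1", start = c(1000, 5000),
                                   end = c(2000, 6000)))
  names(peaks) <- c("a", "b")
  reads <- GRanges("chr1", IRanges(c(1100, 1200, 5500), width = 50))
  m <- binnedCoverageMatrix(reads, peaks, nBins = 10)
  expect_equal(dim(m), c(2L, 10L))
  expect_equal(sum(m["a", ]) >= 2, TRUE)
})
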