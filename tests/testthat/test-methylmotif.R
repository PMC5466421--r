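test_that("methylated k-mer extraction windows cover the methylated CpG", {
  genome <- DNAStringSet(c(chr1 = "ACCCGCCT"))
  peak <- bedToGRanges(data.frame(chrom = "chr1", start = 0, end = 8))
  names(peak) <- "p1"
  # CpG at plus positions 4-5; plus-strand C methylated
  hi <- makeCpgs("chr1", 4, "+", 9, 1)
  got <- extractMethylatedKmers(peak, genome, hi, k = 6, betaMin = 0.6)
  expect_setequal(got[["p1"]], c("ACCCGC", "CCCGCC", "CCGCCT"))

  lo <- makeCpgs("chr1", 4, "+", 3, 7)  # beta 0.3
  expect_length(extractMethylatedKmers(peak, genome, lo)[["p1"]], 0)

  atBoundary <- makeCpgs("chr1", 4, "+", 3, 2)  # beta 0.6 exactly: excluded
  expect_length(extractMethylatedKmers(peak, genome, atBoundary)[["p1"]], 0)
})

test_that("minus-strand methylation yields reverse-complemented k-mers", {
  genome <- DNAStringSet(c(chr1 = "ACCCGCCT"))
  peak <- bedToGRanges(data.frame(chrom = "chr1", start = 0, end = 8))
  names(peak) <- "p1"
  # the G-paired cytosine on the minus strand at plus position 5
  minus <- makeCpgs("chr1", 5, "-", 9, 1)
  got <- extractMethylatedKmers(peak, genome, minus)[["p1"]]
  want <- as.character(reverseComplement(DNAStringSet(
    c("ACCCGC", "CCCGCC", "CCGCCT"))))
  expect_setequal(got, want)

  outOfBounds <- bedToGRanges(data.frame(chrom = "chr1", start = 0, end = 50))
  expect_error(extractMethylatedKmers(outOfBounds, genome, minus),
               "beyond chromosome end")
})

test_that("k-mer presence is per-peak binary", {
  genome <- DNAStringSet(c(chr1 = paste0("AAACGAAACGAAA")))
  peak <- bedToGRanges(data.frame(chrom = "chr1", start = 0, end = 13))
  names(peak) <- "p1"
  cpgs <- makeCpgs("chr1", c(4, 9), "+", c(9, 9), c(1, 1))
  got <- extractMethylatedKmers(peak, genome, cpgs, k = 5)[["p1"]]
  expect_equal(anyDuplicated(got), 0L)
  expect_true("AAACG" %in% got)  # present at both CpGs, recorded once
})

test_that("k-mer enrichment p-values match the hypergeometric model", {
  # N=20 peaks, K=8 carry the k-mer, n=10 foreground, all 8 in foreground
  allK <- c(rep(list("AACGTT"), 8), rep(list(character()), 12))
  names(allK) <- sprintf("pk%02d", 1:20)
  fgK <- allK[1:10]
  res <- kmerEnrichment(fgK, allK)
  row <- res$stats[res$stats$kmer == "AACGTT", ]
  expect_equal(row$fgPeaks, 8L)
  expect_equal(row$bgPeaks, 8L)
  expect_equal(row$p, 66 / 184756, tolerance = 1e-12)
  expect_equal(row$p, bruteHyperUpper(8, 8, 10, 20), tolerance = 1e-12)
  expect_equal(row$pBonferroni, min(1, row$p * nrow(res$stats)))

  # foreground == all peaks: no enrichment possible
  degenerate <- kmerEnrichment(allK, allK)
  expect_true(all(degenerate$stats$p == 1))

  expect_error(kmerEnrichment(list(extra = "AACGTT"), allK), "subset")
})

test_that("hypergeometric tail equals brute-force summation for N <= 60", {
  set.seed(13)
  for (rep in 1:200) {
    N <- sample(2:60, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    want <- bruteHyperUpper(k, K, n, N)
    got <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(got, want, tolerance = 1e-10,
                 label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
  }
})

test_that("enrichment p never increases with the foreground count", {
  N <- 50; K <- 20; n <- 25
  p <- phyper(0:K - 1, K, N - K, n, lower.tail = FALSE)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("PWM construction aligns k-mers at their CpG", {
  single <- buildPwm("CCCGCC")
  expect_equal(pwmConsensus(single), "CCCGCC")
  expect_equal(unname(pwmMatrix(single)["C", 1]), 1)

  pwm <- buildPwm(c("CCCGCC", "ACCGCC"), weights = c(2, 1))
  expect_equal(unname(pwmMatrix(pwm)["C", 1]), 2 / 3)
  expect_equal(unname(pwmMatrix(pwm)["A", 1]), 1 / 3)
  expect_equal(ncol(pwmMatrix(pwm)), 6)

  # different CpG offsets widen the matrix: offsets 3 and 1 -> width 8
  shifted <- buildPwm(c("CCCGCC", "CGAAAA"), weights = c(1, 1))
  expect_equal(ncol(pwmMatrix(shifted)), 8)

  expect_error(buildPwm("AAATTT"), "must contain CG")
  expect_error(buildPwm(character()), "at least one")
})

test_that("information content is 2 bits one-hot, 0 uniform, 1 at half-half", {
  onehot <- buildPwm("CCCGCC")
  expect_equal(pwmInformationContent(onehot), rep(2, 6))
  uniform <- new("MotifPwm",
                 profile = matrix(0.25, 4, 3,
                                  dimnames = list(c("A", "C", "G", "T"), NULL)),
                 support = 1)
  expect_equal(pwmInformationContent(uniform), rep(0, 3))
  half <- new("MotifPwm",
              profile = matrix(c(0.5, 0.5, 0, 0), 4, 1,
                               dimnames = list(c("A", "C", "G", "T"), NULL)),
              support = 1)
  expect_equal(pwmInformationContent(half), 1)
})

test_that("planted methylated motif is recovered from synthetic peaks", {
  genome <- generateGenome(401, nChroms = 1, chromLength = 120000)
  pm <- generatePeaksAndMethylome(genome, 402, nWtSpecific = 25L,
                                  nShared = 12L, nMutSpecific = 3L)
  allPeaks <- c(pm$wtPeaks, pm$mutPeaks[grepl("^mut_specific",
                                              names(pm$mutPeaks))])
  allK <- extractMethylatedKmers(allPeaks, pm$genome, pm$cpgs)
  fgK <- allK[pm$truth$wtSpecificNames]
  res <- kmerEnrichment(fgK, allK)
  expect_equal(res$stats$kmer[1], "CCCGCC")
  expect_true("CCCGCC" %in% res$selected)
  pwm <- buildPwm(res$stats$kmer[res$stats$kmer %in% res$selected],
                  res$stats$fgPeaks[res$stats$kmer %in% res$selected])
  expect_true(grepl("CCCGCC", pwmConsensus(pwm), fixed = TRUE) ||
              grepl("GGCGGG", pwmConsensus(pwm), fixed = TRUE))
})
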