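suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

## --- independent oracles, deliberately naive ------------------------------

# All-pairs interval overlap on the half-open convention (0-based bed-style
# triples): same chrom and a.start < b.end and b.start < a.end.
bruteOverlapPairs <- function(a, b) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(pairs)) return(matrix(integer(), ncol = 2))
  m <- do.call(rbind, pairs)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Hypergeometric upper tail P(X >= k) by explicit support summation.
bruteHyperUpper <- function(k, K, n, N) {
  xs <- max(k, 0):min(K, n)
  if (!length(xs) || k > min(K, n)) return(0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Two-sided Fisher exact p on a 2x2 table by enumerating the support and
# summing probabilities no larger than the observed one.
bruteFisherTwoSided <- function(a, b, c, d) {
  rowTot <- a + b
  K <- a + c; N <- a + b + c + d; n <- rowTot
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  pObs <- probs[xs == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

## --- tiny big-integer arithmetic (base 1e4 digit vectors) -----------------
## An exact-arithmetic route to binomial point masses, independent of dbinom.

bigFromInt <- function(x) {
  out <- integer()
  while (x > 0) { out <- c(out, x %% 10000L); x <- x %/% 10000L }
  if (!length(out)) 0L else out
}

bigMulSmall <- function(big, m) {
  carry <- 0
  out <- integer(length(big))
  for (i in seq_along(big)) {
    v <- big[i] * m + carry
    out[i] <- v %% 10000
    carry <- v %/% 10000
  }
  while (carry > 0) { out <- c(out, carry %% 10000); carry <- carry %/% 10000 }
  out
}

# exponent of prime p in n! (Legendre)
legendreExp <- function(n, p) {
  e <- 0L; q <- p
  while (q <= n) { e <- e + n %/% q; q <- q * p }
  e
}

primesUpTo <- function(n) {
  if (n < 2) return(integer())
  is <- rep(TRUE, n); is[1] <- FALSE
  if (n >= 4) {
    for (i in 2:floor(sqrt(n))) if (is[i]) is[seq(i * i, n, by = i)] <- FALSE
  }
  which(is)
}

# C(n, k) as an exact big integer via prime factorization of factorials.
bigChoose <- function(n, k) {
  big <- bigFromInt(1L)
  for (p in primesUpTo(n)) {
    e <- legendreExp(n, p) - legendreExp(k, p) - legendreExp(n - k, p)
    for (j in seq_len(e)) big <- bigMulSmall(big, p)
  }
  big
}

bigToNumeric <- function(big) sum(big * 10000^(seq_along(big) - 1))

# Exact-arithmetic Binomial(n, 1/2) point mass, as numeric.
bigBinomHalfPointMass <- function(k, n) bigToNumeric(bigChoose(n, k)) / 2^n

## --- fixture builders -----------------------------------------------------

randomIntervals <- function(n, chroms = c("chr1", "chr2"), maxPos = 10000L,
                            maxWidth = 300L) {
  start <- sample.int(maxPos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(maxWidth, n, replace = TRUE))
}

bedToGRanges <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

makeCpgs <- function(chrom, pos, strand, nMeth, nUnmeth) {
  gr <- GRanges(chrom, IRanges(pos, pos), strand = strand)
  mcols(gr)$nMeth <- as.integer(nMeth)
  mcols(gr)$nUnmeth <- as.integer(nUnmeth)
  gr
}

writeTempBed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}
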