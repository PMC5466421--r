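#' @importFrom stats fisher.test
NULL

#' Per-CpG methylation level (beta value)
#'
#' beta = methylated reads / (methylated + unmethylated reads). Vectorized;
#' zero-coverage sites are an error because beta is undefined there —
#' callers must filter first.
#'
#' @param nMeth,nUnmeth non-negative integer read counts.
#' @return numeric vector of beta values in \[0, 1\].
#' @examples
#' computeBeta(3, 1)  # 0.75
#' @export
computeBeta <- function(nMeth, nUnmeth) {
  if (any(nMeth < 0) || any(nUnmeth < 0)) stop("read counts must be non-negative")
  cov <- nMeth + nUnmeth
  if (any(cov == 0)) stop("beta is undefined at zero coverage; filter such sites first")
  nMeth / cov
}

#' Summarize CpG methylation within regions
#'
#' For each region, computes the mean beta over the CpG sites it contains
#' with coverage at least `minCoverage`, and flags the region as highly
#' methylated when the summary exceeds `betaThreshold`. Regions without an
#' eligible CpG get `nCpg = 0`, `meanBeta = NA` and `high = FALSE`.
#'
#' @param regions `GRanges` of regions (e.g. ChIP peaks).
#' @param cpgs `GRanges` of CpG sites as returned by [readCytosineReport()].
#' @param minCoverage minimum read coverage for a CpG to count (default 1,
#'   i.e. every covered site).
#' @param betaThreshold high-methylation cutoff on the summary (default 0.6;
#'   strict `>`).
#' @param summary `"mean"` flags regions by mean beta (the conventional
#'   region summary); `"any"` flags regions containing any single CpG with
#'   beta above the threshold.
#' @return `regions` with added metadata columns `nCpg`, `meanBeta`, `high`.
#' @export
regionMethylation <- function(regions, cpgs, minCoverage = 1L,
                              betaThreshold = 0.6,
                              summary = c("mean", "any")) {
  summary <- match.arg(summary)
  if (betaThreshold <= 0 || betaThreshold >= 1)
    stop("betaThreshold must be in (0, 1)")
  if (minCoverage < 1L) stop("minCoverage must be >= 1")
  cov <- mcols(cpgs)$nMeth + mcols(cpgs)$nUnmeth
  eligible <- cpgs[cov >= minCoverage]
  beta <- computeBeta(mcols(eligible)$nMeth, mcols(eligible)$nUnmeth)
  hits <- findOverlaps(regions, eligible, ignore.strand = TRUE)
  nCpg <- integer(length(regions))
  meanBeta <- rep(NA_real_, length(regions))
  high <- logical(length(regions))
  if (length(hits)) {
    bySite <- split(beta[subjectHits(hits)], queryHits(hits))
    idx <- as.integer(names(bySite))
    nCpg[idx] <- lengths(bySite)
    meanBeta[idx] <- vapply(bySite, mean, numeric(1))
    high[idx] <- if (summary == "mean") {
      meanBeta[idx] > betaThreshold
    } else {
      vapply(bySite, function(b) any(b > betaThreshold), logical(1))
    }
  }
  out <- regions
  mcols(out)$nCpg <- nCpg
  mcols(out)$meanBeta <- meanBeta
  mcols(out)$high <- high
  out
}

#' Fraction of regions with high methylation
#'
#' The denominator is the number of regions containing at least one eligible
#' CpG; regions without CpG information are not evidence either way.
#'
#' @param regionMeth output of [regionMethylation()].
#' @return fraction in \[0, 1\].
#' @export
highMethylationFraction <- function(regionMeth) {
  if (!length(regionMeth)) stop("empty region list")
  withCpg <- mcols(regionMeth)$nCpg > 0L
  if (!any(withCpg)) stop("no region contains an eligible CpG")
  sum(mcols(regionMeth)$high[withCpg]) / sum(withCpg)
}

#' Compare two high-methylation fractions by Fisher's exact test
#'
#' Two-sided exact test on the 2x2 table (high vs not-high in set A vs set
#' B), for contrasts such as WT-specific versus shared peak methylation.
#'
#' @param countHighA,nA high count and total for the first set.
#' @param countHighB,nB high count and total for the second set.
#' @return list with `fractionA`, `fractionB` and the two-sided `p`.
#' @export
compareMethylationFractions <- function(countHighA, nA, countHighB, nB) {
  if (nA <= 0 || nB <= 0) stop("totals must be positive")
  if (countHighA > nA || countHighB > nB) stop("counts cannot exceed totals")
  tab <- matrix(c(countHighA, nA - countHighA,
                  countHighB, nB - countHighB), nrow = 2)
  list(fractionA = countHighA / nA,
       fractionB = countHighB / nB,
       p = fisher.test(tab, alternative = "two.sided")$p.value)
}

#' Read a bisulfite-clone matrix (0/1 grid, one clone per row)
#'
#' @param path tab-separated grid of 0 (unmethylated) / 1 (methylated);
#'   an optional header row of CpG site labels is detected automatically.
#' @return integer matrix, clones x CpG sites.
#' @export
readCloneMatrix <- function(path) {
  fields <- .splitTabLines(path)
  if (!length(fields)) stop("empty clone matrix file")
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L)
    stop("ragged clone matrix: rows have differing CpG column counts")
  labels <- NULL
  first <- suppressWarnings(as.integer(fields[[1]]))
  if (anyNA(first)) {
    labels <- fields[[1]]
    fields <- fields[-1]
    if (!length(fields)) stop("clone matrix has a header but no clones")
  }
  m <- do.call(rbind, lapply(fields, function(f) {
    v <- suppressWarnings(as.integer(f))
    if (anyNA(v) || any(!(v %in% c(0L, 1L))))
      stop("clone matrix entries must be 0 or 1")
    v
  }))
  if (!is.null(labels)) colnames(m) <- labels
  m
}

#' Per-site percent methylation from a clone matrix
#'
#' Each row is one sequenced clone, each column one CpG site; a 1 marks a
#' methylated call. Returns 100 * (methylated clones) / (clones) per site.
#'
#' @param cloneMatrix binary matrix (or coercible), clones x CpG sites.
#' @return numeric vector of percentages, one per CpG column.
#' @examples
#' cloneMatrixMethylation(matrix(1, nrow = 7, ncol = 4))  # 100 100 100 100
#' @export
cloneMatrixMethylation <- function(cloneMatrix) {
  m <- as.matrix(cloneMatrix)
  if (nrow(m) < 1L) stop("need at least one clone")
  if (any(!(m %in% c(0, 1)))) stop("clone matrix entries must be 0 or 1")
  100 * colSums(m) / nrow(m)
}

#' Write a region methylation summary as TSV
#'
#' @param regionMeth output of [regionMethylation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionMethylation <- function(regionMeth, path) {
  df <- data.frame(
    chrom = as.character(seqnames(regionMeth)),
    start = start(regionMeth) - 1L,
    end = end(regionMeth),
    name = if (!is.null(names(regionMeth))) names(regionMeth)
           else sprintf("region_%d", seq_along(regionMeth)),
    n_cpg = mcols(regionMeth)$nCpg,
    mean_beta = mcols(regionMeth)$meanBeta,
    high = mcols(regionMeth)$high)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
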