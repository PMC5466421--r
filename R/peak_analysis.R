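#' @importFrom stats ppois
NULL

#' Poisson sliding-window peak caller
#'
#' A deliberately simple, reproducible enrichment caller for desk-scale
#' data: the genome is tiled in non-overlapping windows of `windowBp`; the
#' read count of each window is tested against a global
#' Poisson(lambda = totalReads * windowBp / genomeLength) null, and windows
#' with upper-tail p below `pCutoff` are merged into peaks. Windows
#' separated by at most one non-significant window are joined, to avoid
#' fragmenting single binding events. The peak score is the best
#' constituent window's -log10(p).
#'
#' This is not a re-implementation of MACS: there is no local lambda,
#' duplicate handling or shift estimation.
#'
#' @param reads `GRanges` of mapped read intervals (strand ignored).
#' @param genomeSizes named integer vector of chromosome lengths (bp).
#' @param windowBp window size in bp (>= 50).
#' @param pCutoff Poisson upper-tail p-value cutoff (default 1e-5, a
#'   conventional stringent threshold for point-source peaks).
#' @return `GRanges` of peaks with `name` and `score` (-log10 p) columns.
#' @export
callPeaksPoisson <- function(reads, genomeSizes, windowBp = 200L,
                             pCutoff = 1e-5) {
  if (length(reads) == 0L) stop("no reads")
  if (windowBp < 50L) stop("windowBp must be >= 50")
  if (is.null(names(genomeSizes)) || any(!nzchar(names(genomeSizes))))
    stop("genomeSizes must be a named vector of chromosome lengths")
  genomeLength <- sum(as.numeric(genomeSizes))
  lambda <- length(reads) * windowBp / genomeLength
  peakList <- list()
  for (chrom in names(genomeSizes)) {
    len <- genomeSizes[[chrom]]
    starts0 <- seq.int(0L, len - 1L, by = windowBp)
    ends0 <- pmin(starts0 + windowBp, len)
    win <- GRanges(chrom, IRanges(starts0 + 1L, ends0))
    cnt <- countOverlaps(win, reads, ignore.strand = TRUE)
    p <- ppois(cnt - 1L, lambda, lower.tail = FALSE)
    sig <- which(p < pCutoff)
    if (!length(sig)) next
    sigWin <- win[sig]
    mcols(sigWin)$mlogp <- -log10(p[sig])
    # merge significant windows separated by <= 1 window gap
    merged <- reduce(sigWin, min.gapwidth = windowBp + 1L,
                     ignore.strand = TRUE)
    ov <- findOverlaps(merged, sigWin)
    score <- vapply(split(mcols(sigWin)$mlogp[subjectHits(ov)],
                          queryHits(ov)), max, numeric(1))
    mcols(merged)$score <- as.numeric(score)
    peakList[[chrom]] <- merged
  }
  if (!length(peakList)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(name = character(), score = numeric())
    return(gr)
  }
  peaks <- suppressWarnings(do.call(c, unname(peakList)))
  nm <- sprintf("peak_%d", seq_along(peaks))
  names(peaks) <- nm
  mcols(peaks)$name <- nm
  mcols(peaks) <- mcols(peaks)[, c("name", "score")]
  peaks
}

.ensureNames <- function(gr, prefix) {
  if (is.null(names(gr)) || any(!nzchar(names(gr)))) {
    nm <- sprintf("%s_%d", prefix, seq_along(gr))
    names(gr) <- nm
    mcols(gr)$name <- nm
  }
  gr
}

#' Classify WT and mutant peaks into shared and condition-specific sets
#'
#' A WT peak overlapping at least `minOverlap` bp of any mutant peak is
#' *shared*; WT peaks with no mutant overlap are *WT-specific*; mutant peaks
#' with no WT overlap are *mutant-specific*. "Same locus" is any >= 1 bp
#' overlap by default.
#'
#' @param wtPeaks,mutPeaks `GRanges` of peaks (named, or names are generated).
#' @param minOverlap minimum overlap in bp that makes two peaks the same
#'   locus (default 1).
#' @return a [PeakClassification-class].
#' @examples
#' wt <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 501), c(200, 600)))
#' mut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(151, 801), c(250, 900)))
#' classifyPeaks(wt, mut)
#' @export
classifyPeaks <- function(wtPeaks, mutPeaks, minOverlap = 1L) {
  wtPeaks <- .ensureNames(wtPeaks, "wt")
  mutPeaks <- .ensureNames(mutPeaks, "mut")
  wtHit <- countOverlaps(wtPeaks, mutPeaks, minoverlap = minOverlap,
                         ignore.strand = TRUE) > 0L
  mutHit <- countOverlaps(mutPeaks, wtPeaks, minoverlap = minOverlap,
                          ignore.strand = TRUE) > 0L
  new("PeakClassification",
      shared = wtPeaks[wtHit],
      wtSpecific = wtPeaks[!wtHit],
      mutSpecific = mutPeaks[!mutHit])
}

#' Peak turnover between two time points
#'
#' Novel peaks are late-time-point peaks with no early overlap; lost peaks
#' are early peaks with no late overlap. Novel peaks are additionally
#' counted near a set of anchor peaks extended by `flankBp` on each side
#' (used for novel histone-acetylation peaks flanking TF binding sites).
#'
#' @param peaksT0,peaksT48 `GRanges` of peaks at the two time points.
#' @param anchorPeaks `GRanges` of anchor peaks (e.g. TF ChIP peaks).
#' @param flankBp flank added to each side of every anchor (bp, >= 0).
#' @return list with `novel` and `lost` (`GRanges`) and the integer
#'   `novelNearAnchor`.
#' @export
peakTurnover <- function(peaksT0, peaksT48, anchorPeaks = GRanges(),
                         flankBp = 0L) {
  if (flankBp < 0L) stop("flankBp must be >= 0")
  novel <- peaksT48[countOverlaps(peaksT48, peaksT0,
                                  ignore.strand = TRUE) == 0L]
  lost <- peaksT0[countOverlaps(peaksT0, peaksT48,
                                ignore.strand = TRUE) == 0L]
  nNear <- 0L
  if (length(anchorPeaks) && length(novel)) {
    ext <- GRanges(seqnames(anchorPeaks),
                   IRanges(pmax(start(anchorPeaks) - flankBp, 1L),
                           end(anchorPeaks) + flankBp))
    nNear <- sum(countOverlaps(novel, ext, ignore.strand = TRUE) > 0L)
  }
  list(novel = novel, lost = lost, novelNearAnchor = nNear)
}

#' Write a peak classification as three BED files plus a count summary
#'
#' @param classification a [PeakClassification-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the summary `data.frame`.
#' @export
writePeakClassification <- function(classification, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBed(sharedPeaks(classification), file.path(dir, "peaks_shared.bed"))
  writeBed(wtSpecificPeaks(classification),
           file.path(dir, "peaks_wt_specific.bed"))
  writeBed(mutSpecificPeaks(classification),
           file.path(dir, "peaks_mut_specific.bed"))
  summary <- data.frame(
    set = c("shared", "wt_specific", "mut_specific"),
    n = c(length(sharedPeaks(classification)),
          length(wtSpecificPeaks(classification)),
          length(mutSpecificPeaks(classification))))
  write.table(summary, file.path(dir, "peak_classification_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}
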