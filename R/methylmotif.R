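#' @importFrom stats phyper
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
NULL

## Positions of methylated CpG dinucleotides on the plus strand, per chrom.
## A plus-strand C at 1-based position g belongs to the CG at (g, g+1); a
## minus-strand C at q belongs to the CG at (q-1, q). Returned as a list of
## data.frames with the CG start and which strand's cytosine is methylated.
.methylatedCgStarts <- function(cpgs, betaMin) {
  cov <- mcols(cpgs)$nMeth + mcols(cpgs)$nUnmeth
  keep <- cov > 0L
  meth <- cpgs[keep][computeBeta(mcols(cpgs)$nMeth[keep],
                                 mcols(cpgs)$nUnmeth[keep]) > betaMin]
  if (!length(meth)) return(list())
  str <- as.character(strand(meth))
  cgStart <- ifelse(str == "-", start(meth) - 1L, start(meth))
  df <- data.frame(chrom = as.character(seqnames(meth)),
                   cgStart = cgStart, strand = str,
                   stringsAsFactors = FALSE)
  split(df[, c("cgStart", "strand")], df$chrom)
}

#' Extract methylated k-mers per peak
#'
#' For each peak, every k-base window of its sequence that covers a CpG
#' dinucleotide whose cytosine has beta above `betaMin` is recorded. Both
#' strands are scanned: a window whose methylated cytosine lies on the minus
#' strand contributes its reverse complement, so all k-mers live in
#' plus-strand k-mer space without collapsing a k-mer with its reverse
#' complement (the motifs of interest are strand-asymmetric). Presence per
#' peak is a set: a k-mer is counted at most once per peak.
#'
#' @param peaks `GRanges` of peaks (named).
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param cpgs CpG sites as returned by [readCytosineReport()].
#' @param k k-mer length (default 6).
#' @param betaMin methylation threshold; strictly greater-than (default 0.6).
#' @return named list (one element per peak) of character vectors of k-mers.
#' @export
extractMethylatedKmers <- function(peaks, genome, cpgs, k = 6L,
                                   betaMin = 0.6) {
  if (k < 2L) stop("k must be >= 2")
  peaks <- .ensureNames(peaks, "peak")
  chromLen <- stats::setNames(Biostrings::width(genome), names(genome))
  pk <- as.character(seqnames(peaks))
  bad <- !(pk %in% names(genome)) | end(peaks) > chromLen[pk] | start(peaks) < 1L
  if (any(bad))
    stop("peak beyond chromosome end: ",
         paste(names(peaks)[bad], collapse = ", "))
  methByChrom <- .methylatedCgStarts(cpgs, betaMin)
  out <- stats::setNames(rep(list(character()), length(peaks)), names(peaks))
  seqCache <- list()
  for (i in seq_along(peaks)) {
    chrom <- pk[i]
    m <- methByChrom[[chrom]]
    if (is.null(m) || !nrow(m)) next
    ps <- start(peaks)[i]; pe <- end(peaks)[i]
    inPeak <- m[m$cgStart >= ps & m$cgStart + 1L <= pe, , drop = FALSE]
    if (!nrow(inPeak)) next
    if (is.null(seqCache[[chrom]]))
      seqCache[[chrom]] <- as.character(genome[[chrom]])
    sq <- seqCache[[chrom]]
    kmers <- character()
    for (j in seq_len(nrow(inPeak))) {
      g <- inPeak$cgStart[j]
      sFrom <- max(ps, g - k + 2L)
      sTo <- min(g, pe - k + 1L)
      if (sFrom > sTo) next
      w <- substring(sq, sFrom:sTo, (sFrom:sTo) + k - 1L)
      if (inPeak$strand[j] == "-")
        w <- as.character(reverseComplement(DNAStringSet(w)))
      kmers <- c(kmers, w)
    }
    out[[i]] <- unique(kmers)
  }
  out
}

#' Methylated k-mer enrichment in foreground peaks (hypergeometric)
#'
#' For each k-mer observed among all peaks, tests whether the number of
#' *foreground* peaks containing it is surprisingly large given its overall
#' peak frequency, under the hypergeometric null: drawing n = |foreground|
#' peaks from N = |all| of which K carry the k-mer,
#' p = P(X >= observed). Bonferroni correction multiplies by the number of
#' distinct k-mers actually tested (the enumerated hypotheses), not 4^k.
#'
#' @param fgKmers per-peak k-mer sets for the foreground peaks (a subset of
#'   `allKmers` by peak name), from [extractMethylatedKmers()].
#' @param allKmers per-peak k-mer sets for all peaks.
#' @param alpha Bonferroni-adjusted significance cutoff used to select
#'   k-mers for logo construction (default 0.01).
#' @return list with `stats` (data.frame sorted by p: kmer, fgPeaks,
#'   bgPeaks, p, pBonferroni) and `selected` (character vector of k-mers
#'   with adjusted p below `alpha`).
#' @export
kmerEnrichment <- function(fgKmers, allKmers, alpha = 0.01) {
  if (!all(names(fgKmers) %in% names(allKmers)))
    stop("foreground peaks must be a subset of all peaks")
  nAll <- length(allKmers)
  nFg <- length(fgKmers)
  bgCount <- table(unlist(lapply(allKmers, unique), use.names = FALSE))
  if (!length(bgCount)) {
    return(list(stats = data.frame(kmer = character(), fgPeaks = integer(),
                                   bgPeaks = integer(), p = numeric(),
                                   pBonferroni = numeric()),
                selected = character()))
  }
  fgTab <- table(unlist(lapply(fgKmers, unique), use.names = FALSE))
  kmers <- names(bgCount)
  fgCount <- integer(length(kmers))
  fgCount[match(names(fgTab), kmers)] <- as.integer(fgTab)
  K <- as.integer(bgCount)
  if (any(fgCount > K)) stop("foreground counts exceed background counts")
  p <- phyper(fgCount - 1L, K, nAll - K, nFg, lower.tail = FALSE)
  nTested <- length(kmers)
  pBonf <- pmin(1, p * nTested)
  stats <- data.frame(kmer = kmers, fgPeaks = fgCount, bgPeaks = K,
                      p = p, pBonferroni = pBonf, stringsAsFactors = FALSE)
  stats <- stats[order(stats$p, stats$kmer), , drop = FALSE]
  rownames(stats) <- NULL
  list(stats = stats, selected = stats$kmer[stats$pBonferroni < alpha])
}

#' Build a position weight matrix from selected k-mers
#'
#' K-mers are stacked after aligning them at the offset of their first CpG
#' dinucleotide; each contributes its foreground peak count as weight. The
#' matrix width is k plus the spread of CpG offsets; columns covered by only
#' some k-mers are normalized over the covering weight.
#'
#' @param kmers character vector of k-mers, each containing "CG".
#' @param weights numeric weights, typically the foreground peak counts from
#'   [kmerEnrichment()].
#' @return a [MotifPwm-class].
#' @export
buildPwm <- function(kmers, weights = rep(1, length(kmers))) {
  if (!length(kmers)) stop("need at least one selected k-mer")
  if (length(weights) != length(kmers))
    stop("weights must match kmers in length")
  off <- as.integer(regexpr("CG", kmers, fixed = TRUE))
  if (any(off < 1L)) stop("every selected k-mer must contain CG")
  k <- nchar(kmers)
  shift <- max(off) - off
  width <- max(shift + k)
  counts <- matrix(0, nrow = 4, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(kmers)) {
    bases <- strsplit(kmers[i], "")[[1]]
    cols <- shift[i] + seq_len(k[i])
    for (j in seq_along(bases)) {
      counts[bases[j], cols[j]] <- counts[bases[j], cols[j]] + weights[i]
    }
  }
  colTot <- colSums(counts)
  if (any(colTot == 0)) {
    keep <- colTot > 0
    counts <- counts[, keep, drop = FALSE]
    colTot <- colTot[keep]
  }
  profile <- sweep(counts, 2, colTot, "/")
  new("MotifPwm", profile = profile, support = sum(weights))
}

#' Per-column information content of a PWM (bits)
#'
#' IC_j = 2 + sum_b f_bj log2 f_bj, with 0 log 0 = 0; 2 bits for a one-hot
#' column, 0 for a uniform one.
#'
#' @param pwm a [MotifPwm-class].
#' @return numeric vector, one value per column.
#' @export
pwmInformationContent <- function(pwm) {
  f <- pwmMatrix(pwm)
  terms <- ifelse(f > 0, f * log2(f), 0)
  2 + colSums(terms)
}

#' Write a PWM in MEME minimal motif format
#'
#' @param pwm a [MotifPwm-class].
#' @param path output path.
#' @param name motif name written into the file.
#' @return `path`, invisibly.
#' @export
writeMemeMotif <- function(pwm, path, name = "motif_1") {
  f <- pwmMatrix(pwm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %g E= 0",
                       ncol(f), pwmSupport(pwm))), con)
  for (j in seq_len(ncol(f)))
    writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                       f["A", j], f["C", j], f["G", j], f["T", j]), con)
  invisible(path)
}

#' Write a k-mer enrichment table as TSV (sorted by p)
#'
#' @param enrichment output of [kmerEnrichment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKmerStats <- function(enrichment, path) {
  write.table(enrichment$stats, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
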