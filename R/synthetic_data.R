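#' @importFrom stats rlnorm rnorm rpois runif
NULL

## Seeded generators. One study seed fans out to per-generator child seeds by
## fixed offsets so that every generator is a pure function of (seed, params).
.childSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset)
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a random genome
#'
#' I.i.d. bases with P(C) = P(G) = gc/2; deterministic given the seed.
#'
#' @param seed integer seed.
#' @param nChroms number of chromosomes (named chr1, chr2, ...).
#' @param chromLength length of each chromosome in bp (>= 10000).
#' @param gc GC content in (0, 1).
#' @return a [Biostrings::DNAStringSet].
#' @export
generateGenome <- function(seed, nChroms = 2L, chromLength = 300000L,
                           gc = 0.5) {
  if (gc <= 0 || gc > 1) stop("gc must be in (0, 1]")
  if (chromLength < 10000L) stop("chromLength must be >= 10 kb")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  .withSeed(seed, {
    seqs <- vapply(seq_len(nChroms), function(i) {
      paste(sample(c("A", "C", "G", "T"), chromLength, replace = TRUE,
                   prob = prob), collapse = "")
    }, character(1))
    out <- DNAStringSet(seqs)
    names(out) <- sprintf("chr%d", seq_len(nChroms))
    out
  })
}

## All plus-strand CG dinucleotide start positions in a chromosome string.
.cgStarts <- function(seqChar) {
  hits <- gregexpr("CG", seqChar, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

#' Generate WT/mutant peak sets with a planted methylated motif and methylome
#'
#' Places non-overlapping peaks on the genome and partitions them into
#' WT-specific, shared and mutant-specific sets. The motif is spliced into
#' the center of a fraction of WT-specific peaks (and, unmethylated, into a
#' small fraction of shared peaks). The cytosine report covers every CpG of
#' the resulting genome on both strands: CpGs inside motif-planted
#' WT-specific peaks get counts realizing `betaHigh` exactly, all other CpGs
#' counts realizing `betaLow` — high-methylation is thereby concentrated in
#' the WT-specific peaks, the structure the downstream analysis assumes.
#'
#' @param genome a [Biostrings::DNAStringSet] (modified copy is returned).
#' @param seed integer seed.
#' @param nWtSpecific,nShared,nMutSpecific set sizes of the planted partition.
#' @param peakWidth peak width in bp.
#' @param gapBp minimum gap enforced between peaks (slot spacing).
#' @param motif planted motif; must contain "CG".
#' @param betaHighCounts integer (meth, unmeth) counts for high-beta CpGs
#'   (default c(9, 1): beta = 0.9 exactly).
#' @param betaLowCounts counts for background CpGs (default c(2, 8): 0.2).
#' @param fracMotifInSpecific fraction of WT-specific peaks carrying the
#'   methylated motif.
#' @param fracMotifInShared fraction of shared peaks carrying an
#'   unmethylated motif copy.
#' @return list: `genome` (with motifs spliced in), `wtPeaks`, `mutPeaks`
#'   (`GRanges`), `cpgs` (`GRanges` cytosine report), `truth` (list with the
#'   planted partition and motif peak names).
#' @export
generatePeaksAndMethylome <- function(genome, seed, nWtSpecific = 60L,
                                      nShared = 30L, nMutSpecific = 10L,
                                      peakWidth = 400L, gapBp = 1600L,
                                      motif = "CCCGCC",
                                      betaHighCounts = c(9L, 1L),
                                      betaLowCounts = c(2L, 8L),
                                      fracMotifInSpecific = 0.8,
                                      fracMotifInShared = 0.05) {
  if (!grepl("CG", motif, fixed = TRUE)) stop("motif must contain CG")
  if (fracMotifInSpecific < 0 || fracMotifInSpecific > 1 ||
      fracMotifInShared < 0 || fracMotifInShared > 1)
    stop("motif fractions must be in [0, 1]")
  margin <- 8000L
  slotSize <- peakWidth + gapBp
  nTotal <- nWtSpecific + nShared + nMutSpecific
  .withSeed(seed, {
    chromNames <- names(genome)
    lens <- Biostrings::width(genome)
    slots <- do.call(rbind, lapply(seq_along(chromNames), function(i) {
      nSlots <- (lens[i] - 2L * margin) %/% slotSize
      if (nSlots < 1L) return(NULL)
      data.frame(chrom = chromNames[i],
                 start = margin + (seq_len(nSlots) - 1L) * slotSize + 1L)
    }))
    if (is.null(slots) || nrow(slots) < nTotal)
      stop("cannot place ", nTotal, " non-overlapping peaks at this density")
    pick <- slots[sample.int(nrow(slots), nTotal), , drop = FALSE]
    peaks <- GRanges(pick$chrom, IRanges(pick$start, pick$start + peakWidth - 1L))
    grp <- rep(c("wt_specific", "shared", "mut_specific"),
               c(nWtSpecific, nShared, nMutSpecific))
    nm <- sprintf("%s_%03d", grp, unlist(lapply(
      c(nWtSpecific, nShared, nMutSpecific), seq_len)))
    names(peaks) <- nm
    mcols(peaks)$name <- nm
    mcols(peaks)$score <- rep(10, nTotal)

    seqChar <- stats::setNames(as.character(genome), chromNames)
    splice <- function(idx) {
      for (i in idx) {
        chrom <- as.character(seqnames(peaks))[i]
        at <- start(peaks)[i] + (peakWidth - nchar(motif)) %/% 2L
        substr(seqChar[[chrom]], at, at + nchar(motif) - 1L) <<- motif
      }
    }
    wtIdx <- which(grp == "wt_specific")
    shIdx <- which(grp == "shared")
    nMotif <- round(fracMotifInSpecific * nWtSpecific)
    motifIdx <- sort(sample(wtIdx, nMotif))
    splice(motifIdx)
    nShMotif <- round(fracMotifInShared * nShared)
    shMotifIdx <- if (nShMotif > 0) sort(sample(shIdx, nShMotif)) else integer()
    splice(shMotifIdx)

    highRegions <- peaks[motifIdx]
    cpgChrom <- character(); cpgPos <- integer(); cpgStrand <- character()
    cpgMeth <- integer(); cpgUnmeth <- integer()
    for (chrom in chromNames) {
      cg <- .cgStarts(seqChar[[chrom]])
      if (!length(cg)) next
      hr <- highRegions[as.character(seqnames(highRegions)) == chrom]
      isHigh <- rep(FALSE, length(cg))
      if (length(hr)) {
        # a CpG counts as peak methylation if either of its cytosines lies
        # inside a motif-planted peak
        cgGr <- GRanges(chrom, IRanges(cg, cg + 1L))
        isHigh <- countOverlaps(cgGr, hr, ignore.strand = TRUE) > 0L
      }
      nMeth <- as.integer(ifelse(isHigh, betaHighCounts[1], betaLowCounts[1]))
      nUnmeth <- as.integer(ifelse(isHigh, betaHighCounts[2], betaLowCounts[2]))
      # both strands of each CpG: plus C at cg, minus C at cg + 1
      cpgChrom <- c(cpgChrom, rep(chrom, 2L * length(cg)))
      cpgPos <- c(cpgPos, cg, cg + 1L)
      cpgStrand <- c(cpgStrand, rep(c("+", "-"), each = length(cg)))
      cpgMeth <- c(cpgMeth, nMeth, nMeth)
      cpgUnmeth <- c(cpgUnmeth, nUnmeth, nUnmeth)
    }
    cpgs <- GRanges(cpgChrom, IRanges(cpgPos, cpgPos), strand = cpgStrand,
                    nMeth = cpgMeth, nUnmeth = cpgUnmeth)
    cpgs <- GenomicRanges::sort(cpgs, ignore.strand = TRUE)
    mcols(cpgs)$beta <- computeBeta(mcols(cpgs)$nMeth, mcols(cpgs)$nUnmeth)

    genomeOut <- DNAStringSet(seqChar)
    names(genomeOut) <- chromNames
    wtPeaks <- peaks[grp %in% c("wt_specific", "shared")]
    mutPeaks <- peaks[grp %in% c("shared", "mut_specific")]
    names(mutPeaks) <- sub("^shared", "shared_mut", names(mutPeaks))
    mcols(mutPeaks)$name <- names(mutPeaks)
    list(genome = genomeOut, wtPeaks = wtPeaks, mutPeaks = mutPeaks,
         cpgs = cpgs,
         truth = list(plantedMotif = motif,
                      motifPeakNames = names(peaks)[motifIdx],
                      sharedMotifPeakNames = names(peaks)[shMotifIdx],
                      wtSpecificNames = names(peaks)[grp == "wt_specific"],
                      sharedNames = names(peaks)[grp == "shared"],
                      mutSpecificNames = names(mutPeaks)[
                        grepl("^mut_specific", names(mutPeaks))]))
  })
}

#' Generate gene models and enhancer links with planted direct targets
#'
#' Builds gene models so that a chosen subset of WT-specific peaks falls in
#' the upstream window, 5'-UTR or an exon of a planted proximal target gene
#' (cycling through the three categories), adds decoy genes away from the
#' target peaks, and builds an enhancer link table mapping further
#' WT-specific peaks to planted enhancer target genes plus decoy links in
#' peak-free regions.
#'
#' @param wtSpecific `GRanges` of WT-specific peaks (named).
#' @param genomeSizes named chromosome lengths.
#' @param seed integer seed.
#' @param nProximal,nEnhancer planted target counts by route.
#' @param nDecoyGenes modeled genes that are not targets.
#' @param geneWidth decoy/target gene span in bp.
#' @return list: `geneModels` ([GeneModelSet-class]), `enhancerMap`
#'   (`GRanges`), `truth` (data.frame gene_id, category, peak).
#' @export
generateTargets <- function(wtSpecific, genomeSizes, seed, nProximal = 18L,
                            nEnhancer = 12L, nDecoyGenes = 30L,
                            geneWidth = 4000L) {
  if (nProximal + nEnhancer > length(wtSpecific))
    stop("not enough WT-specific peaks to plant targets")
  .withSeed(seed, {
    pickIdx <- sample.int(length(wtSpecific), nProximal + nEnhancer)
    proxIdx <- pickIdx[seq_len(nProximal)]
    enhIdx <- pickIdx[nProximal + seq_len(nEnhancer)]
    cats <- rep(c("upstream", "utr5", "exon"), length.out = nProximal)

    genes <- list(); exons <- list(); utr5 <- list(); ids <- character()
    truth <- list()
    addGene <- function(id, chrom, gStart, gEnd, str, ex, u5) {
      ids <<- c(ids, id)
      genes[[length(genes) + 1L]] <<- GRanges(chrom, IRanges(gStart, gEnd),
                                              strand = str)
      exons[[length(exons) + 1L]] <<- GRanges(chrom, ex, strand = str)
      utr5[[length(utr5) + 1L]] <<- if (is.null(u5)) GRanges()
                                    else GRanges(chrom, u5, strand = str)
    }
    for (j in seq_len(nProximal)) {
      i <- proxIdx[j]
      chrom <- as.character(seqnames(wtSpecific))[i]
      ps <- start(wtSpecific)[i]; pe <- end(wtSpecific)[i]
      id <- sprintf("TGT_PROX_%02d", j)
      if (cats[j] == "upstream") {
        gStart <- pe + 2000L; gEnd <- gStart + geneWidth - 1L
        addGene(id, chrom, gStart, gEnd, "+",
                IRanges(gStart, gEnd), IRanges(gStart, gStart + 199L))
      } else if (cats[j] == "utr5") {
        gStart <- ps - 500L; gEnd <- pe + 1500L
        u5End <- pe + 100L
        addGene(id, chrom, gStart, gEnd, "+",
                IRanges(c(gStart, u5End + 400L), c(u5End, gEnd)),
                IRanges(gStart, u5End))
      } else {
        gStart <- ps - 2000L; gEnd <- pe + 200L
        addGene(id, chrom, gStart, gEnd, "+",
                IRanges(c(gStart, ps - 100L), c(gStart + 300L, gEnd)),
                IRanges(gStart, gStart + 150L))
      }
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = id, category = cats[j],
        peak = names(wtSpecific)[i], stringsAsFactors = FALSE)
    }
    # decoy genes in peak-free space: beyond every peak's upstream reach
    chromNames <- names(genomeSizes)
    for (j in seq_len(nDecoyGenes)) {
      id <- sprintf("DECOY_%02d", j)
      ok <- FALSE
      for (try in 1:50) {
        chrom <- sample(chromNames, 1L)
        gStart <- sample.int(genomeSizes[[chrom]] - geneWidth - 12000L, 1L) + 1L
        cand <- GRanges(chrom, IRanges(pmax(gStart - 11000L, 1L),
                                       gStart + geneWidth + 11000L))
        if (countOverlaps(cand, wtSpecific, ignore.strand = TRUE) == 0L) {
          ok <- TRUE; break
        }
      }
      if (!ok) next
      gEnd <- gStart + geneWidth - 1L
      addGene(id, chrom, gStart, gEnd, sample(c("+", "-"), 1L),
              IRanges(gStart, gEnd), IRanges(gStart, gStart + 199L))
    }
    g <- suppressWarnings(do.call(c, genes)); names(g) <- ids
    exl <- GRangesList(exons); names(exl) <- ids
    ul <- GRangesList(utr5); names(ul) <- ids
    gm <- new("GeneModelSet", genes = g, exons = exl, utr5 = ul)

    enhRows <- list()
    for (j in seq_len(nEnhancer)) {
      i <- enhIdx[j]
      id <- sprintf("TGT_ENH_%02d", j)
      enhRows[[length(enhRows) + 1L]] <- GRanges(
        as.character(seqnames(wtSpecific))[i],
        IRanges(pmax(start(wtSpecific)[i] - 200L, 1L),
                end(wtSpecific)[i] + 200L),
        gene_id = id, confidence = round(runif(1, 0.5, 1), 3))
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = id, category = "enhancer",
        peak = names(wtSpecific)[i], stringsAsFactors = FALSE)
    }
    # decoy enhancer links in peak-free space
    for (j in seq_len(max(nEnhancer %/% 2L, 1L))) {
      for (try in 1:50) {
        chrom <- sample(chromNames, 1L)
        s <- sample.int(genomeSizes[[chrom]] - 2000L, 1L) + 1L
        cand <- GRanges(chrom, IRanges(s, s + 800L))
        if (countOverlaps(cand, wtSpecific, ignore.strand = TRUE) == 0L) {
          mcols(cand)$gene_id <- sprintf("DECOY_ENH_%02d", j)
          mcols(cand)$confidence <- round(runif(1, 0.5, 1), 3)
          enhRows[[length(enhRows) + 1L]] <- cand
          break
        }
      }
    }
    enhancerMap <- suppressWarnings(do.call(c, enhRows))
    list(geneModels = gm, enhancerMap = enhancerMap,
         truth = do.call(rbind, truth))
  })
}

#' Generate 4-condition expression tables with planted up-regulation
#'
#' Baseline FPKM is log-normal; planted WT-only up genes (direct targets
#' plus unbound up genes) are multiplied by `inductionFold` at 48 h in the
#' untreated arm but only by `1 + azaAttenuation * (inductionFold - 1)` in
#' the demethylated (5-Aza) arm, so their induction fold change drops under
#' 5-Aza. Genes up in both arms keep full induction under 5-Aza and are also
#' induced in the mutant table. Multiplicative log-normal noise applies to
#' every measurement.
#'
#' @param geneIds character vector of all gene ids in the table.
#' @param targetIds planted WT-only up-regulated direct targets.
#' @param seed integer seed.
#' @param nUpUnbound additional WT-only up genes without binding (first ids
#'   not in `targetIds` are used).
#' @param nSharedUp genes up in both WT and mutant arms.
#' @param meanlog,sdlog baseline log-normal parameters (FPKM scale).
#' @param inductionFold expression fold at 48 h for up genes (> 1).
#' @param azaAttenuation residual induction fraction under 5-Aza in \[0, 1\]
#'   (0 = fully blocked).
#' @param noiseSd sd of log-normal measurement noise.
#' @return list: `wt` (data.frame gene_id, t0, t48, t0_aza, t48_aza),
#'   `mut` (gene_id, t0, t48), `truth` (gene_id, direction, arm).
#' @export
generateExpression <- function(geneIds, targetIds, seed, nUpUnbound = 30L,
                               nSharedUp = 20L, meanlog = 1, sdlog = 1,
                               inductionFold = 4, azaAttenuation = 0.15,
                               noiseSd = 0.1) {
  if (inductionFold < 1) stop("inductionFold must be >= 1")
  if (azaAttenuation < 0 || azaAttenuation > 1)
    stop("azaAttenuation must be in [0, 1]")
  if (!all(targetIds %in% geneIds)) stop("targetIds must be in geneIds")
  .withSeed(seed, {
    n <- length(geneIds)
    free <- setdiff(geneIds, targetIds)
    upUnbound <- head(free, nUpUnbound)
    sharedUp <- head(setdiff(free, upUnbound), nSharedUp)
    upWtOnly <- c(targetIds, upUnbound)
    base <- rlnorm(n, meanlog, sdlog)
    planted <- geneIds %in% c(upWtOnly, sharedUp)
    base[planted] <- pmax(base[planted], 1)  # keep planted genes expressed
    foldWt <- ifelse(geneIds %in% c(upWtOnly, sharedUp), inductionFold, 1)
    azaFold <- ifelse(geneIds %in% upWtOnly,
                      1 + azaAttenuation * (inductionFold - 1),
                      ifelse(geneIds %in% sharedUp, inductionFold, 1))
    foldMut <- ifelse(geneIds %in% sharedUp, inductionFold, 1)
    eps <- function() exp(rnorm(n, 0, noiseSd))
    wt <- data.frame(gene_id = geneIds,
                     t0 = base * eps(),
                     t48 = base * foldWt * eps(),
                     t0_aza = base * eps(),
                     t48_aza = base * azaFold * eps(),
                     stringsAsFactors = FALSE)
    mut <- data.frame(gene_id = geneIds,
                      t0 = base * eps(),
                      t48 = base * foldMut * eps(),
                      stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = c(upWtOnly, sharedUp),
                        direction = rep("up", length(upWtOnly) + length(sharedUp)),
                        arm = rep(c("wt_only", "both"),
                                  c(length(upWtOnly), length(sharedUp))),
                        stringsAsFactors = FALSE)
    list(wt = wt, mut = mut, truth = truth)
  })
}

#' Generate histone-mark read sets for two time points
#'
#' Per-region read counts are Poisson(`depth`) at 0 h and
#' Poisson(`depth * fold`) at 48 h for effect regions (Poisson(`depth`) both
#' times elsewhere), with reads placed uniformly inside the region.
#' Background reads are scattered uniformly over the genome at both time
#' points.
#'
#' @param regions `GRanges` of signal regions.
#' @param effect logical vector: which regions carry the planted increase.
#' @param seed integer seed.
#' @param depth expected reads per region (> 0).
#' @param fold coverage fold change at 48 h for effect regions (> 0).
#' @param genomeSizes named chromosome lengths for background reads.
#' @param nBackgroundReads background reads per time point.
#' @param readLength read interval length in bp.
#' @return list with `t0` and `t48` read `GRanges`.
#' @export
generateHistoneReads <- function(regions, effect, seed, depth = 50,
                                 fold = 4, genomeSizes,
                                 nBackgroundReads = 20000L,
                                 readLength = 50L) {
  if (depth <= 0 || fold <= 0) stop("depth and fold must be positive")
  if (length(effect) != length(regions))
    stop("effect must match regions in length")
  .withSeed(seed, {
    drawRegionReads <- function(lambda) {
      cnt <- rpois(length(regions), lambda)
      idx <- rep(seq_along(regions), cnt)
      if (!length(idx)) return(GRanges())
      maxStart <- pmax(end(regions)[idx] - readLength + 1L, start(regions)[idx])
      s <- start(regions)[idx] +
        floor(runif(length(idx)) * (maxStart - start(regions)[idx] + 1L))
      GRanges(as.character(seqnames(regions))[idx],
              IRanges(s, s + readLength - 1L))
    }
    drawBackground <- function() {
      chroms <- sample(names(genomeSizes), nBackgroundReads, replace = TRUE,
                       prob = as.numeric(genomeSizes) / sum(as.numeric(genomeSizes)))
      s <- floor(runif(nBackgroundReads) *
                   (genomeSizes[chroms] - readLength)) + 1L
      GRanges(chroms, IRanges(s, s + readLength - 1L))
    }
    t0 <- suppressWarnings(
      c(drawRegionReads(rep(depth, length(regions))), drawBackground()))
    t48 <- suppressWarnings(
      c(drawRegionReads(ifelse(effect, depth * fold, depth)),
        drawBackground()))
    list(t0 = GenomicRanges::sort(t0), t48 = GenomicRanges::sort(t48))
  })
}

#' Simulate a complete study with planted ground truth
#'
#' Orchestrates all generators from a single seed (fanned out to fixed child
#' seeds) and returns every input the pipeline consumes together with the
#' planted truth: the peak partition, the methylated motif and its carrier
#' peaks, direct target genes with categories, the DEG structure and the
#' histone effect regions.
#'
#' @param seed integer seed.
#' @param params named list overriding any default listed in Details.
#' @details Default scale: 2 chromosomes x 300 kb, 60/30/10
#'   WT-specific/shared/mutant-specific peaks of 400 bp, motif CCCGCC
#'   (methylated, beta 0.9) in 80% of WT-specific peaks, background beta
#'   0.2, 600 expression genes of which 30 planted proximal+enhancer targets
#'   (18 + 12), 30 unbound up genes and 20 up in both arms, induction fold
#'   4, 5-Aza attenuation 0.15, histone depth 50 with 4-fold increase at 80%
#'   of target regions.
#' @return list with `genome`, `wtPeaks`, `mutPeaks`, `cpgs`, `geneModels`,
#'   `enhancerMap`, `expression` (list wt/mut), `degTable`, `histoneReads`
#'   (list t0/t48), `genomeSizes`, `params` and `truth`.
#' @export
simulateStudy <- function(seed, params = list()) {
  p <- utils::modifyList(list(
    nChroms = 2L, chromLength = 300000L, gc = 0.5,
    nWtSpecific = 60L, nShared = 30L, nMutSpecific = 10L,
    peakWidth = 400L, gapBp = 1600L,
    motif = "CCCGCC", fracMotifInSpecific = 0.8, fracMotifInShared = 0.05,
    betaHighCounts = c(9L, 1L), betaLowCounts = c(2L, 8L),
    nProximal = 18L, nEnhancer = 12L, nDecoyGenes = 30L,
    nGenes = 600L, nUpUnbound = 30L, nSharedUp = 20L,
    inductionFold = 4, azaAttenuation = 0.15, noiseSd = 0.1,
    histoneDepth = 50, histoneFold = 4, histoneEffectFrac = 0.8,
    halfWidth = 1000L, nBackgroundReads = 20000L, readLength = 50L,
    degLog2fcMin = 1), params)

  genome0 <- generateGenome(.childSeed(seed, 1L), p$nChroms, p$chromLength,
                            p$gc)
  pm <- generatePeaksAndMethylome(genome0, .childSeed(seed, 2L),
                                  p$nWtSpecific, p$nShared, p$nMutSpecific,
                                  p$peakWidth, p$gapBp, p$motif,
                                  p$betaHighCounts, p$betaLowCounts,
                                  p$fracMotifInSpecific, p$fracMotifInShared)
  genomeSizes <- stats::setNames(Biostrings::width(pm$genome),
                                 names(pm$genome))
  wtSpecific <- pm$wtPeaks[pm$truth$wtSpecificNames]
  tg <- generateTargets(wtSpecific, genomeSizes, .childSeed(seed, 3L),
                        p$nProximal, p$nEnhancer, p$nDecoyGenes)
  fillerIds <- sprintf("GENE_%04d", seq_len(
    max(p$nGenes - length(tg$truth$gene_id) - length(geneIds(tg$geneModels)), 0L)))
  allGeneIds <- unique(c(tg$truth$gene_id, geneIds(tg$geneModels), fillerIds))
  ex <- generateExpression(allGeneIds, tg$truth$gene_id, .childSeed(seed, 4L),
                           p$nUpUnbound, p$nSharedUp,
                           inductionFold = p$inductionFold,
                           azaAttenuation = p$azaAttenuation,
                           noiseSd = p$noiseSd)
  degTable <- rbind(
    callDegsNaive(ex$wt, "t0", "t48", condition = "wt",
                  log2fcMin = p$degLog2fcMin),
    callDegsNaive(ex$mut, "t0", "t48", condition = "mut",
                  log2fcMin = p$degLog2fcMin))
  anchorPeaks <- wtSpecific[unique(tg$truth$peak)]
  regions <- buildSignalRegions(anchorPeaks, p$halfWidth)
  nEffect <- round(p$histoneEffectFrac * length(regions))
  effect <- rep(FALSE, length(regions))
  effect[.withSeed(.childSeed(seed, 5L),
                   sample.int(length(regions), nEffect))] <- TRUE
  hr <- generateHistoneReads(regions, effect, .childSeed(seed, 6L),
                             p$histoneDepth, p$histoneFold, genomeSizes,
                             p$nBackgroundReads, p$readLength)
  truth <- list(
    plantedMotif = p$motif,
    motifPeakNames = pm$truth$motifPeakNames,
    wtSpecificNames = pm$truth$wtSpecificNames,
    sharedNames = pm$truth$sharedNames,
    mutSpecificNames = pm$truth$mutSpecificNames,
    targets = tg$truth,
    degTruth = ex$truth,
    histoneEffectRegions = names(regions)[effect])
  list(genome = pm$genome, wtPeaks = pm$wtPeaks, mutPeaks = pm$mutPeaks,
       cpgs = pm$cpgs, geneModels = tg$geneModels,
       enhancerMap = tg$enhancerMap, expression = ex[c("wt", "mut")],
       degTable = degTable, histoneReads = hr, genomeSizes = genomeSizes,
       params = p, truth = truth)
}

#' Write gene models as BED12
#'
#' @param geneModels a [GeneModelSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModelsBed12 <- function(geneModels, path) {
  ids <- geneIds(geneModels)
  g <- geneRanges(geneModels)
  rows <- vapply(seq_along(ids), function(i) {
    ex <- geneExons(geneModels)[[i]]
    ex <- GenomicRanges::sort(ex)
    u5 <- geneUtr5(geneModels)[[i]]
    s0 <- start(g)[i] - 1L; e0 <- end(g)[i]
    str <- as.character(strand(g))[i]
    if (length(u5)) {
      thick0 <- if (str == "+") c(max(end(u5)), e0)
                else c(s0, min(start(u5)) - 1L)
    } else thick0 <- c(s0, s0)
    paste(as.character(seqnames(g))[i], s0, e0, ids[i], 0, str,
          thick0[1], thick0[2], "0", length(ex),
          paste0(paste(GenomicRanges::width(ex), collapse = ","), ","),
          paste0(paste(start(ex) - 1L - s0, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Write every simulated input in the pipeline's file formats
#'
#' Emits exactly the formats the readers consume: BED peaks and reads, FASTA
#' genome, cytosine report, BED12 gene models, expression and DEG TSVs,
#' enhancer map TSV, chromosome sizes, and the planted truth as JSON.
#'
#' @param sim output of [simulateStudy()].
#' @param dir output directory (created).
#' @return named character vector of the written paths, invisibly.
#' @export
writeStudy <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    wtPeaks = file.path(dir, "wt_peaks.bed"),
    mutPeaks = file.path(dir, "mut_peaks.bed"),
    genome = file.path(dir, "genome.fa"),
    cytosineReport = file.path(dir, "cytosine_report.tsv"),
    geneModels = file.path(dir, "genes.bed12"),
    expressionWt = file.path(dir, "expression_wt.tsv"),
    expressionMut = file.path(dir, "expression_mut.tsv"),
    degTable = file.path(dir, "deg.tsv"),
    enhancerMap = file.path(dir, "enhancers.tsv"),
    histoneT0 = file.path(dir, "histone_t0.bed"),
    histoneT48 = file.path(dir, "histone_t48.bed"),
    chromSizes = file.path(dir, "chrom.sizes"),
    truth = file.path(dir, "truth.json"))
  writeBed(sim$wtPeaks, paths["wtPeaks"])
  writeBed(sim$mutPeaks, paths["mutPeaks"])
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  writeCytosineReport(sim$cpgs, paths["cytosineReport"])
  writeGeneModelsBed12(sim$geneModels, paths["geneModels"])
  write.table(sim$expression$wt, paths["expressionWt"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$expression$mut, paths["expressionMut"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$degTable, paths["degTable"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  em <- sim$enhancerMap
  write.table(data.frame(as.character(seqnames(em)), start(em) - 1L, end(em),
                         mcols(em)$gene_id, mcols(em)$confidence),
              paths["enhancerMap"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeBed(sim$histoneReads$t0, paths["histoneT0"])
  writeBed(sim$histoneReads$t48, paths["histoneT48"])
  write.table(data.frame(names(sim$genomeSizes), sim$genomeSizes),
              paths["chromSizes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
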