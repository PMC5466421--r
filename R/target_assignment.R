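#' @importFrom stats p.adjust pbinom setNames
NULL

.CATEGORY_LEVELS <- c("utr5", "exon", "upstream", "enhancer")

#' Strand-aware upstream windows of gene TSSs
#'
#' For a '+' gene the window is the `upstreamBp` bases ending just before
#' the TSS; for a '-' gene, the `upstreamBp` bases starting just after it.
#' Windows are clipped at position 1.
#'
#' @param geneModels a [GeneModelSet-class].
#' @param upstreamBp window size in bp (default 10000).
#' @return `GRanges` named by gene id.
#' @export
upstreamWindows <- function(geneModels, upstreamBp = 10000L) {
  g <- geneRanges(geneModels)
  tss <- geneTss(geneModels)
  plus <- as.character(strand(g)) == "+"
  s <- ifelse(plus, pmax(tss - upstreamBp, 1L), tss + 1L)
  e <- ifelse(plus, tss - 1L, tss + upstreamBp)
  keep <- e >= s
  out <- GRanges(as.character(seqnames(g))[keep], IRanges(s[keep], e[keep]))
  names(out) <- geneIds(geneModels)[keep]
  out
}

#' Assign peaks to genes via proximal regulatory regions
#'
#' A peak is proximally assigned to a gene when it overlaps the gene's
#' 5'-UTR, an exon, or the strand-aware upstream window (`upstreamBp` bp,
#' default 10 kb, upstream of the TSS). When several categories apply to the
#' same peak-gene pair, one category is kept by the precedence
#' utr5 > exon > upstream. A peak may be assigned to multiple genes.
#'
#' @param peaks `GRanges` of peaks (named).
#' @param geneModels a [GeneModelSet-class].
#' @param upstreamBp upstream window size in bp.
#' @return data.frame with columns `peak`, `gene_id`, `category`.
#' @export
classifyProximal <- function(peaks, geneModels, upstreamBp = 10000L) {
  peaks <- .ensureNames(peaks, "peak")
  pieces <- list()
  addHits <- function(regionGr, geneOf, category) {
    if (!length(regionGr)) return()
    hits <- findOverlaps(peaks, regionGr, ignore.strand = TRUE)
    if (!length(hits)) return()
    pieces[[length(pieces) + 1L]] <<- data.frame(
      peak = names(peaks)[queryHits(hits)],
      gene_id = geneOf[subjectHits(hits)],
      category = category, stringsAsFactors = FALSE)
  }
  ids <- geneIds(geneModels)
  u5 <- unlist(geneUtr5(geneModels), use.names = FALSE)
  u5gene <- rep(ids, lengths(geneUtr5(geneModels)))
  addHits(u5, u5gene, "utr5")
  ex <- unlist(geneExons(geneModels), use.names = FALSE)
  exGene <- rep(ids, lengths(geneExons(geneModels)))
  addHits(ex, exGene, "exon")
  up <- upstreamWindows(geneModels, upstreamBp)
  addHits(up, names(up), "upstream")
  if (!length(pieces))
    return(data.frame(peak = character(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE))
  df <- unique(do.call(rbind, pieces))
  df$rank <- match(df$category, .CATEGORY_LEVELS)
  df <- df[order(df$peak, df$gene_id, df$rank), , drop = FALSE]
  df <- df[!duplicated(df[, c("peak", "gene_id")]), , drop = FALSE]
  df$rank <- NULL
  rownames(df) <- NULL
  df
}

#' Assign peaks to genes via enhancer links
#'
#' A peak is linked to a gene when it overlaps an enhancer interval mapped
#' to that gene in the link table. Multiple enhancers of one gene hit by the
#' same peak collapse to a single peak-gene link.
#'
#' @param peaks `GRanges` of peaks (named).
#' @param enhancerMap `GRanges` from [readEnhancerMap()].
#' @return data.frame with columns `peak`, `gene_id`, `category` ("enhancer").
#' @export
linkEnhancerTargets <- function(peaks, enhancerMap) {
  peaks <- .ensureNames(peaks, "peak")
  hits <- findOverlaps(peaks, enhancerMap, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(peak = character(), gene_id = character(),
                      category = character(), stringsAsFactors = FALSE))
  df <- unique(data.frame(
    peak = names(peaks)[queryHits(hits)],
    gene_id = mcols(enhancerMap)$gene_id[subjectHits(hits)],
    category = "enhancer", stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Up-regulated, WT-only genes from per-arm DEG tables
#'
#' A gene qualifies when it is significantly up-regulated in the WT arm
#' (log2fc > 0, p < `pCutoff`) and not significant in the mutant arm at the
#' same cutoff.
#'
#' @param degTable data.frame with `gene_id`, `log2fc`, `p`, `condition`.
#' @param wtCondition,mutCondition condition labels of the two arms.
#' @param pCutoff DEG significance cutoff (default 0.001).
#' @return character vector of gene ids.
#' @export
wtOnlyUpGenes <- function(degTable, wtCondition = "wt", mutCondition = "mut",
                          pCutoff = 0.001) {
  wt <- degTable[degTable$condition == wtCondition, , drop = FALSE]
  mut <- degTable[degTable$condition == mutCondition, , drop = FALSE]
  upWt <- wt$gene_id[wt$log2fc > 0 & wt$p < pCutoff]
  degMut <- mut$gene_id[mut$p < pCutoff]
  setdiff(upWt, degMut)
}

#' Direct target genes of methylation-dependent binding
#'
#' Targets are genes that are up-regulated in the WT arm only and carry at
#' least one WT-specific peak assigned by the proximal or the enhancer
#' route. A gene assigned by both routes is counted once with its proximal
#' category (precedence utr5 > exon > upstream > enhancer), mirroring the
#' convention that enhancer links only add genes not already explained
#' proximally.
#'
#' @param proximal data.frame from [classifyProximal()].
#' @param enhancer data.frame from [linkEnhancerTargets()].
#' @param upGenes character vector of WT-only up-regulated gene ids (e.g.
#'   from [wtOnlyUpGenes()]).
#' @return data.frame with `gene_id`, `category`, `peaks` (comma-separated
#'   supporting peak names), `direction` ("up").
#' @export
identifyDirectTargets <- function(proximal, enhancer, upGenes) {
  assign <- rbind(proximal, enhancer)
  assign <- assign[assign$gene_id %in% upGenes, , drop = FALSE]
  if (!nrow(assign))
    return(data.frame(gene_id = character(), category = character(),
                      peaks = character(), direction = character(),
                      stringsAsFactors = FALSE))
  assign$rank <- match(assign$category, .CATEGORY_LEVELS)
  out <- do.call(rbind, lapply(split(assign, assign$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1],
               category = d$category[which.min(d$rank)],
               peaks = paste(sort(unique(d$peak)), collapse = ","),
               direction = "up", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Enrichment of up-regulated genes among peak-associated genes
#'
#' Given k peak-associated up-regulated genes among n peak-associated
#' expressed genes, K up-regulated genes among the N expressed genes,
#' fold enrichment is (k/n) / (K/N) and p the one-sided hypergeometric
#' upper tail P(X >= k).
#'
#' @param k associated and up-regulated count.
#' @param n associated and expressed count.
#' @param K up-regulated and expressed count.
#' @param N size of the expressed universe.
#' @return list with `k`, `n`, `K`, `N`, `foldEnrichment`, `foldDisplay`
#'   (rounded to 1 decimal) and `p`.
#' @examples
#' targetEnrichment(116, 2518, 308, 12824)$foldDisplay  # 1.9
#' @export
targetEnrichment <- function(k, n, K, N) {
  if (n <= 0 || K <= 0 || N <= 0) stop("counts must be positive")
  if (k > n || k > K || n > N || K > N) stop("inconsistent 2x2 composition")
  fold <- if (k == 0) 0 else (k / n) / (K / N)
  list(k = k, n = n, K = K, N = N,
       foldEnrichment = fold,
       foldDisplay = round(fold, 1),
       p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Gene-set enrichment by hypergeometric test with BH-FDR
#'
#' For each named set, tests the overlap with the target list against the
#' universe: p = P(X >= overlap) under Hypergeometric(N = |universe|,
#' K = |set in universe|, n = |targets|). Sets are intersected with the
#' universe first. Adjusted by Benjamini-Hochberg; significant means
#' FDR below `fdrCutoff`.
#'
#' @param targets character vector of target gene ids (must lie in universe).
#' @param geneSets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of background gene ids.
#' @param fdrCutoff significance cutoff on the FDR (default 0.05).
#' @return data.frame: set, setSize, overlap, p, fdr, significant.
#' @export
geneSetEnrichment <- function(targets, geneSets, universe, fdrCutoff = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  targets <- unique(targets)
  if (!all(targets %in% universe))
    stop("targets must be a subset of the universe")
  n <- length(targets); N <- length(universe)
  rows <- lapply(names(geneSets), function(s) {
    set <- intersect(geneSets[[s]], universe)
    k <- length(intersect(set, targets))
    K <- length(set)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, setSize = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$fdr <- p.adjust(df$p, method = "BH")
  df$significant <- df$fdr < fdrCutoff
  df[order(df$p), , drop = FALSE]
}

#' Demethylating-agent (5-Aza) reversal of induction
#'
#' Within each arm (untreated, 5-Aza) the induction fold change of a gene is
#' FC = FPKM(t48) / FPKM(t0); a gene's induction is *reduced* by 5-Aza when
#' the difference in fold change, dFC = FC_aza - FC_untreated, is negative.
#' Returns the reduced fraction among targets, the reduced fraction q among
#' all expressed genes, and the one-sided exact binomial probability of
#' observing at least the target count reduced when each target is reduced
#' independently with probability q.
#'
#' An alternative convention compares expression at the induced time point
#' only (t48_aza vs t48), available via `method = "t48"`.
#'
#' @param expr expression data.frame with `gene_id` and the four condition
#'   columns `t0`, `t48`, `t0_aza`, `t48_aza`, already restricted to the
#'   expressed universe.
#' @param targets character vector of target gene ids (subset of
#'   `expr$gene_id`).
#' @param method `"deltaFC"` (default) or `"t48"`.
#' @return list with `nTargets`, `kTargetsReduced`, `fracTargetsReduced`,
#'   `fracUniverseReduced` and the one-sided binomial `p`.
#' @export
azaReversalStats <- function(expr, targets, method = c("deltaFC", "t48")) {
  method <- match.arg(method)
  need <- c("t0", "t48", "t0_aza", "t48_aza")
  miss <- setdiff(need, colnames(expr))
  if (length(miss))
    stop("expression table missing condition column: ",
         paste(miss, collapse = ", "))
  if (!all(targets %in% expr$gene_id))
    stop("targets must appear in the expression table")
  reduced <- if (method == "deltaFC") {
    (expr$t48_aza / expr$t0_aza) - (expr$t48 / expr$t0) < 0
  } else {
    expr$t48_aza < expr$t48
  }
  isTarget <- expr$gene_id %in% targets
  q <- mean(reduced)
  kT <- sum(reduced[isTarget])
  nT <- sum(isTarget)
  if (nT == 0) stop("no targets present")
  list(nTargets = nT,
       kTargetsReduced = kT,
       fracTargetsReduced = kT / nT,
       fracUniverseReduced = q,
       p = pbinom(kT - 1, nT, q, lower.tail = FALSE))
}

#' Naive differential-expression caller (plumbing)
#'
#' A stand-in caller for synthetic data only: a gene is called up (down)
#' when its induction |log2 fold change| exceeds `log2fcMin`, with a nominal
#' p of 0 for calls and 1 otherwise so that downstream p-based filters keep
#' exactly the fold-change calls. Real DEG tables should come from a
#' dedicated caller and be loaded with [readDegTable()].
#'
#' @param expr expression data.frame with `gene_id` and the two columns
#'   named in `cond0`/`cond48`.
#' @param cond0,cond48 condition column names.
#' @param condition label written into the `condition` column.
#' @param log2fcMin fold-change threshold (default 1, i.e. 2-fold).
#' @param pseudo pseudocount added to both FPKM values before the ratio.
#' @return data.frame in [readDegTable()] layout, calls only.
#' @export
callDegsNaive <- function(expr, cond0 = "t0", cond48 = "t48",
                          condition = "wt", log2fcMin = 1, pseudo = 0.01) {
  lfc <- log2((expr[[cond48]] + pseudo) / (expr[[cond0]] + pseudo))
  called <- abs(lfc) > log2fcMin
  data.frame(gene_id = expr$gene_id[called],
             log2fc = lfc[called],
             p = rep(0, sum(called)),
             condition = rep(condition, sum(called)),
             stringsAsFactors = FALSE)
}

#' Genes expressed above an FPKM floor
#'
#' A gene belongs to the expressed universe when its FPKM exceeds `fpkmMin`
#' in at least one condition column.
#'
#' @param expr expression data.frame with `gene_id` plus condition columns.
#' @param fpkmMin expression floor (default 0.5 FPKM).
#' @return character vector of gene ids.
#' @export
expressedGenes <- function(expr, fpkmMin = 0.5) {
  condCols <- setdiff(colnames(expr), "gene_id")
  keep <- apply(expr[, condCols, drop = FALSE], 1, function(v) any(v > fpkmMin))
  expr$gene_id[keep]
}
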