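makeGeneModel <- function(id, chrom, start, end, strand,
                          exons = IRanges(start, end),
                          utr5 = NULL) {
  g <- GRanges(chrom, IRanges(start, end), strand = strand)
  names(g) <- id
  exl <- GRangesList(list(GRanges(chrom, exons, strand = strand)))
  names(exl) <- id
  ul <- GRangesList(list(if (is.null(utr5)) GRanges()
                         else GRanges(chrom, utr5, strand = strand)))
  names(ul) <- id
  new("GeneModelSet", genes = g, exons = exl, utr5 = ul)
}

test_that("proximal classification is strand-aware with utr5>exon>upstream", {
  # + strand gene, TSS 20001 (bed 20000); peak 10 kb window upstream
  gm <- makeGeneModel("G1", "chr1", 20001, 25000, "+")
  peak <- bedToGRanges(data.frame(chrom = "chr1", start = 12000, end = 12500))
  names(peak) <- "pk"
  res <- classifyProximal(peak, gm)
  expect_equal(res$category, "upstream")
  expect_equal(res$gene_id, "G1")

  # peak overlapping 5'UTR and exon of the same gene: utr5 wins
  gm2 <- makeGeneModel("G2", "chr1", 1000, 5000, "+",
                       exons = IRanges(c(1000, 3000), c(1500, 5000)),
                       utr5 = IRanges(1000, 1200))
  peak2 <- bedToGRanges(data.frame(chrom = "chr1", start = 1100, end = 1400))
  names(peak2) <- "pk2"
  expect_equal(classifyProximal(peak2, gm2)$category, "utr5")

  # - strand gene span bed [5000,8000): upstream window right of the TSS
  gm3 <- makeGeneModel("G3", "chr1", 5001, 8000, "-")
  peak3 <- bedToGRanges(data.frame(chrom = "chr1", start = 8500, end = 9000))
  names(peak3) <- "pk3"
  expect_equal(classifyProximal(peak3, gm3)$category, "upstream")
  # ... and nothing beyond 10 kb
  far <- bedToGRanges(data.frame(chrom = "chr1", start = 18100, end = 18600))
  names(far) <- "pkFar"
  expect_equal(nrow(classifyProximal(far, gm3)), 0L)
})

test_that("enhancer links collapse multiple enhancers of one gene", {
  peaks <- bedToGRanges(data.frame(chrom = "chr1", start = 1500, end = 1600))
  names(peaks) <- "pk"
  em <- GRanges("chr1", IRanges(c(1001, 1551), c(2000, 1800)))
  mcols(em)$gene_id <- c("GENE7", "GENE7")
  mcols(em)$confidence <- c(1, 0.8)
  res <- linkEnhancerTargets(peaks, em)
  expect_equal(nrow(res), 1L)
  expect_equal(res$gene_id, "GENE7")
  expect_equal(res$category, "enhancer")
})

test_that("direct targets require WT-only up-regulation and a peak route", {
  prox <- data.frame(peak = "pk1", gene_id = "G1", category = "upstream",
                     stringsAsFactors = FALSE)
  enh <- data.frame(peak = c("pk2", "pk3"), gene_id = c("G1", "G2"),
                    category = "enhancer", stringsAsFactors = FALSE)
  tgt <- identifyDirectTargets(prox, enh, upGenes = c("G1", "G2", "G9"))
  expect_setequal(tgt$gene_id, c("G1", "G2"))
  # proximal category wins when both routes assign the gene
  expect_equal(tgt$category[tgt$gene_id == "G1"], "upstream")
  expect_equal(tgt$peaks[tgt$gene_id == "G1"], "pk1,pk2")
  expect_equal(tgt$category[tgt$gene_id == "G2"], "enhancer")

  # gene up in both arms is excluded upstream of this call
  deg <- data.frame(gene_id = c("G1", "G2", "G2"),
                    log2fc = c(2, 2, 2), p = c(1e-5, 1e-5, 1e-5),
                    condition = c("wt", "wt", "mut"))
  expect_equal(wtOnlyUpGenes(deg), "G1")
})

test_that("target enrichment reproduces the fold-change identity", {
  er <- targetEnrichment(116, 2518, 308, 12824)
  expect_equal(er$foldEnrichment, (116 / 2518) / (308 / 12824))
  expect_equal(er$foldDisplay, 1.9)
  expect_equal(er$p, phyper(115, 308, 12824 - 308, 2518, lower.tail = FALSE))

  zero <- targetEnrichment(0, 100, 10, 1000)
  expect_equal(zero$foldEnrichment, 0)
  expect_equal(zero$p, 1)
  expect_error(targetEnrichment(50, 40, 60, 100), "inconsistent")

  # small-instance agreement with brute-force enumeration
  set.seed(31)
  for (rep in 1:50) {
    N <- sample(5:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(targetEnrichment(k, n, K, N)$p, bruteHyperUpper(k, K, n, N),
                 tolerance = 1e-10)
  }
})

test_that("gene-set enrichment applies the hypergeometric + BH recipe", {
  universe <- sprintf("G%03d", 1:100)
  sets <- list(hit = universe[1:10], chance = universe[11:30])
  targets <- universe[1:5]
  res <- geneSetEnrichment(targets, sets, universe)
  expect_equal(res$p[res$set == "hit"], 252 / 75287520, tolerance = 1e-12)
  expect_true(all(res$fdr >= res$p))

  single <- geneSetEnrichment(targets, sets["hit"], universe)
  expect_equal(single$fdr, single$p)

  expect_error(geneSetEnrichment("not_there", sets, universe), "subset")
  expect_error(geneSetEnrichment(targets, sets, character()), "empty universe")
})

test_that("5-Aza reversal statistics follow the delta-fold-change rule", {
  # deterministic table: targets fully reversed, half the universe reduced
  n <- 40
  expr <- data.frame(gene_id = sprintf("G%02d", 1:n),
                     t0 = 1, t48 = 1, t0_aza = 1, t48_aza = 1)
  expr$t48[1:10] <- 4                      # targets induced untreated
  expr$t48_aza[1:10] <- 1.5                # attenuated under 5-Aza
  expr$t48_aza[11:25] <- 0.9               # reduced background
  expr$t48_aza[26:40] <- 1.1               # increased background
  res <- azaReversalStats(expr, sprintf("G%02d", 1:10))
  expect_equal(res$fracTargetsReduced, 1)
  q <- res$fracUniverseReduced
  expect_equal(res$p, pbinom(9, 10, q, lower.tail = FALSE))

  # all targets reduced at q = 0.5 gives p = 0.5^n (targets count in q)
  expr2 <- data.frame(gene_id = c("T1", "T2", "B1", "B2", "B3", "B4"),
                      t0 = 1, t48 = 2, t0_aza = 1,
                      t48_aza = c(1, 1, 1.5, 3, 3, 3))
  res2 <- azaReversalStats(expr2, c("T1", "T2"))
  expect_equal(res2$fracUniverseReduced, 0.5)
  expect_equal(res2$p, 0.5^2)

  expect_error(azaReversalStats(expr2[, -5], "T1"), "t48_aza")
})

test_that("with no 5-Aza effect target and universe fractions agree", {
  set.seed(77)
  ex <- generateExpression(sprintf("G%03d", 1:300), sprintf("G%03d", 1:30),
                           seed = 5, nUpUnbound = 0L, nSharedUp = 0L,
                           azaAttenuation = 1)  # full induction under 5-Aza
  res <- azaReversalStats(ex$wt, sprintf("G%03d", 1:30))
  # both arms identical in expectation: reduced is a coin flip everywhere
  se <- 3 * sqrt(0.25 / 30)
  expect_lt(abs(res$fracTargetsReduced - res$fracUniverseReduced), se + 0.1)
})

test_that("planted direct targets are recovered exactly from a simulation", {
  sim <- simulateStudy(17)
  wtSpec <- sim$wtPeaks[sim$truth$wtSpecificNames]
  prox <- classifyProximal(wtSpec, sim$geneModels)
  enh <- linkEnhancerTargets(wtSpec, sim$enhancerMap)
  up <- wtOnlyUpGenes(sim$degTable)
  universe <- expressedGenes(sim$expression$wt)
  tgt <- identifyDirectTargets(prox, enh, intersect(up, universe))
  expect_setequal(tgt$gene_id, sim$truth$targets$gene_id)
  # category vocabulary and per-gene uniqueness
  expect_true(all(tgt$category %in% c("utr5", "exon", "upstream", "enhancer")))
  expect_equal(anyDuplicated(tgt$gene_id), 0L)
  expect_equal(sum(table(tgt$category)), nrow(tgt))
})
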