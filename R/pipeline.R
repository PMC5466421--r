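#' @importFrom jsonlite write_json
NULL

.PARAM_DEFAULTS <- list(
  k = 6L, betaMin = 0.6, upstreamBp = 10000L, fpkmMin = 0.5,
  degP = 0.001, alphaBonferroni = 0.01, halfWidth = 1000L,
  nearBp = 4000L, farBp = 6000L, fdr = 0.05, minCoverage = 1L)

#' Assemble and validate a pipeline configuration
#'
#' Bundles input paths and analysis parameters. Defaults are the thresholds
#' the analysis is built around: 6-mers, beta > 0.6 for a methylated CpG,
#' 10 kb upstream windows, FPKM > 0.5 expressed universe, DEG p < 0.001,
#' Bonferroni-adjusted motif cutoff 0.01, +/- 1 kb signal regions with
#' 4-6 kb flanking controls, FDR < 0.05 for gene sets.
#'
#' @param wtPeaks,mutPeaks BED paths of the two peak sets.
#' @param genome FASTA path.
#' @param cytosineReport bismark-style cytosine report path.
#' @param geneModels BED12 path.
#' @param expression 4-condition expression TSV path (t0, t48, t0_aza,
#'   t48_aza).
#' @param degTable DEG TSV path (gene_id, log2fc, p, condition with arms
#'   `wt` and `mut`).
#' @param enhancerMap enhancer link TSV path.
#' @param histoneT0,histoneT48 BED paths of histone-mark reads at 0/48 h.
#' @param outDir output directory.
#' @param geneSets optional GMT path.
#' @param seed integer seed recorded in the report.
#' @param ... parameter overrides (see Details / defaults above).
#' @return a validated config (list, class `pipelineConfig`).
#' @export
pipelineConfig <- function(wtPeaks, mutPeaks, genome, cytosineReport,
                           geneModels, expression, degTable, enhancerMap,
                           histoneT0, histoneT48, outDir,
                           geneSets = NULL, seed = 1L, ...) {
  paths <- list(wtPeaks = wtPeaks, mutPeaks = mutPeaks, genome = genome,
                cytosineReport = cytosineReport, geneModels = geneModels,
                expression = expression, degTable = degTable,
                enhancerMap = enhancerMap, histoneT0 = histoneT0,
                histoneT48 = histoneT48)
  missing <- names(paths)[!vapply(paths, function(p)
    is.character(p) && length(p) == 1L && file.exists(p), logical(1))]
  if (length(missing))
    stop("config validation failed; missing or unreadable input(s): ",
         paste(missing, collapse = ", "))
  params <- utils::modifyList(.PARAM_DEFAULTS, list(...))
  stopifnot(params$k >= 2, params$betaMin > 0, params$betaMin < 1,
            params$upstreamBp > 0, params$fpkmMin >= 0,
            params$degP > 0, params$degP <= 1,
            params$alphaBonferroni > 0, params$alphaBonferroni <= 1,
            params$halfWidth > 0, params$farBp > params$nearBp,
            params$nearBp >= 0, params$fdr > 0, params$fdr <= 1)
  structure(list(paths = paths, geneSets = geneSets, outDir = outDir,
                 seed = as.integer(seed), params = params),
            class = "pipelineConfig")
}

#' Read a flat key = value pipeline configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Path keys match the [pipelineConfig()] arguments; remaining keys are
#' parameter overrides.
#'
#' @param path config file path.
#' @return a validated config via [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("[=:]", lines)])
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  keys <- trimws(vapply(kv, `[[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[[`, character(1), 3L))
  named <- stats::setNames(as.list(vals), keys)
  pathArgs <- c("wtPeaks", "mutPeaks", "genome", "cytosineReport",
                "geneModels", "expression", "degTable", "enhancerMap",
                "histoneT0", "histoneT48", "outDir", "geneSets")
  args <- named[intersect(names(named), pathArgs)]
  rest <- named[setdiff(names(named), c(pathArgs, "seed"))]
  rest <- lapply(rest, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  if ("seed" %in% names(named)) args$seed <- as.integer(named$seed)
  do.call(pipelineConfig, c(args, rest))
}

.stage <- function(name, expr) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages, in order: peak classification; per-peak methylation summaries and
#' the WT-specific vs shared high-methylation contrast; methylated k-mer
#' enrichment and motif construction; proximal and enhancer target
#' assignment with hypergeometric enrichment; optional gene-set enrichment;
#' histone-mark dynamics on the target-supporting peaks; 5-Aza reversal
#' statistics. Writes TSV outputs and a JSON report into the output
#' directory and returns the report.
#'
#' @param config a config from [pipelineConfig()] or [readPipelineConfig()].
#' @return the report, invisibly (a nested list; also written as
#'   `report.json`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  p <- config$params
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  inputs <- .stage("load inputs", {
    list(wt = readBed(config$paths$wtPeaks, kind = "peak"),
         mut = readBed(config$paths$mutPeaks, kind = "peak"),
         genome = Biostrings::readDNAStringSet(config$paths$genome),
         cpgs = readCytosineReport(config$paths$cytosineReport),
         gm = readGeneModelsBed12(config$paths$geneModels),
         expr = readExpressionTable(config$paths$expression),
         deg = readDegTable(config$paths$degTable),
         enh = readEnhancerMap(config$paths$enhancerMap),
         hT0 = readBed(config$paths$histoneT0),
         hT48 = readBed(config$paths$histoneT48))
  })
  names(inputs$genome) <- sub("\\s.*$", "", names(inputs$genome))
  suppressWarnings(validateChromosomes(inputs$wt, inputs$mut,
                                       c("WT peaks", "mutant peaks")))

  cls <- .stage("classify peaks", {
    classifyPeaks(inputs$wt, inputs$mut)
  })
  writePeakClassification(cls, config$outDir)

  meth <- .stage("methylome summaries", {
    rmSpec <- regionMethylation(wtSpecificPeaks(cls), inputs$cpgs,
                                p$minCoverage, p$betaMin)
    rmShared <- regionMethylation(sharedPeaks(cls), inputs$cpgs,
                                  p$minCoverage, p$betaMin)
    writeRegionMethylation(rmSpec,
                           file.path(config$outDir, "methylation_wt_specific.tsv"))
    writeRegionMethylation(rmShared,
                           file.path(config$outDir, "methylation_shared.tsv"))
    cmp <- compareMethylationFractions(
      sum(mcols(rmSpec)$high), sum(mcols(rmSpec)$nCpg > 0),
      sum(mcols(rmShared)$high), sum(mcols(rmShared)$nCpg > 0))
    list(rmSpec = rmSpec, rmShared = rmShared,
         fracHighSpecific = highMethylationFraction(rmSpec),
         fracHighShared = highMethylationFraction(rmShared),
         fisherP = cmp$p)
  })

  motifs <- .stage("motif enrichment", {
    allPeaks <- c(wtSpecificPeaks(cls), sharedPeaks(cls),
                  mutSpecificPeaks(cls))
    allKmers <- extractMethylatedKmers(allPeaks, inputs$genome, inputs$cpgs,
                                       p$k, p$betaMin)
    fgKmers <- allKmers[names(wtSpecificPeaks(cls))]
    enr <- kmerEnrichment(fgKmers, allKmers, p$alphaBonferroni)
    writeKmerStats(enr, file.path(config$outDir, "kmer_enrichment.tsv"))
    pwm <- NULL
    if (length(enr$selected)) {
      sel <- enr$stats[enr$stats$kmer %in% enr$selected, , drop = FALSE]
      pwm <- buildPwm(sel$kmer, sel$fgPeaks)
      writeMemeMotif(pwm, file.path(config$outDir, "motif.meme"))
    }
    list(enrichment = enr, pwm = pwm,
         topKmer = if (nrow(enr$stats)) enr$stats$kmer[1] else NA_character_,
         consensus = if (!is.null(pwm)) pwmConsensus(pwm) else NA_character_)
  })

  targets <- .stage("target assignment", {
    universe <- expressedGenes(inputs$expr, p$fpkmMin)
    upGenes <- wtOnlyUpGenes(inputs$deg, pCutoff = p$degP)
    prox <- classifyProximal(wtSpecificPeaks(cls), inputs$gm, p$upstreamBp)
    enh <- linkEnhancerTargets(wtSpecificPeaks(cls), inputs$enh)
    tgt <- identifyDirectTargets(prox, enh, intersect(upGenes, universe))
    assocGenes <- intersect(unique(c(prox$gene_id, enh$gene_id)), universe)
    enrich <- targetEnrichment(
      k = nrow(tgt), n = max(length(assocGenes), 1L),
      K = max(length(intersect(upGenes, universe)), 1L),
      N = length(universe))
    write.table(tgt, file.path(config$outDir, "direct_targets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(table = tgt, proximal = prox, enhancer = enh,
         universeSize = length(universe), upGenes = upGenes,
         enrichment = enrich)
  })

  gse <- NULL
  if (!is.null(config$geneSets)) {
    gse <- .stage("gene-set enrichment", {
      sets <- readGmt(config$geneSets)
      universe <- expressedGenes(inputs$expr, p$fpkmMin)
      res <- geneSetEnrichment(intersect(targets$table$gene_id, universe),
                               sets, universe, p$fdr)
      write.table(res, file.path(config$outDir, "gene_set_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
  }

  histone <- .stage("histone dynamics", {
    supPeaks <- unique(unlist(strsplit(targets$table$peaks, ",")))
    supPeaks <- supPeaks[supPeaks %in% names(wtSpecificPeaks(cls))]
    anchors <- if (length(supPeaks)) wtSpecificPeaks(cls)[supPeaks]
               else wtSpecificPeaks(cls)
    hd <- histoneDynamics(anchors, inputs$hT0, inputs$hT48,
                          p$halfWidth, p$nearBp, p$farBp)
    sig <- hd$regions
    df <- data.frame(chrom = as.character(seqnames(sig)),
                     start = start(sig) - 1L, end = end(sig),
                     name = names(sig),
                     rpm_log2_t0 = mcols(sig)$rpmLog2T0,
                     rpm_log2_t48 = mcols(sig)$rpmLog2T48,
                     delta = mcols(sig)$delta,
                     delta_norm = mcols(sig)$deltaNorm)
    write.table(df, file.path(config$outDir, "histone_signal.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hd
  })

  aza <- .stage("5-Aza reversal", {
    universe <- expressedGenes(inputs$expr, p$fpkmMin)
    exprU <- inputs$expr[inputs$expr$gene_id %in% universe, , drop = FALSE]
    tgtIn <- intersect(targets$table$gene_id, universe)
    if (length(tgtIn)) azaReversalStats(exprU, tgtIn) else NULL
  })

  report <- list(
    parameters = c(p, seed = config$seed),
    inputs = lapply(config$paths, normalizePath),
    peaks = list(nWt = length(sharedPeaks(cls)) + length(wtSpecificPeaks(cls)),
                 nMut = length(sharedPeaks(cls)) + length(mutSpecificPeaks(cls)),
                 nShared = length(sharedPeaks(cls)),
                 nWtSpecific = length(wtSpecificPeaks(cls)),
                 nMutSpecific = length(mutSpecificPeaks(cls))),
    methylation = list(fracHighWtSpecific = meth$fracHighSpecific,
                       fracHighShared = meth$fracHighShared,
                       fisherP = meth$fisherP),
    motifs = list(nTested = nrow(motifs$enrichment$stats),
                  nSelected = length(motifs$enrichment$selected),
                  topKmer = motifs$topKmer,
                  topP = if (nrow(motifs$enrichment$stats))
                    motifs$enrichment$stats$p[1] else NA_real_,
                  consensus = motifs$consensus),
    targets = list(nTargets = nrow(targets$table),
                   byCategory = as.list(table(targets$table$category)),
                   universeSize = targets$universeSize,
                   nUpWtOnly = length(targets$upGenes),
                   foldEnrichment = targets$enrichment$foldEnrichment,
                   enrichmentP = targets$enrichment$p),
    geneSets = if (!is.null(gse)) list(nSignificant = sum(gse$significant))
               else NULL,
    histone = histone$stats[c("n", "kUp", "kDown", "fracUp", "fracDown",
                              "pUp", "pDown", "tailUp", "tailDown")],
    aza = aza)
  write_json(report, file.path(config$outDir, "report.json"),
             auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(report)
}

#' Simulate a study, write its files, run the pipeline, score recovery
#'
#' The closed-loop driver: generates a synthetic study at the given seed,
#' writes every input in its on-disk format, runs [runPipeline()] on those
#' files, and compares the results against the planted truth.
#'
#' @param seed integer seed.
#' @param dir working directory for inputs and outputs (default a tempdir).
#' @param params overrides passed to [simulateStudy()].
#' @param ... parameter overrides passed to [pipelineConfig()].
#' @return list with `report`, `recovery` (flags and rates vs the planted
#'   truth), `sim` and `config`.
#' @export
runSyntheticPipeline <- function(seed, dir = tempfile("synthstudy"),
                                 params = list(), ...) {
  sim <- simulateStudy(seed, params)
  paths <- writeStudy(sim, dir)
  config <- pipelineConfig(
    wtPeaks = paths[["wtPeaks"]], mutPeaks = paths[["mutPeaks"]],
    genome = paths[["genome"]], cytosineReport = paths[["cytosineReport"]],
    geneModels = paths[["geneModels"]], expression = paths[["expressionWt"]],
    degTable = paths[["degTable"]], enhancerMap = paths[["enhancerMap"]],
    histoneT0 = paths[["histoneT0"]], histoneT48 = paths[["histoneT48"]],
    outDir = file.path(dir, "out"), seed = seed, ...)
  report <- runPipeline(config)
  recl <- classifyPeaks(readBed(paths[["wtPeaks"]], "peak"),
                        readBed(paths[["mutPeaks"]], "peak"))
  truth <- sim$truth
  tgt <- utils::read.table(file.path(dir, "out", "direct_targets.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  recovery <- list(
    partitionExact =
      setequal(names(wtSpecificPeaks(recl)), truth$wtSpecificNames) &&
      setequal(names(sharedPeaks(recl)), truth$sharedNames) &&
      setequal(names(mutSpecificPeaks(recl)), truth$mutSpecificNames),
    motifTop = identical(report$motifs$topKmer, truth$plantedMotif),
    motifSelected = truth$plantedMotif %in%
      utils::read.table(file.path(dir, "out", "kmer_enrichment.tsv"),
                        header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)$kmer,
    targetRecall = mean(truth$targets$gene_id %in% tgt$gene_id),
    targetFalse = sum(!(tgt$gene_id %in% truth$targets$gene_id)),
    histoneFracUp = report$histone$fracUp,
    histoneUpSignificant = report$histone$tailUp < 0.05)
  list(report = report, recovery = recovery, sim = sim, config = config)
}
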