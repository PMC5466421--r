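#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList
NULL

#' Partition of two ChIP peak sets into shared and condition-specific peaks
#'
#' Holds the result of comparing a wild-type (WT) factor's ChIP-seq peaks
#' with those of a methyl-binding-deficient mutant. A WT peak overlapping at
#' least one mutant peak is *shared*; the remaining WT peaks are
#' *WT-specific* and the remaining mutant peaks *mutant-specific*. The three
#' sets partition the input peaks: every WT peak is in exactly one of
#' shared/WT-specific, every mutant peak in exactly one of
#' shared/mutant-specific.
#'
#' @slot shared [GenomicRanges::GRanges] of WT peaks that overlap a mutant peak.
#' @slot wtSpecific [GenomicRanges::GRanges] of WT peaks with no mutant overlap.
#' @slot mutSpecific [GenomicRanges::GRanges] of mutant peaks with no WT overlap.
#'
#' @seealso [classifyPeaks()]
#' @exportClass PeakClassification
setClass("PeakClassification",
  slots = c(shared = "GRanges", wtSpecific = "GRanges", mutSpecific = "GRanges")
)

setValidity("PeakClassification", function(object) {
  msg <- character()
  nm <- list(
    shared = names(object@shared),
    wtSpecific = names(object@wtSpecific),
    mutSpecific = names(object@mutSpecific)
  )
  for (s in names(nm)) {
    if (length(nm[[s]]) && anyDuplicated(nm[[s]]))
      msg <- c(msg, sprintf("duplicated peak names within '%s'", s))
  }
  if (length(intersect(nm$shared, nm$wtSpecific)))
    msg <- c(msg, "shared and WT-specific sets share peak names")
  if (length(intersect(nm$shared, nm$mutSpecific)))
    msg <- c(msg, "shared and mutant-specific sets share peak names")
  if (length(intersect(nm$wtSpecific, nm$mutSpecific)))
    msg <- c(msg, "WT-specific and mutant-specific sets share peak names")
  if (length(msg)) msg else TRUE
})

#' @describeIn PeakClassification-class peaks bound in both conditions
#' @param object,x a `PeakClassification`
#' @export
sharedPeaks <- function(object) object@shared

#' @describeIn PeakClassification-class peaks bound by the wild type only
#' @export
wtSpecificPeaks <- function(object) object@wtSpecific

#' @describeIn PeakClassification-class peaks bound by the mutant only
#' @export
mutSpecificPeaks <- function(object) object@mutSpecific

setMethod("show", "PeakClassification", function(object) {
  nWT <- length(object@shared) + length(object@wtSpecific)
  nMut <- length(object@shared) + length(object@mutSpecific)
  cat("PeakClassification\n")
  cat(sprintf("  WT peaks:      %d (%d shared + %d WT-specific)\n",
              nWT, length(object@shared), length(object@wtSpecific)))
  cat(sprintf("  mutant peaks:  %d (%d shared + %d mutant-specific)\n",
              nMut, length(object@shared), length(object@mutSpecific)))
  invisible(NULL)
})

#' Gene models with exon and 5'-UTR structure
#'
#' Minimal stranded gene models used for proximal peak-to-gene assignment.
#' The transcription start site (TSS) is the 5' end of the gene span on its
#' strand. Exons and 5'-UTR intervals are kept per gene; both must lie
#' within the gene span.
#'
#' @slot genes [GenomicRanges::GRanges] of gene spans, named by gene id, stranded.
#' @slot exons [GenomicRanges::GRangesList] of exons, one element per gene.
#' @slot utr5 [GenomicRanges::GRangesList] of 5'-UTR intervals, one element per gene.
#'
#' @seealso [readGeneModelsBed12()], [classifyProximal()]
#' @exportClass GeneModelSet
setClass("GeneModelSet",
  slots = c(genes = "GRanges", exons = "GRangesList", utr5 = "GRangesList")
)

setValidity("GeneModelSet", function(object) {
  msg <- character()
  ids <- names(object@genes)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "gene spans must be uniquely named by gene id")
  if (!identical(names(object@exons), ids) || !identical(names(object@utr5), ids))
    msg <- c(msg, "exons and utr5 lists must be named identically to genes")
  if (any(S4Vectors::runValue(GenomicRanges::strand(object@genes)) == "*"))
    msg <- c(msg, "gene models must be stranded")
  if (length(object@genes)) {
    within <- vapply(seq_along(object@genes), function(i) {
      ex <- object@exons[[i]]
      length(ex) == 0L || all(
        as.character(GenomicRanges::seqnames(ex)) ==
          as.character(GenomicRanges::seqnames(object@genes[i])) &
        GenomicRanges::start(ex) >= GenomicRanges::start(object@genes[i]) &
        GenomicRanges::end(ex) <= GenomicRanges::end(object@genes[i]))
    }, logical(1))
    if (!all(within)) msg <- c(msg, "exons must lie within their gene span")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModelSet-class gene identifiers
#' @param object a `GeneModelSet`
#' @export
geneIds <- function(object) names(object@genes)

#' @describeIn GeneModelSet-class stranded gene spans as a `GRanges`
#' @export
geneRanges <- function(object) object@genes

#' @describeIn GeneModelSet-class exons as a `GRangesList` named by gene
#' @export
geneExons <- function(object) object@exons

#' @describeIn GeneModelSet-class 5'-UTR intervals as a `GRangesList`
#' @export
geneUtr5 <- function(object) object@utr5

#' @describeIn GeneModelSet-class 1-based TSS position per gene (start of the
#'   span on '+', end on '-')
#' @export
geneTss <- function(object) {
  g <- object@genes
  ifelse(as.character(GenomicRanges::strand(g)) == "+",
         GenomicRanges::start(g), GenomicRanges::end(g))
}

setMethod("show", "GeneModelSet", function(object) {
  cat(sprintf("GeneModelSet with %d genes on %d sequence(s)\n",
              length(object@genes),
              length(unique(as.character(GenomicRanges::seqnames(object@genes))))))
  invisible(NULL)
})

#' Position weight matrix built from enriched methylated k-mers
#'
#' Per-position base frequencies (rows A, C, G, T; columns sum to 1) obtained
#' by stacking selected k-mers aligned at their CpG dinucleotide, each k-mer
#' weighted by the number of foreground peaks containing it. Columns not
#' covered by every k-mer are normalized over the covering weight only.
#'
#' @slot profile numeric matrix, 4 rows named A/C/G/T, one column per motif
#'   position; every column sums to 1.
#' @slot support total k-mer occurrence weight behind the matrix.
#'
#' @seealso [buildPwm()], [pwmInformationContent()]
#' @exportClass MotifPwm
setClass("MotifPwm", slots = c(profile = "matrix", support = "numeric"))

setValidity("MotifPwm", function(object) {
  msg <- character()
  if (!identical(rownames(object@profile), c("A", "C", "G", "T")))
    msg <- c(msg, "profile rows must be named A, C, G, T")
  cs <- colSums(object@profile)
  if (any(abs(cs - 1) > 1e-9))
    msg <- c(msg, "every profile column must sum to 1")
  if (any(object@profile < 0))
    msg <- c(msg, "profile frequencies must be non-negative")
  if (length(object@support) != 1L || object@support <= 0)
    msg <- c(msg, "support must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifPwm-class the 4 x width frequency matrix
#' @param object a `MotifPwm`
#' @export
pwmMatrix <- function(object) object@profile

#' @describeIn MotifPwm-class total contributing k-mer weight
#' @export
pwmSupport <- function(object) object@support

#' @describeIn MotifPwm-class majority-base consensus string
#' @export
pwmConsensus <- function(object) {
  paste(rownames(object@profile)[apply(object@profile, 2, which.max)],
        collapse = "")
}

setMethod("show", "MotifPwm", function(object) {
  cat(sprintf("MotifPwm  width %d  support %g  consensus %s\n",
              ncol(object@profile), object@support, pwmConsensus(object)))
  print(round(object@profile, 3))
  invisible(NULL)
})
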