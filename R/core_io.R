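#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#'   countOverlaps reduce mcols mcols<- strand<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits DataFrame
#' @importFrom utils read.table write.table
NULL

## GRanges is the internal coordinate currency (1-based, closed). BED input
## (0-based, half-open) is converted on read and back on write; cytosine
## reports are already 1-based.

.splitTabLines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a BED file of genomic intervals or peaks
#'
#' Reads BED3/BED6 into a `GRanges`, converting BED's 0-based half-open
#' coordinates to the 1-based closed convention used internally. File order
#' is preserved. For `kind = "peak"` the name column (4) must be present and
#' unique; the score column (5) is read when present and defaults to 0.
#' BED strand "." becomes the unspecified strand `"*"`.
#'
#' @param path path to a tab-separated BED file.
#' @param kind `"interval"` for plain regions, `"peak"` to require unique names.
#' @return a `GRanges`; peaks carry `name` (also set as `names()`) and `score`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t500\t600"), bed)
#' readBed(bed)
#' @export
readBed <- function(path, kind = c("interval", "peak")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("BED file not found: ", path)
  fields <- .splitTabLines(path)
  if (!length(fields)) {
    gr <- GRanges()
    if (kind == "peak") mcols(gr)$score <- numeric()
    return(gr)
  }
  n <- length(fields)
  chrom <- character(n); s0 <- integer(n); e0 <- integer(n)
  nm <- character(n); score <- numeric(n); str <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d: fewer than 3 columns", i))
    st <- suppressWarnings(as.integer(f[2]))
    en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en))
      stop(sprintf("malformed BED line %d: non-integer coordinates", i))
    if (st < 0L)
      stop(sprintf("malformed BED line %d: negative start", i))
    if (en <= st)
      stop(sprintf("malformed BED line %d: end <= start", i))
    if (!nzchar(f[1]))
      stop(sprintf("malformed BED line %d: empty chromosome name", i))
    chrom[i] <- f[1]; s0[i] <- st; e0[i] <- en
    nm[i] <- if (length(f) >= 4L && nzchar(f[4])) f[4] else sprintf("region_%d", i)
    score[i] <- if (length(f) >= 5L) {
      v <- suppressWarnings(as.numeric(f[5])); if (is.na(v)) 0 else v
    } else 0
    str[i] <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "*"
  }
  if (kind == "peak" && anyDuplicated(nm))
    stop("duplicated peak names in ", path)
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0), strand = str)
  names(gr) <- nm
  mcols(gr)$name <- nm
  mcols(gr)$score <- score
  gr
}

#' Write intervals or peaks as BED
#'
#' Inverse of [readBed()]: emits BED6 (name, score, strand; strand `"*"`
#' written as `"."`), converting back to 0-based half-open coordinates.
#'
#' @param gr a `GRanges`; `name`/`score` metadata columns are used if present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
        else if (!is.null(names(gr))) names(gr)
        else sprintf("region_%d", seq_along(gr))
  sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else rep(0, length(gr))
  st <- as.character(strand(gr))
  st[st == "*"] <- "."
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   nm, sc, st)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bismark-style cytosine report
#'
#' Expects tab-separated columns chrom, position (1-based), strand (+/-),
#' count of methylated reads, count of unmethylated reads, context. Only
#' CpG-context rows are retained; CHG/CHH rows are skipped. Returns
#' width-1 stranded `GRanges` with `nMeth`, `nUnmeth` and `beta` metadata
#' columns (`beta` is `NA` at zero coverage).
#'
#' @param path path to the report.
#' @return a `GRanges` of CpG cytosines.
#' @export
readCytosineReport <- function(path) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  fields <- .splitTabLines(path)
  keep <- list()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 6L)
      stop(sprintf("malformed cytosine report line %d: fewer than 6 columns", i))
    if (f[6] != "CpG") next
    pos <- suppressWarnings(as.integer(f[2]))
    nm <- suppressWarnings(as.integer(f[4]))
    nu <- suppressWarnings(as.integer(f[5]))
    if (is.na(pos) || pos < 1L)
      stop(sprintf("malformed cytosine report line %d: bad position", i))
    if (!(f[3] %in% c("+", "-")))
      stop(sprintf("malformed cytosine report line %d: unknown strand '%s'",
                   i, f[3]))
    if (is.na(nm) || is.na(nu) || nm < 0L || nu < 0L)
      stop(sprintf("malformed cytosine report line %d: negative or non-integer counts", i))
    keep[[length(keep) + 1L]] <- list(f[1], pos, f[3], nm, nu)
  }
  if (!length(keep)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(nMeth = integer(), nUnmeth = integer(),
                           beta = numeric())
    return(gr)
  }
  chrom <- vapply(keep, `[[`, character(1), 1L)
  pos <- vapply(keep, `[[`, integer(1), 2L)
  str <- vapply(keep, `[[`, character(1), 3L)
  nm <- vapply(keep, `[[`, integer(1), 4L)
  nu <- vapply(keep, `[[`, integer(1), 5L)
  gr <- GRanges(chrom, IRanges(pos, pos), strand = str)
  cov <- nm + nu
  mcols(gr) <- DataFrame(nMeth = nm, nUnmeth = nu,
                         beta = ifelse(cov > 0, nm / cov, NA_real_))
  gr
}

#' Write CpG sites as a bismark-style cytosine report
#'
#' @param cpgs width-1 `GRanges` with `nMeth` and `nUnmeth` metadata columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCytosineReport <- function(cpgs, path) {
  df <- data.frame(as.character(seqnames(cpgs)), start(cpgs),
                   as.character(strand(cpgs)),
                   mcols(cpgs)$nMeth, mcols(cpgs)$nUnmeth, "CpG")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Map each query interval to the subject intervals it overlaps
#'
#' Two intervals overlap iff they are on the same chromosome and share at
#' least one base. Under the half-open BED convention intervals that merely
#' abut never overlap. Strand is ignored.
#'
#' @param query,subject `GRanges`.
#' @return a list, one integer vector of subject indices per query interval.
#' @export
overlapMap <- function(query, subject) {
  hits <- findOverlaps(query, subject, minoverlap = 1L, ignore.strand = TRUE)
  out <- rep(list(integer()), length(query))
  if (length(hits)) {
    sp <- split(subjectHits(hits), queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  out
}

#' Warn when chromosome names are private to one interval set
#'
#' Chromosome matching is exact string equality (no "chr" aliasing); this
#' check surfaces inputs whose naming schemes silently fail to overlap.
#'
#' @param a,b `GRanges`.
#' @param labels labels used in the warning text.
#' @return invisibly, the character vector of one-sided chromosome names.
#' @export
validateChromosomes <- function(a, b, labels = c("first", "second")) {
  ca <- unique(as.character(seqnames(a)))
  cb <- unique(as.character(seqnames(b)))
  only <- c(setdiff(ca, cb), setdiff(cb, ca))
  if (length(only) && length(ca) && length(cb))
    warning(sprintf("chromosomes present in only one input (%s vs %s): %s",
                    labels[1], labels[2], paste(only, collapse = ", ")))
  invisible(only)
}

#' Read BED12 gene models
#'
#' Parses the exon block structure of BED12 into a [GeneModelSet-class].
#' 5'-UTRs are derived from the thickStart/thickEnd (CDS) columns: the
#' exonic sequence 5' of the CDS on the gene's strand. Records with
#' `thickStart == thickEnd` (non-coding) get no 5'-UTR.
#'
#' @param path path to a BED12 file.
#' @return a `GeneModelSet`.
#' @export
readGeneModelsBed12 <- function(path) {
  if (!file.exists(path)) stop("BED12 file not found: ", path)
  fields <- .splitTabLines(path)
  genes <- list(); exons <- list(); utr5 <- list(); ids <- character()
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 12L)
      stop(sprintf("malformed BED12 line %d: fewer than 12 columns", i))
    s0 <- as.integer(f[2]); e0 <- as.integer(f[3])
    if (is.na(s0) || is.na(e0) || e0 <= s0)
      stop(sprintf("malformed BED12 line %d: bad gene span", i))
    if (!(f[6] %in% c("+", "-")))
      stop(sprintf("malformed BED12 line %d: gene models must be stranded", i))
    nBlocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    starts <- as.integer(strsplit(f[12], ",")[[1]])
    if (length(sizes) != nBlocks || length(starts) != nBlocks)
      stop(sprintf("malformed BED12 line %d: blockCount mismatch", i))
    exS0 <- s0 + starts
    exE0 <- exS0 + sizes
    ex <- GRanges(f[1], IRanges(exS0 + 1L, exE0), strand = f[6])
    thickS0 <- as.integer(f[7]); thickE0 <- as.integer(f[8])
    u5 <- GRanges()
    if (!is.na(thickS0) && !is.na(thickE0) && thickE0 > thickS0) {
      u5 <- if (f[6] == "+") {
        r <- IRanges::restrict(IRanges::ranges(ex), end = thickS0)
        GRanges(f[1], r[IRanges::width(r) > 0], strand = "+")
      } else {
        r <- IRanges::restrict(IRanges::ranges(ex), start = thickE0 + 1L)
        GRanges(f[1], r[IRanges::width(r) > 0], strand = "-")
      }
    }
    ids <- c(ids, f[4])
    genes[[length(genes) + 1L]] <- GRanges(f[1], IRanges(s0 + 1L, e0),
                                           strand = f[6])
    exons[[length(exons) + 1L]] <- ex
    utr5[[length(utr5) + 1L]] <- u5
  }
  if (anyDuplicated(ids)) stop("duplicated gene ids in ", path)
  g <- suppressWarnings(do.call(c, genes))  # genes may span disjoint chroms
  names(g) <- ids
  exl <- GRangesList(exons); names(exl) <- ids
  ul <- GRangesList(utr5); names(ul) <- ids
  new("GeneModelSet", genes = g, exons = exl, utr5 = ul)
}

#' Read an expression table (gene id + one FPKM column per condition)
#'
#' The file must have a header row whose first column is `gene_id`. Gene ids
#' must be unique; FPKM values must be non-negative.
#'
#' @param path path to a tab-separated table.
#' @return a `data.frame` with character `gene_id` and numeric condition columns.
#' @export
readExpressionTable <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!("gene_id" %in% colnames(df)))
    stop("expression table missing required column: gene_id")
  if (ncol(df) < 2L)
    stop("expression table has no condition columns")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicated gene_id in expression table: ",
         paste(unique(dup), collapse = ", "))
  num <- setdiff(colnames(df), "gene_id")
  for (cn in num) {
    df[[cn]] <- as.numeric(df[[cn]])
    if (anyNA(df[[cn]]) || any(df[[cn]] < 0))
      stop("expression column '", cn, "' must be non-negative numeric")
  }
  df
}

#' Read an enhancer-to-gene link table
#'
#' Tab-separated columns: chrom, start (0-based), end, gene_id, and an
#' optional confidence. Returns a `GRanges` of enhancer intervals with
#' `gene_id` and `confidence` metadata.
#'
#' @param path path to the table.
#' @return a `GRanges`.
#' @export
readEnhancerMap <- function(path) {
  if (!file.exists(path)) stop("enhancer map not found: ", path)
  fields <- .splitTabLines(path)
  if (!length(fields)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character(), confidence = numeric())
    return(gr)
  }
  n <- length(fields)
  chrom <- character(n); s0 <- integer(n); e0 <- integer(n)
  gid <- character(n); conf <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 4L)
      stop(sprintf("malformed enhancer map line %d: missing required column gene_id", i))
    s0[i] <- as.integer(f[2]); e0[i] <- as.integer(f[3])
    if (is.na(s0[i]) || is.na(e0[i]) || e0[i] <= s0[i])
      stop(sprintf("malformed enhancer map line %d: bad interval", i))
    if (!nzchar(f[4]))
      stop(sprintf("malformed enhancer map line %d: empty gene_id", i))
    chrom[i] <- f[1]; gid[i] <- f[4]
    conf[i] <- if (length(f) >= 5L) as.numeric(f[5]) else NA_real_
  }
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0))
  mcols(gr) <- DataFrame(gene_id = gid, confidence = conf)
  gr
}

#' Read a differential-expression table
#'
#' Tab-separated with header; required columns `gene_id`, `log2fc`, `p`,
#' `condition` (the comparison arm, e.g. `wt` / `mut`).
#'
#' @param path path to the table.
#' @return a `data.frame`.
#' @export
readDegTable <- function(path) {
  if (!file.exists(path)) stop("DEG table not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "log2fc", "p", "condition")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("DEG table missing required column: ", paste(miss, collapse = ", "))
  df
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  fields <- .splitTabLines(path)
  sets <- lapply(fields, function(f) {
    if (length(f) < 3L) stop("malformed GMT line: fewer than 3 columns")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}
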