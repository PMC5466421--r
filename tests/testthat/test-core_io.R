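test_that("BED parsing converts coordinates and preserves order, strand, score", {
  f <- writeTempBed(c("chr1\t100\t200", "chr1\t500\t600"))
  gr <- readBed(f)
  expect_length(gr, 2)
  expect_equal(start(gr), c(101L, 501L))  # 0-based half-open -> 1-based closed
  expect_equal(end(gr), c(200L, 600L))

  f6 <- writeTempBed("chr2\t10\t20\tpk1\t7.5\t-")
  p <- readBed(f6, kind = "peak")
  expect_equal(names(p), "pk1")
  expect_equal(mcols(p)$score, 7.5)
  expect_equal(as.character(strand(p)), "-")

  fd <- writeTempBed("chr1\t5\t9\tx\t1\t.")
  expect_equal(as.character(strand(readBed(fd))), "*")
})

test_that("malformed BED lines raise errors naming the line", {
  expect_error(readBed(writeTempBed("chr1\t200\t100")), "line 1")
  expect_error(readBed(writeTempBed(c("chr1\t1\t2", "chr1\tx\t9"))), "line 2")
  expect_error(readBed(writeTempBed("chr1\t100")), "line 1")
  expect_error(readBed(writeTempBed(c("chr1\t1\t5\ta", "chr1\t1\t5\ta")),
                       kind = "peak"), "duplicated")
})

test_that("interval/peak sets round-trip through BED", {
  set.seed(11)
  df <- randomIntervals(40)
  gr <- bedToGRanges(df)
  names(gr) <- sprintf("p%02d", seq_along(gr))
  mcols(gr)$name <- names(gr)
  mcols(gr)$score <- round(runif(40) * 100, 3)
  f <- tempfile(fileext = ".bed")
  writeBed(gr, f)
  back <- readBed(f, kind = "peak")
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(as.character(seqnames(back)), as.character(seqnames(gr)))
  expect_equal(names(back), names(gr))
  expect_equal(mcols(back)$score, mcols(gr)$score)
})

test_that("cytosine report parsing keeps CpG rows only and validates fields", {
  f <- tempfile()
  writeLines(c("chr1\t11\t+\t3\t1\tCpG",
               "chr1\t50\t+\t5\t0\tCHH",
               "chr1\t80\t-\t0\t4\tCpG"), f)
  cpgs <- readCytosineReport(f)
  expect_length(cpgs, 2)
  expect_equal(start(cpgs), c(11L, 80L))
  expect_equal(mcols(cpgs)$nMeth, c(3L, 0L))
  expect_equal(mcols(cpgs)$beta, c(0.75, 0))

  empty <- tempfile(); file.create(empty)
  expect_length(readCytosineReport(empty), 0)

  bad1 <- tempfile(); writeLines("chr1\t11\t+\t-3\t1\tCpG", bad1)
  expect_error(readCytosineReport(bad1), "negative")
  bad2 <- tempfile(); writeLines("chr1\t11\t?\t3\t1\tCpG", bad2)
  expect_error(readCytosineReport(bad2), "strand")
})

test_that("cytosine report round-trips", {
  cpgs <- makeCpgs("chr1", c(4, 5, 90), c("+", "-", "+"),
                   c(9, 9, 2), c(1, 1, 8))
  f <- tempfile()
  writeCytosineReport(cpgs, f)
  back <- readCytosineReport(f)
  expect_equal(start(back), start(cpgs))
  expect_equal(as.character(strand(back)), as.character(strand(cpgs)))
  expect_equal(mcols(back)$nMeth, mcols(cpgs)$nMeth)
})

test_that("overlapMap matches the all-pairs brute force, incl. boundary cases", {
  # half-open abutment never overlaps
  a <- bedToGRanges(data.frame(chrom = "chr1", start = 100, end = 200))
  b <- bedToGRanges(data.frame(chrom = "chr1", start = 200, end = 300))
  expect_equal(overlapMap(a, b), list(integer()))
  b2 <- bedToGRanges(data.frame(chrom = "chr1", start = 150, end = 250))
  expect_equal(overlapMap(a, b2), list(1L))

  set.seed(42)
  for (rep in 1:5) {
    dfa <- randomIntervals(50, chroms = c("chr1", "chr2", "chrX"))
    dfb <- randomIntervals(50, chroms = c("chr1", "chr2", "chrX"))
    got <- overlapMap(bedToGRanges(dfa), bedToGRanges(dfb))
    gotPairs <- do.call(rbind, lapply(seq_along(got), function(i)
      if (length(got[[i]])) cbind(i, sort(got[[i]])) else NULL))
    want <- bruteOverlapPairs(dfa, dfb)
    if (is.null(gotPairs)) gotPairs <- matrix(integer(), ncol = 2)
    dimnames(gotPairs) <- NULL
    expect_equal(gotPairs, want)
  }
  # empty sets
  expect_equal(overlapMap(GRanges(), bedToGRanges(dfa)), list())
  expect_equal(overlapMap(bedToGRanges(dfa), GRanges()),
               rep(list(integer()), 50))
})

test_that("BED12 gene models parse blocks, 5'UTRs and round-trip", {
  # + strand gene: span 1000-3000, 3 exons, CDS starts at 1300
  f <- tempfile()
  writeLines(paste("chr1", 1000, 3000, "GENEA", 0, "+",
                   1300, 2800, "0", 3,
                   "400,300,500,", "0,800,1500,", sep = "\t"), f)
  gm <- readGeneModelsBed12(f)
  expect_equal(geneIds(gm), "GENEA")
  expect_length(geneExons(gm)[["GENEA"]], 3)
  u5 <- geneUtr5(gm)[["GENEA"]]
  expect_equal(start(u5), 1001L)  # exonic prefix before CDS
  expect_equal(end(u5), 1300L)
  expect_equal(geneTss(gm), 1001L)

  # - strand gene: TSS at the right end
  f2 <- tempfile()
  writeLines(paste("chr1", 5000, 8000, "GENEB", 0, "-",
                   5000, 7500, "0", 2,
                   "1000,1000,", "0,2000,", sep = "\t"), f2)
  gm2 <- readGeneModelsBed12(f2)
  expect_equal(geneTss(gm2), 8000L)
  u5b <- geneUtr5(gm2)[["GENEB"]]
  expect_equal(start(u5b), 7501L)
  expect_equal(end(u5b), 8000L)

  out <- tempfile()
  writeGeneModelsBed12(gm, out)
  back <- readGeneModelsBed12(out)
  expect_equal(start(geneExons(back)[["GENEA"]]),
               start(geneExons(gm)[["GENEA"]]))
  expect_equal(start(geneUtr5(back)[["GENEA"]]),
               start(geneUtr5(gm)[["GENEA"]]))
})

test_that("expression and enhancer tables enforce their schemas", {
  f <- tempfile()
  writeLines(c("gene_id\tt0\tt48", "G1\t1.5\t3.0", "G2\t0.1\t0.2"), f)
  expr <- readExpressionTable(f)
  expect_equal(expr$gene_id, c("G1", "G2"))
  expect_equal(expr$t48, c(3.0, 0.2))

  dup <- tempfile()
  writeLines(c("gene_id\tt0", "G1\t1", "G1\t2"), dup)
  expect_error(readExpressionTable(dup), "duplicated gene_id")

  noCol <- tempfile()
  writeLines(c("gene\tt0", "G1\t1"), noCol)
  expect_error(readExpressionTable(noCol), "gene_id")

  em <- tempfile()
  writeLines("chr1\t1000\t2000\tGENE7\t1.0", em)
  links <- readEnhancerMap(em)
  expect_equal(mcols(links)$gene_id, "GENE7")
  expect_equal(start(links), 1001L)
  bad <- tempfile(); writeLines("chr1\t1000\t2000", bad)
  expect_error(readEnhancerMap(bad), "gene_id")
})
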