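Package: mCpGtargets
Title: Methyl-CpG-Dependent Transcription-Factor Binding and Direct Target
    Gene Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies genes directly transactivated through methyl-CpG
    dependent transcription-factor binding by integrating ChIP-seq peak
    sets from a wild-type factor and a methyl-binding-deficient mutant
    with a whole-genome bisulfite methylome. Provides shared versus
    WT-specific peak classification, per-region beta-value summaries,
    methylated 6-mer motif enrichment under a hypergeometric null with
    Bonferroni correction, proximal and enhancer-linked target gene
    assignment with hypergeometric enrichment statistics, demethylating
    agent (5-Aza) reversal analysis, and a control-normalized log2-RPM
    histone-mark dynamics statistic with exact binomial direction tests.
    Includes seeded synthetic-data generators with planted ground truth
    and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Epigenetics, DNAMethylation, ChIPSeq, MotifDiscovery,
    Transcription, GeneRegulation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
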