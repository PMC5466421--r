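---
title: "Identifying direct targets of methyl-CpG-dependent transcription-factor binding"
author: "mCpGtargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying direct targets of methyl-CpG-dependent transcription-factor binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mCpGtargets)
```

## The analysis problem

A transcription factor that reads methylated CpG binds a set of genomic loci
that an engineered mutant, deficient only in methyl-CpG binding, cannot.
The analysis this package implements reconstructs the factor's
methylation-dependent regulatory program from five data layers:

1. **ChIP-seq peak sets** for the wild-type factor and the mutant, both
   induced for the same time. Peaks present in both define
   methylation-independent binding; peaks private to the wild type are the
   methylation-dependent candidates.
2. **A whole-genome bisulfite methylome** giving per-CpG methylated and
   unmethylated read counts, from which β = m/(m+u).
3. **Expression tables** across four conditions (± induction, ± a
   DNA-methyltransferase inhibitor) plus differential-expression calls per
   arm.
4. **An enhancer→gene link table** from an external enhancer-target
   predictor.
5. **Histone-mark read sets** (an active and two repressive marks) at 0 h
   and 48 h of induction.

The pipeline classifies peaks, verifies that methylation concentrates in
the WT-specific set, extracts the methylated sequence motif, assigns
WT-specific peaks to genes, intersects with WT-only up-regulated genes to
call direct targets, quantifies the statistical enrichment, tests whether
global demethylation reverses the induction of the targets, and measures
chromatin remodeling around the target-linked peaks.

## Statistical model and assumptions

**Peak classification.** "Bound at the same locus" is operationalized as
≥ 1 bp interval overlap (configurable via `minOverlap`). This is the
minimal reproducible rule; any stricter definition (fractional overlap,
summit distance) is a special case a user can apply upstream. The original
workflow derived condition-specific peaks by re-calling peaks with the other
sample as background before removing shared loci; at desk scale this package
defines WT-specific purely by non-overlap, which is deterministic, has no
tuning parameters, and preserves the partition identity
|WT| = |shared| + |WT-specific| that all downstream bookkeeping relies on.

**Methylation summaries.** A region's methylation is summarized by the mean
β over the CpGs it contains with coverage ≥ `minCoverage` (default 1 — any
covered site counts, since β is already a coverage-normalized quantity). A
region is "highly methylated" when the summary exceeds `betaThreshold`
(default 0.6, strict `>`). Whether a published peak-level "β > 60%"
criterion means the mean or any single CpG is genuinely ambiguous; the mean
is the conventional region summary and is the default, with
`summary = "any"` available. Fractions are computed over regions containing
at least one eligible CpG — a peak with no CpG is evidence neither way.
The two-set contrast uses the two-sided Fisher exact test (tables with
probability ≤ the observed are summed), the standard exact choice for a
2×2 of region counts.

**Methylated k-mer enrichment.** The unit of counting is a *peak*
(presence/absence), not occurrences: the hypergeometric null models drawing
n foreground peaks from the N total peaks, and K is the number of peaks
carrying the k-mer at least once in methylated form. An occurrence-count
mode would need a different null (occurrences are not exchangeable across
peaks of different lengths). Both strands are scanned; minus-strand windows
are reverse-complemented into plus-strand k-mer space, and a k-mer is *not*
collapsed with its reverse complement because methyl-reading motifs are
strand-asymmetric. A symmetric consequence, visible in every synthetic run,
is that the reverse complement of a planted double-stranded motif ties with
it exactly; ties are ordered alphabetically for reporting, and validation
asserts the planted motif attains the minimal p rather than a unique rank.
Bonferroni multiplies by the number of *distinct methylated k-mers observed
in the background* — only enumerated hypotheses are corrected for, not the
4^k sequence space, most of which was never tested. The logo PWM stacks
selected k-mers aligned at their first CG offset, weighted by foreground
peak count; a stacking rule has to be chosen and the CpG anchor is the only
alignment point every selected k-mer is guaranteed to share.

**Target assignment.** Proximal regulatory space is the union of 5′-UTRs,
exons, and an upstream window of exactly `upstreamBp` = 10,000 bp
(strand-aware, clipped at the chromosome start). When one peak–gene pair
hits several categories the precedence is utr5 ≻ exon ≻ upstream — the
more specific, promoter-proximal annotation wins; published category
percentages are disjoint, so *some* precedence is required and this is the
one that keeps the 5′-UTR, the most informative overlap, from being diluted.
The enhancer route adds genes via link-table overlap, and a gene reachable
by both routes is counted once with its proximal category, mirroring the
convention that enhancer links contribute *additional* genes. Enrichment is
the one-sided hypergeometric upper tail P(X ≥ k); whether a published
p-value for this 2×2 used the one-sided tail or another convention cannot
be determined from printed aggregates, so the orthodox one-sided tail is
reported and the raw 2×2 is kept in the result for any re-analysis.

**5-Aza reversal.** "Reduced by demethylation" is defined on the difference
of induction fold changes across arms, ΔFC = FC(aza) − FC(untreated) < 0 —
the quantity a fold-change-difference histogram displays — rather than on
absolute expression at 48 h, which conflates the inhibitor's global effect
on baselines; the alternative (`method = "t48"`) is provided. The
significance is a one-sided exact binomial of the target count against the
universe fraction q, treating q as fixed — a good approximation when the
universe is two orders of magnitude larger than the target set.

**Histone dynamics.** Signal regions are ± `halfWidth` (default 1000 bp)
around peak midpoints (floor division; regions clamped, not dropped, at the
chromosome start so that one peak always yields one region). Controls are
the 4–6 kb flanks of every peak; controls that would extend below position
zero are dropped (a truncated control would have a different expected read
count, biasing the centering), and controls overlapping any peak are
removed. Per region, signal is log2((reads + 1) / total × 10^6): the
pseudocount of one read makes the log total and costs < 3% of a unit at
the default simulated depth. Deltas are centered on the *lower median* of
the control deltas — with an even control count the lower of the two
central order statistics — so that "50% up / 50% down" holds exactly up to
ties, which are excluded from both direction counts but kept in n. The
direction imbalance over n regions is reported two ways under
Binomial(n, ½): the exact point probability of the observed count, and the
one-sided tail. The point mass is what reproduces the published
significance values for this statistic (verified against an independent
exact big-integer oracle in the test suite before being asserted anywhere);
the tail is the statistically orthodox quantity, and both are always
returned so no information is lost whichever convention a reader expects.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `minOverlap` | 1 | bp | peak overlap defining "same locus" |
| `betaThreshold` / `betaMin` | 0.6 | β | high-methylation / methylated-CpG cutoff (strict >) |
| `minCoverage` | 1 | reads | CpG eligibility for region summaries |
| `k` | 6 | nt | k-mer length for motif enrichment |
| `alphaBonferroni` | 0.01 | — | adjusted-p cutoff selecting logo k-mers |
| `upstreamBp` | 10000 | bp | proximal upstream window |
| `fpkmMin` | 0.5 | FPKM | expressed-universe floor (> in ≥ 1 condition) |
| `degP` | 0.001 | — | DEG significance per arm |
| `halfWidth` | 1000 | bp | histone signal region half-width |
| `nearBp`, `farBp` | 4000, 6000 | bp | control flank placement |
| `pseudocount` | 1 | reads | added before log2 RPM |
| `fdr` | 0.05 | — | gene-set significance cutoff |
| `windowBp`, `pCutoff` | 200, 1e-5 | bp, — | stand-in Poisson peak caller |

## What the synthetic generator emulates — and what it does not

`simulateStudy()` is first-class, tested code: a pure function of one seed
(fanned out to fixed per-generator child seeds) that emits every input the
pipeline consumes, in the exact file formats the readers parse, plus a
planted-truth record. It emulates the *statistical structure* the analysis
assumes:

* a peak partition with known membership (defaults 60 WT-specific /
  30 shared / 10 mutant-specific, 400 bp peaks on 2 × 300 kb of i.i.d.
  50%-GC sequence);
* the methylated motif CCCGCC spliced into 80% of WT-specific peaks with
  every CpG in those peaks given counts 9/1 (β = 0.9 exactly — β values are
  realized as integer count pairs so `computeBeta()` reproduces them
  bit-exactly), background CpGs at 2/8 (β = 0.2), and an unmethylated motif
  copy in 5% of shared peaks;
* 30 planted direct targets (18 proximal, cycling upstream/5′-UTR/exon
  geometry; 12 enhancer-linked), 30 decoy genes away from WT-specific
  peaks, decoy enhancer links in peak-free space, 30 up-regulated genes with
  no binding, and 20 genes up in both arms;
* 600-gene expression tables with log-normal baselines, 4-fold induction,
  an aza arm retaining 15% of the induction effect, and 10% log-normal
  measurement noise;
* histone reads at Poisson(depth 50) per region, 4-fold increased at 48 h
  in 80% of target regions, over 20,000 uniform background reads.

Defaults were chosen once so the full closed loop runs in well under two
minutes on one CPU while keeping every count large enough for the
statistics to be non-trivial. What the generator deliberately does **not**
model: realistic fragment-length and GC-coverage biases, bisulfite
conversion errors, CpG-island spatial clustering, peak-width variation,
chromatin-state autocorrelation, and expression mean–variance structure.
Passing the closed loop therefore demonstrates that the *inference
machinery* is correct when its assumptions hold — exact partition recovery,
top-ranked planted motif, exact target recall, a positive histone
imbalance — not that the pipeline is robust to every artifact of real
sequencing data.

## Numerical and degenerate-input choices

* Internal coordinates are Bioconductor-native `GRanges` (1-based, closed);
  BED's 0-based half-open coordinates are converted on read and back on
  write, and the half-open overlap semantics (abutting intervals never
  overlap) are preserved exactly.
* Chromosome names match by exact string equality; `validateChromosomes()`
  warns about names private to one input instead of silently aliasing.
* β is undefined at zero coverage: `computeBeta()` errors rather than
  returning 0/0, and region summaries filter such sites first.
* Regions with no eligible CpG carry `nCpg = 0`, `meanBeta = NA`,
  `high = FALSE`, and are excluded from fraction denominators;
  an all-no-CpG input is an error, not a 0/0.
* `kmerEnrichment()` sorts by p then k-mer string — deterministic under the
  exact ties that double-stranded motifs produce.
* The Poisson stand-in caller merges significant windows separated by at
  most one window gap, to avoid fragmenting one binding event.
* Empty inputs fail fast with named errors (no reads, empty control set,
  empty universe, foreground not a subset of background).

## Validation strategy

Every exact-test routine is checked against brute-force support enumeration
(hypergeometric and two-sided Fisher for all/random instances with totals
≤ 60), interval overlap against the O(n²) all-pairs oracle on 200-interval
instances, and the binomial point masses against an independent
big-integer implementation (prime-factorized binomial coefficients,
base-10^4 long multiplication) for n up to 200. Closed-loop tests assert
planted-truth recovery across seeds, and a null histone simulation checks
the direction statistic is centered at ½ in the absence of an effect. The
acceptance script (`scripts/acceptance.R`) recomputes all headline numbers
from scratch at a caller-supplied seed.

## Known limitations

* WT-specific status is defined by non-overlap only; a locus bound in both
  conditions at very different strengths is "shared". A coverage-ratio
  refinement would need the raw read sets, which the pipeline does not
  require.
* The k-mer null treats peaks as exchangeable; peaks of very different
  lengths or CpG densities violate this mildly (synthetic peaks are
  constant-width, real peaks are not).
* The stand-in DEG caller and Poisson peak caller are plumbing for
  synthetic data, not replacements for dedicated callers on real data —
  real DEG tables and peak sets enter as files.
* The enhancer route trusts the external link table; no enhancer calling is
  attempted.
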