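---
title: "Methods: pole-specific chromatin accessibility and CRE annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pole-specific chromatin accessibility and CRE annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

After amputation, a planarian wound must decide whether to regenerate a head
or a tail. That decision is visible in the chromatin long before any
anterior or posterior marker gene is expressed: within hours, accessible
chromatin regions (ACRs) in the wound differ between anterior- and
posterior-facing wounds, and the pattern flips when the Wnt pathway is
perturbed (silencing the Wnt inhibitor *notum* makes anterior wounds look
posterior; silencing *wnt1* makes posterior wounds look anterior).
`woundRegulome` implements the analysis chain that turns fragment-level
ATAC-seq data from such a design into biological statements: pole-specific
ACRs, putative enhancers versus promoters, per-element accessibility states
after RNAi, cis-regulatory element (CRE) classes around each gene, motif
content (TCF, FoxG/forkhead, homeobox), and the intersection of motif-bearing
genes with genes downregulated after *wnt1* RNAi.

Because the package is exercised end to end on a synthetic wound regulome
with a machine-readable truth ledger, every stage can be tested as a
recovery problem rather than by eyeballing real data.

## Stage-by-stage model

### Peak calling (MACS2-style stand-in)

Fragments are first restricted to nucleosome-free inserts
(length ≤ 100 bp, boundary inclusive) and Tn5 cut sites can be recentered
(+4 bp on the plus strand, −5 bp on the minus strand). The caller counts
fragment midpoints in sliding windows (width 150 bp, step 50 bp) and tests
each count against a local Poisson rate
`lambda_local = max(lambda_genome, lambda_5kb, lambda_10kb)`, the same
decision structure as a local-lambda peak caller. Window p-values are BH
adjusted genome-wide; significant windows (q < 0.05 with at least one
fragment) are merged, and each merged candidate is trimmed to the span where
per-base coverage stays above 25% of the regional maximum. The summit is the
leftmost coverage maximum, so outputs are fully deterministic. The full
MACS2 model (fragment-size deconvolution, broad mode, control subtraction)
is deliberately out of scope: downstream stages only require a principled,
testable caller.

### Differential accessibility (NB Wald test)

Counts per region are modelled as negative binomial with mean `m` and
variance `m + alpha m^2`. Counts are scaled to effective library size
(genome-wide totals, not matrix column sums). The dispersion is estimated
per region by method of moments and then pooled: a lowess trend on the log
mean, constrained to be non-increasing (isotonic regression), replaces the
noisy per-region values. Three numerical choices matter at two replicates
per group and are worth recording:

* the method-of-moments denominator uses the *unbiased* estimate of `m^2`
  (`mbar^2 - s^2/n`), otherwise the dispersion is systematically
  underestimated;
* the lowess smooth runs without robustness iterations (`iter = 0`);
  the MoM estimates are strongly right-skewed, and a robust fit tracks a
  trimmed mean and again underestimates the dispersion;
* the Wald variance of the log2 fold change is evaluated by the delta
  method *at the pooled mean* rather than at the two group means. At
  `n = 2` the observed group means are strongly correlated with the
  observed fold change; plugging them into the variance produces an
  anti-conservative test (null rejection ≈ 0.09 at nominal 0.05), while
  the pooled-mean form is calibrated (≈ 0.05 in the package's null
  simulations).

All-zero regions are reported with `p = 1` and `log2fc = 0`. Pole-specific
ACRs require `q < 0.05` and a two-fold change (`|log2fc| > 1`), partitioned
by sign.

### Enhancer/promoter split and the second round

ACRs are crossmatched against H3K27ac: regions where ATAC signal
significantly exceeds the acetylation mark are promoter-like; balanced
regions that carry ChIP evidence are putative enhancers. The "second round"
re-tests each pole's putative enhancers against the RNAi samples of the
perturbed wound and feeds a five-state decision table
(`classify_rnai_state`): non-significant regions with positive counts in
both RNAi replicates are ACCESSIBLE; significant regions with all
replicates positive are MORE or LESS accessible by the sign of the fold
change; significant regions with fewer than two positive RNAi replicates
are NON_ACCESSIBLE. "Positive" means raw count > 0; the
remaining cells of the table are reported as UNCLASSIFIED rather than
silently absorbed, which makes the undefined corners of the rule set
visible in the summaries.

### CRE annotation

Merged multi-sample peaks (set union of evidence; summit from the
best-scoring constituent; literal-overlap merging by default) must be
supported by at least two samples. Each surviving peak is assigned to the
gene minimising the absolute summit-to-TSS distance, with ties broken by
the lexicographically smallest gene identifier. Distances are measured
summit to TSS in transcription orientation (negative = upstream). The
class rules, applied in order:

* ATAC-only evidence: core promoter (CP) strictly within 100 bp upstream;
  proximal promoter (PP) from 100 to 500 bp upstream inclusive (the shared
  100 bp boundary belongs to PP, stated explicitly so tests are stable);
  anything else unannotated.
* ChIP evidence: first intron (FI) when the summit falls inside the
  assigned gene's first intron, taking precedence over the distance
  classes; otherwise proximal (Pro) within 2 kb of the TSS, distal (Dis)
  from 2 kb to 10 kb; beyond 10 kb unannotated.

Downstream peaks are eligible for Pro/Dis but not CP/PP, which are defined
as upstream classes.

### Motif analysis

The scanner is a log2-odds PWM scanner with an exact score null: the null
distribution of the window score under the background model is computed by
dynamic-programming convolution of the per-position score distributions,
discretised at 1/1000 bit. The match threshold for a given p-value
(default 1e-4) and every reported hit p-value come from this exact null;
both strands are scanned and `N` bases never match. The background is the
mononucleotide composition of the input genome, not uniform.
Over-representation uses length-matched background regions sampled
uniformly from the genome excluding the targets (seeded) and a one-sided
exact (hypergeometric) test of region-level hit frequency — a region
counts once if it has at least one hit — with BH adjustment across motifs.
The exact form is used rather than a binomial with a plug-in background
frequency because the background frequency is itself estimated from a
finite sample; the plug-in binomial is measurably anti-conservative at
small target counts, while the exact test keeps the null flag rate at or
below nominal.

Per-gene FoxG ratios divide FoxG hits by all motif hits over the gene's
regions in a pole; a gene with hits only in anterior regions is "A to 0",
only posterior "0 to P", both "SIMILAR" (no closeness tolerance is imposed,
since the ratios are already zero/non-zero by construction), neither
"NONE". Hits are pooled across a gene's regions rather than averaged per
region.

### Differential expression and integration

Genes below 1 CPM in more than the smallest group's worth of samples are
removed. The DE test is an empirical-Bayes moderated t on log2-CPM
(0.5-count offset): per-gene variances are shrunk toward a scaled
inverse-chi-square prior whose parameters are estimated by method of
moments on `log s^2` (the trigamma-inverse construction); the moderated t
has `d0 + d` degrees of freedom. Significance requires `q < 0.05` and
`|log2fc| > 0.5`. The test is verified against limma's `eBayes` on a
fixture, and the `d0 -> Inf` limit reproduces a common-variance z-test.
voom-style precision weights are intentionally omitted; the calibration of
the moderated t on NB counts at the simulated depths is checked directly by
the null-simulation tests. The integration step intersects the
downregulated set with TCF-in-enhancer, TCF-in-promoter and FoxG gene sets
plus arbitrary external lists, with optional identifier mapping.

## The synthetic wound regulome

The generator builds a 2 Mb genome (four chromosomes, 35% GC — an AT-rich
composition typical of flatworm genomes) with 200 multi-exon genes laid
out in 10 kb territories, so that each planted element is closest to its
own gene's TSS by construction. Each gene receives one element, cycling
through the five classes: CP centred 50 bp upstream, PP at 300 bp, Pro at
0.7–1.8 kb, Dis at 2.5–4.3 kb, FI centred in the first intron
(900–1400 bp wide by construction). Ten enhancer-class genes also receive
a secondary, shared core promoter so that genes with motifs in both
compartments exist. Elements are anterior-specific, posterior-specific or
shared (40/40/20%).

Accessibility is a multiplier of the per-element fragment depth
(default 200): open = 1, the silent pole of a pole-specific element = 1/8
(the planted pole effect), and the RNAi states map to 1 (ACCESSIBLE), 4
(MORE), 1/4 (LESS) and 0 (NON) plus a count noise floor of 0.1. Two
choices deserve explanation:

* MORE/LESS are symmetric four-fold changes. A smaller MORE effect
  (e.g. 2.5x) is statistically invisible at two replicates, which would
  make the planted state unrecoverable *in principle*, not just in one
  unlucky run.
* The region count table carries only the small 0.1 background mean while
  the fragment tracks carry a realistic uniform floor (5 fragments/kb).
  The "positive counts" rule of the state classifier is raw count > 0;
  with a fragment-level background folded into the counts, deeply closed
  chromatin would almost never produce a zero and NON_ACCESSIBLE truth
  could not be expressed at this depth. The count table is therefore the
  idealised region quantification (what a counting step over a consensus
  peak set produces at moderate depth), and the fragment tracks exist for
  the peak caller.

Fragment centres are drawn from a half-uniform, half-Beta(4,4) mixture
inside the element. Purely uniform placement would give flat coverage whose
argmax — the summit — lands anywhere on the plateau, making summit-based
classification meaningless; the mixture models the empirical concentration
of transposase insertions near the centre of a nucleosome-free region
while keeping enough uniform mass that trimmed peak boundaries still track
the element edges.

The three bundled motifs (TCF-, FoxG/forkhead- and homeobox-like) are
synthetic constructions, 10–11 bp wide with two degenerate W positions and
dominant-base probability ≈ 0.97. Their consensus sequences keep enough
G/C content that, against the AT-rich background, an instance sampled from
the PWM with one mismatch still clears the 1e-4 scan threshold — this is
what makes the ledger's planted instances recoverable at the documented
≥ 95% rate. TCF motifs are planted in the enhancer elements of 25 of the
30 genes downregulated under *wnt1* RNAi (5 of them also in a secondary
promoter); FoxG motifs go into 60% of pole-specific enhancer elements per
pole; every element carries two homeobox instances as motif background.

RNA-seq uses a log-normal baseline (median ≈ 300 counts, sdlog 0.8),
three replicates per arm and NB dispersion 0.02 — a deliberately
well-powered bulk design, as would be obtained from pooling many animals
per replicate, so that the planted log2 fold change of −1 is detectable
with the package's default thresholds (q < 0.05, |lfc| > 0.5).

### What the simulation does and does not emulate

It emulates: pole-asymmetric NB counts with realistic overdispersion, the
RNAi flip logic, H3K27ac restricted to enhancer-class elements, planted
motifs, and DE planted on TCF-motif genes. It does not emulate sequencing
error, mappability or GC bias, fragment-length structure beyond the NFR
range, replicate-level batch effects, or peak shapes more complex than a
single summit. Passing recovery tests therefore demonstrates the
correctness and calibration of the decision logic, not robustness to every
artefact of real libraries.

## Problem sizes and determinism

The test and acceptance suites run the default regulome (2 Mb, 200 genes,
8 ATAC samples), null simulations of 5,000 regions and 10,000 genes, 100
random 1 kb sequences against five PWMs, and 100 seeded null runs of the
peak caller — sizes chosen so the whole suite exercises every claim at
meaningful statistical resolution. All randomness flows from one master
seed through stage-specific derived seeds; `run_pipeline()` run twice with
the same seed is byte-identical apart from the manifest timestamp. The
`simulate`, `peaks` and `merge` stages are resumable skip-points (their
outputs are the expensive files); the statistical stages are recomputed
deterministically from those files on every run.

## Known limitations

* The NB Wald test is calibrated for moderate counts (means ≳ 10); at very
  low counts the normal approximation of the log ratio degrades, which is
  why the classifier couples significance with the positivity rule.
* One TSS per gene; no isoform-aware distances.
* The enhancer/promoter split inherits the simplification that promoters
  lack H3K27ac; in real data active promoters carry the mark too, and the
  crossmatch should be read as "ATAC excess over the local acetylation
  level", not as a biological absence claim.
* `mergePeaks`-style merging is literal-overlap by default; a `max_gap`
  argument exposes fixed-gap merging where needed.
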