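# woundRegulome

Regulatory-genomics analysis of wound polarity in regenerating planarians:
from ATAC-seq fragment intervals to pole-specific accessible chromatin,
enhancer annotation, motif content and Wnt-target integration — with a
seeded synthetic "wound regulome" so that every stage is testable against
planted ground truth.

## The problem and who this is for

A planarian wound regenerates a head or a tail depending on signals from
the pre-existing tissue, and the earliest readable trace of that decision
is chromatin accessibility: anterior- and posterior-facing wounds open
different regulatory elements within hours, and silencing *notum* or
*wnt1* (RNAi) flips the pattern. Analysing such an experiment requires a
chain of genomic decisions — peak calling, differential accessibility,
H3K27ac-based enhancer/promoter separation, distance-based cis-regulatory
element (CRE) classes, motif scanning and enrichment, differential
expression — each with thresholds that determine the biology reported.
`woundRegulome` packages that chain as tested, reusable R functions for
anyone analysing polarity/regeneration ATAC + ChIP + RNA-seq designs (or
teaching/benchmarking such pipelines).

## The statistics at the core

* **Differential accessibility** — per-region negative binomial model
  (mean *m*, variance *m* + α*m*²) with a trended, monotone-regularised
  method-of-moments dispersion and a Wald test on log₂ fold change;
  pole-specific ACRs require FDR < 0.05 and |log₂fc| > 1.
* **RNAi state classification** — the "second round" decision table over
  (significance, replicate positivity, fold-change sign) mapping each
  putative enhancer to ACCESSIBLE / MORE / LESS / NON-ACCESSIBLE /
  UNCLASSIFIED.
* **CRE classes** — summit-to-TSS distance rules: CP (< 100 bp upstream),
  PP (100–500 bp upstream), and with H3K27ac evidence FI (first intron),
  Pro (≤ 2 kb), Dis (2–10 kb).
* **Motif analysis** — log₂-odds PWM scanning with an exact score null
  (dynamic-programming convolution, 1/1000-bit bins), FIMO-style p < 1e-4
  matches, binomial region-level over-representation against sampled
  background, per-gene FoxG ratio categories ("A to 0", "0 to P").
* **Differential expression** — empirical-Bayes moderated t on log₂-CPM
  (CPM ≥ 1 filter, FDR < 0.05, |log₂fc| > 0.5), intersected with
  TCF/FoxG motif-bearing gene sets.

## Worked example

```r
library(woundRegulome)
res <- run_pipeline("wr_demo", seed = 1, quiet = TRUE)

sapply(res$acrs, nrow)
#> anterior posterior
#>       74        76

round(res$state_summaries$anterior_vs_notum_ant$fractions, 3)
#>      ACCESSIBLE MORE_ACCESSIBLE LESS_ACCESSIBLE  NON_ACCESSIBLE
#>           0.094           0.000           0.250           0.656

table(res$annos$cre_class)
#>  CP Dis  FI  PP Pro
#>  49  40  40  40  41

length(res$integration$downregulated)      # wnt1-RNAi downregulated genes
#> [1] 29
length(res$integration$tcf_enhancer_down)  # ... with a TCF motif in an enhancer
#> [1] 24
```

Reading the numbers: of 210 planted regulatory elements, 74 are detected
as anterior-specific and 76 as posterior-specific ACRs (the generator
plants ~40% per pole). After *notum* RNAi only ~9% of anterior putative
enhancers remain fully accessible while ~66% close completely — the
chromatin of the anterior wound has adopted the posterior pattern. The
five CRE classes are recovered at their planted sizes, and 24 of the 29
downregulated genes carry a TCF motif in their enhancer, the signature of
direct Wnt/β-catenin targets.

Every output is also written under `wr_demo/` (`results/*.bed`,
`*.tsv`, `state_summary.json`, `integration_report.json`, plus a manifest
with per-file digests). A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`.

## Package layout

* `R/` — configuration and interval/gene-model types, file I/O
  (BED/narrowPeak/GFF3/FASTA/JASPAR/TSV), synthetic regulome generator,
  peak caller, NB differential test + state classifier, CRE annotation,
  motif machinery, moderated-t DE + integration, pipeline orchestration.
* `tests/testthat/` — unit, property and recovery tests, including
  brute-force and exhaustive-enumeration oracles.
* `vignettes/wound-regulome-methods.Rmd` — the models, their assumptions,
  parameter choices and limitations.
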