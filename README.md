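# chromloops

Tools for studying transcription-factor-mediated chromatin loop
reorganization from multiomics data — the analysis arm of a two-condition
study design in which a stimulus (e.g. G-CSF acting through STAT3)
rewires enhancer-promoter loops and upregulates the genes sitting in loop
anchors.

The package is aimed at computational biologists who have aligned Hi-C
read pairs, TF peak calls and a replicated expression matrix, and who
want the full chain of statistics between those inputs and the figures of
a loop-reorganization paper:

* **Hi-C core** — strand-aware restriction-site pair filtering (reads
  kept within 500 bp upstream of a cut site), cis binning at 5 kb,
  iterative-correction (ICE) normalization with an explicit bias-vector
  contract, A/B compartments from the leading eigenvector of the O/E
  correlation matrix, insulation-score TADs, donut-background Poisson
  loop calling with BH-FDR, and gained / lost / static differential loop
  classification.
* **Peak integration** — aggregate profiles and colocalization heatmap
  matrices around reference peaks (±5 kb), hypergeometric peak-overlap
  tests on a 1 kb genome tiling with Venn counts, promoter (±1 kb of a
  TSS) vs intergenic peak classification, PWM scanning and per-loop-class
  motif enrichment, and an enhancer-promoter spatial-interaction test
  against a distance-stratified permutation null.
* **Expression & networks** — moderated differential expression on
  log-expression (limma), gene-set hypergeometric enrichment (GMT input),
  the loop-anchor gene statistic ("what fraction of upregulated genes sit
  in loop anchors"), accessibility signature scores, TF-target network
  construction with out-degree ranking, and the 2^-ddCT qPCR helper.
* **Synthetic data** — a fully specified toy multiomics experiment
  (genome + cut sites + genes + peaks + Hi-C pairs + expression) with
  planted ground truth, so every stage is testable offline.
* **Pipeline** — `run_pipeline()` chains the stages and writes
  standard-format outputs (.pairs, BED, BEDPE, bedGraph, TSV, JSON
  report); runs are bitwise reproducible under a fixed seed.

The statistical core in the field's notation: contacts are balanced so
that `raw_ij = b_i b_j n_ij` with equal marginals of `n`; compartments are
`sign(v_1)` of `corr(O/E)` oriented by gene density; a loop is a pixel
with `P(X >= obs)` small under `X ~ Poisson(E_d * local O/E * b_i b_j)`
with BH control across the tested band; overlap and enrichment tests are
upper-tail hypergeometric `P(K hits in n draws from N)`; the E-P statistic
is the mean O/E contact over promoter-enhancer bin pairs against
`(1 + #{null >= obs}) / (n_perm + 1)` from distance-matched redraws.

## Worked example

```r
library(chromloops)

cfg <- default_config(seed = 1)
rep <- run_pipeline(cfg)
print(rep)
```

```
pipeline_report (seed 1)
  DE: 100 up / 100 down (recall 1.00, empirical FDR 0.000)
  up-genes in loop anchors: 45.0% (p = 1.14e-14)
  peak overlap p = 4.01e-63; E-P interaction p = 0.00799
  loops: recall 0.80, precision 0.95; compartments 100.0%
  loop classes: gained=17 lost=16 static=21 unclassified=1
  top motif gained=STAT3_like static=CTCF_like; top TF=STAT3_like (degree 70)
```

Reading the report: the simulated experiment planted 100 up- and 100
down-regulated genes (all recovered, no false calls), loops of three
classes (80% of treatment-condition loops re-found at 95% precision;
compartment labels fully recovered), and two TF peak sets whose overlap
is astronomically significant by the hypergeometric test. The
enhancer-promoter permutation test finds the planted E-P loops
(p ≈ 0.008 against 1000 distance-matched redraws), the STAT3-like motif
ranks first in gained-loop anchors while the CTCF-like motif ranks first
in static anchors, and the STAT3-like factor tops the TF-target network
on the upregulated genes — the qualitative fingerprint of
STAT3-mediated loop gain driving target-gene upregulation. 45% of the
called up-genes sit in called loop anchors (53% were planted; the gap is
the documented recall ceiling of single-pixel loop calling at this
coverage — see the methods vignette).

Individual stages are plain functions on plain data: `filter_pairs()`,
`bin_pairs()`, `ice_normalize()`, `call_compartments()`, `call_tads()`,
`call_loops()`, `classify_loops()`, `peak_overlap_test()`,
`ep_interaction_test()`, `differential_expression()`,
`anchor_gene_enrichment()`, `build_tf_network()`, each documented with
its contract. `vignettes/chromloops-methods.Rmd` explains the models,
parameters and generator design.

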