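---
title: "Methods: Hi-C processing, peak statistics and multiomics integration in chromloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hi-C processing, peak statistics and multiomics integration in chromloops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chromloops` implements the analysis arm of a multiomics study design in
which a cytokine stimulus reorganizes chromatin loops and thereby
upregulates target genes: two conditions (reference and treatment) of in
situ Hi-C, TF binding peaks for a CTCF-like and a STAT3-like factor, and
replicated expression data. This vignette describes the statistical
models, the tunable parameters, the synthetic experiment generator that
backs the test suite, and the numerical choices that make results
reproducible. Everything stated here about behavior is computed by the
package's tests or by `scripts/acceptance.R`; no external data are
required.

## Coordinate frame

All coordinates are 0-based, half-open (native BED). A `genome_layout`
carries chromosome lengths, restriction cut-site positions and the working
bin size (default 5 kb, the resolution used for high-resolution loop maps).
`make_bins()` tiles chromosomes left to right; the global bin index is
1-based and stable. The promoter of a gene is the window
`[tss - w, tss + w)` with `w = 1000` bp by default ("±1 kb around the
TSS"); the half-open right edge keeps promoter/intergenic classification an
exact partition. Peak ranking ("top k peaks") uses the BED score column,
with chromosome-then-start tie-breaks for determinism.

## Hi-C processing

**Pair filtering.** Exact duplicate pairs are collapsed, then a pair is
kept only if *both* reads lie within 500 bp upstream of a restriction cut
site (MboI-style GATC). "Upstream" is strand-relative: a `+` read points
toward the next site downstream of its 5' end, a `-` read toward the
previous one. This mirrors Hi-C fragment geometry, where each read points
at the ligation junction. The filter report partitions the input exactly
into unknown-chromosome, duplicate, site-filtered and kept records.

**Binning.** Cis pairs are accumulated into symmetric per-chromosome count
matrices; the upper-triangle-plus-diagonal mass equals the number of cis
pairs. Trans pairs are counted but not matrixed — every downstream
statistic here is cis.

**ICE normalization.** `ice_normalize()` iteratively divides the matrix by
the outer product of its row marginals (renormalized to mean one over
unmasked rows) until the maximum relative marginal deviation falls below
`tol` (default 1e-5, cap 200 iterations). Bins with zero raw marginal are
masked throughout the package: excluded from convergence, eigenvectors,
insulation and loop testing. The bias vector satisfies the factorization
identity `raw[i,j] = bias[i] * bias[j] * norm[i,j]` on every unmasked
pixel, which the tests check to 1e-6 relative error.

**Expected by distance.** `expected_by_distance()` returns the raw
per-distance pixel mean over unmasked pixels, with no monotone smoothing.
It feeds both the compartment and the loop models.

**A/B compartments.** The observed/expected matrix is correlated column
against column (Pearson) and the leading eigenvector of the correlation
matrix is the compartment coordinate; its sign is oriented so that
correlation with a user-supplied activity track (per-bin gene density in
the pipeline) is positive, and bins are labeled A (positive) or B
(negative). Two numerical choices matter. First, the first two diagonals
of O/E are dropped before correlating: they carry decay noise, not
compartment signal, and leaving them in blurs block edges near
compartment boundaries. Second, zero-variance or masked columns are left `unassigned`, so a
constant matrix degenerates gracefully to all-unassigned rather than to an
arbitrary labeling.

**TADs.** Insulation scores: the mean contact in a `window_bins` x
`window_bins` square crossing each bin, expressed as log2 relative to the
chromosome mean. Boundaries are local minima whose prominence over
`±delta_bins` exceeds 0.1; adjacent boundary calls collapse to the deepest
bin. Domains are the intervals between consecutive boundaries, tiling the
chromosome.

**Loop calling.** Every pixel in the distance band (pipeline default
4-120 bins, i.e. 20-600 kb at 5 kb resolution) is tested for focal
enrichment over its local background. The Poisson mean for a pixel is the
expected-at-distance value scaled by the local O/E level around the pixel
and by the ICE biases, and the p-value is the upper Poisson tail of the
raw count. Benjamini-Hochberg correction runs across all tested pixels;
significant pixels cluster by 8-connectivity and each cluster reports one
loop at its maximum-enrichment pixel.

The local background has two regimes:

* Without compartment labels, the background is the *maximum* of a square
  donut ring (outer half-width `donut_radius`, inner exclusion
  `inner_radius`) and horizontal/vertical stripe estimators. The maximum
  is deliberately conservative: at a sharp compartment transition the ring
  mixes strong and weak pixel classes and underestimates the background
  for within-compartment pixels, which the stripe estimators catch.
* With per-bin labels (`group`), the expected model itself is stratified
  into same-label and cross-label pixel classes, removing the compartment
  checkerboard from the O/E residual; the ring mean then suffices and
  buys back the power the conservative maximum costs. Labels should be
  majority-smoothed first (`smooth_labels()`): compartments are
  megabase-scale, so an isolated flipped bin is noise, and fed raw into a
  stratified expected model it would masquerade as an enriched stripe
  across its whole row.

The pipeline runs compartments first and feeds smoothed labels to the
caller; the two-pass design is the package's own choice where the study
only names loop calling as a step.

**Differential loops.** Loops are matched across conditions when both
anchors agree within `match_tol_bins` (default 1). Matched loops are
`static`. A condition-specific loop must also pass a fold-change check at
its pixel — raw counts scaled to equal total cis mass between conditions,
with a half-count pseudocount — to be called `gained` or `lost`
(`fc_thresh = 1.5`); otherwise it is `unclassified`. Scaling by total cis
mass (rather than joint re-normalization) is the simplest defensible
between-condition comparability rule and is recorded in the output.

## Peak statistics

**Profiles and colocalization.** `aggregate_profile()` averages a signal
track in 50 bp cells across ±5 kb windows centered on reference-peak
midpoints (window geometry follows the usual aggregate-plot convention;
2 * flank / step columns). `colocalization_heatmap()` fixes the row order
by the first track's row sums and reuses it for all tracks, so the
matrices are directly comparable.

**Peak overlap.** The hypergeometric overlap test needs a well-defined
universe; the package tiles the genome at 1 kb and counts bins touched by
at least 1 bp of a peak. With N bins, K hit by one set, n by the other and
k by both, p = P(X >= k) upper-tail. Venn counts are reported in both bin
units and peak units. Tests verify the p-value against exhaustive subset
enumeration for small N.

**Motif scanning and enrichment.** PWMs score windows with log2-odds
against a background base composition on both strands; the default
threshold is 80% of the maximum attainable score. Windows containing N are
skipped; same-strand overlapping occurrences are kept. Motif enrichment
across loop-anchor classes is a hypergeometric test on
regions-containing-an-occurrence, BH-corrected across motifs within each
class. This is a known-motif analysis; de novo discovery is out of scope.

**Enhancer-promoter interaction test.** The statistic is the mean
distance-normalized (O/E) contact over all promoter-bin x enhancer-bin
pairs in the distance band (peaks map to their midpoint bin). The null
redraws the same numbers of pseudo-promoters and pseudo-enhancers from
the peak universe without replacement, `n_perm` times; both observed and
null statistics are stratum means over quantile strata of the observed
pair distances, weighted by the observed stratum frequencies. Two
anti-confounding layers are deliberate: per-pair O/E normalization removes
the steep within-stratum distance decay, and the stratified weighting
matches the distance profile of each null draw to the observed one. The
p-value uses the add-one estimator `(1 + #{null >= obs}) / (n_perm + 1)`,
which never returns zero at finite `n_perm`. Calibration is tested: under
a structureless null the p-values are uniform (KS over 200 replicates).
With only a handful of genuinely looped promoter-enhancer pairs the
global mean statistic has limited power by construction — a shift of a
few pixels among thousands of pairs — so a non-significant p on a sparse
experiment is the expected honest answer, while planted broad elevation
is detected reliably (see the test suite).

## Expression and integration

**Differential expression.** Log2 fold changes use pseudocounted condition
means. Significance comes from limma's moderated two-group test on
`log2(x + 1)` values with a mean-variance trend. With 2-3 replicates,
per-gene variance estimates are too unstable for a plain Welch test to
recover realistic effects at BH thresholds (its p-values bottom out near
1e-3 at n = 3); empirical-Bayes moderation is the field-standard remedy
and is the package's design choice. Up calls require `q < alpha` and
`lfc >= lfc_thresh` (defaults 0.05 and 1), down calls mirror.

**Gene-set enrichment** is upper-tail hypergeometric per set against a
supplied universe (GMT input), BH-corrected across sets.

**Loop-anchor genes.** A gene is "in anchors" iff its TSS lies in a loop
anchor interval, each anchor one bin wide, optionally padded
(`anchor_pad`, default 0). The reported fraction of upregulated genes in
anchors is accompanied by a hypergeometric test against the whole gene
collection. The pipeline evaluates membership against the union of loops
called in either condition: anchors are a property of the cell state, and
the union also makes the statistic robust to single-condition misses of
static loops.

**TF network.** Edges are relation-table records whose TF is in the
enriched-TF list (by default, motifs enriched in gained-loop anchors at
`q < 0.05`) and whose target is an upregulated gene; TFs rank by
out-degree. The definition of "enriched TFs" is an input rather than a
hard-wired rule, because upstream conventions vary.

**Relative qPCR.** `ddct_fold_change()` implements
`2^-((ct_t,s - ct_ref,s) - (ct_t,c - ct_ref,c))`.

## The synthetic experiment generator

`sim_config()` fixes the reference toy experiment; these defaults are the
study conditions the whole test suite runs under:

* genome: 2 chromosomes x 2 Mb, 5 kb bins; GATC cut sites with
  exponential spacing, mean 400 bp (floor of 4 bp so planted GATCs never
  collide);
* compartments: 4 alternating A/B blocks per chromosome; contacts x2
  within the same label, /2 across; distance decay `(1 + d)^-1`;
* genes: 2000, lengths 300-600 bp, packed into one compact island per
  block (`gene_island_fraction = 0.35`) with 75% of genes in A blocks.
  Gene islands emulate gene clusters and deserts; without them, ±1 kb
  promoter windows around 2000 TSS would tile the whole genome and the
  promoter/intergenic peak dichotomy would collapse;
* peaks: 300 per factor, 200 bp wide, log-normal scores. A
  colocalization fraction (0.4) of STAT3-like peaks sit within 100 bp of
  a CTCF-like peak; 35% sit in promoter windows; the remainder are
  A-compartment-biased, because enhancer-type binding concentrates in
  active chromatin — placing them uniformly would make the E-P
  interaction statistic systematically colder than its compartment-matched
  null;
* loops: 20 gained, 15 lost, 25 static at 5-fold pixel enrichment,
  planted 30-300 kb apart (the empirical loop-size scale), within a
  single compartment block (loops are intra-domain in real data), with
  >= 8 bins Chebyshev separation so each loop's local background is
  uncontaminated. Static loops anchor at CTCF-like peak bins; gained
  loops connect an intergenic STAT3-like enhancer peak bin to a promoter
  peak bin, and their target genes are planted upregulated;
* expression: 100 up / 100 down genes at 4-fold effect, 3 replicates,
  20% multiplicative CV; 53% of up-genes are placed (cycling over
  distinct anchor bins) in treatment-condition loop anchors;
* Hi-C: 5e5 read pairs per condition; read ends are placed 0-300 bp
  upstream of a cut site inside their bin so the 500 bp filter keeps
  them, except a deliberate 1% placed in cut-site dead zones to exercise
  the filter;
* every stage derives its seed from the master seed; identical
  configurations reproduce bitwise.

Motif consensus sequences (`CCACCAGGTGGC` for the CTCF-like factor,
`TTCCCGGAA` for the STAT3-like factor) are written into the emitted FASTA
at peak centers, shifted a few bases when they would clash with a
recorded cut site or another motif.

What the generator does *not* emulate: sequencing errors and read-level
artifacts, trans contacts, copy-number or mappability bias, nested TADs,
anchors wider than one bin, and the long-tailed loop-strength
distribution of real data. Passing tests therefore demonstrate that the
statistics are implemented correctly and are well calibrated at this
scale — not that the pipeline's operating characteristics transfer
unchanged to genome-scale human data.

## Measured operating characteristics and limitations

At the default coverage (5e5 pairs per condition, so ~2.5e5 cis pairs per
chromosome), single-pixel 5-fold loops sit near the Poisson/BH detection
boundary: the caller's recall is ~0.8 with precision ~0.95 (median over
ten seeds, as the test suite measures), and recall rises steeply with
per-chromosome coverage. One downstream consequence is that the end-to-end recovered
anchor-gene fraction sits ~6 points below its planted value (planted
fraction x anchor retention ~0.85 + ~1% background), since planted genes
on gained (single-condition) loops are lost whenever their loop is
missed. The loop caller reports pixel-exact positions when it fires, so
anchor padding cannot recover those losses — it only adds gene-island
background and overshoots in the other direction. The package keeps the
unpadded default and reports the fraction as measured.

Problem sizes in the test suite are chosen to keep a full run in a few
minutes on one core: unit fixtures use 40-200-bin matrices and 5e4-4e5
sampled pairs; calibration uses 200 permutation replicates at
`n_perm = 199`; end-to-end recovery uses the full default experiment over
ten seeds. `ep_interaction_test` and the simulator are the only stochastic
components, and both record their seeds in results and reports.
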