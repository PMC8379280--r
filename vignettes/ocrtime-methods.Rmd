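---
title: "Methods: models, parameters and design choices in ocrtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in ocrtime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ocrtime implements the statistical core of an integrative RNA-Seq/ATAC-Seq
time-course analysis over three differentiation stages (D0, D14, D28 of a
dopaminergic induction design: 3, 4 and 3 RNA replicates, one ATAC sample
per time point). This vignette describes the models, the tunable
parameters and the choices made where the design was genuinely open. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Differential expression model

Counts for gene *i* in sample *j* are modelled as negative binomial with
mean `s_j q_ij` and dispersion `alpha_i`, where `s_j` are median-of-ratios
size factors: the median over genes (restricted to genes with no zero
count) of `count_ij / geometric_mean_i`. Size factors are defined up to a
common scale; only their ratios matter downstream.

The Wald test operates on normalized group means with a pseudo-count of
0.5: `log2FC = log2((mean_B + 0.5)/(mean_A + 0.5))`, with a delta-method
standard error using the NB variance `mu + alpha mu^2`, and a two-sided
normal p-value. Dispersions come from within-group method-of-moments
estimates. The mean–dispersion trend is the binned median of the total
squared coefficient of variation, corrected for the median bias of a
chi-square variance estimate with the pooled degrees of freedom, with the
expected counting (shot-noise) component subtracted per bin, connected by
log-log interpolation and held flat beyond the outer bins.

Two regimes:

* **Replicated groups** (RNA): per-gene estimates are shrunk fully to the
  trend by default (`shrink_weight = 1`), except that genes whose raw
  estimate exceeds four times the trend keep their raw value — an outlier
  escape that protects genuinely over-dispersed genes from anticonservative
  shrinkage. This default was fixed by a calibration study: on 2,000 flat
  NB genes (dispersion 0.1, 3 vs 4 replicates) the fraction of p < 0.05 is
  close to nominal, whereas weaker shrinkage inflates it.
* **Single-sample groups** (ATAC, one sample per time point): there is no
  within-group replication, so the two samples are pooled as replicates of
  a common mean over the "quiet" subset (observed |log2FC| < 1), and the
  trend uses the 25th percentile per bin with the matching chi-square
  quantile inversion. The low quantile resists upward contamination by
  peaks with genuine between-group signal, which a pooled estimate cannot
  distinguish from noise at n = 1 + 1. Results carry a `low_confidence`
  flag.

The DEG rule is a conjunction: BH FDR < 0.05, linear fold-change > 4 in
either direction, and FPKM ≥ 1 in at least one replicate of the
comparison. `fc > 4` is interpreted on the linear scale of normalized
means, two-sided, since both up- and downregulated genes are reported.
Batch adjustment (`adjust_batch()`, per-batch geometric-mean centering of
log counts) is available but off by default, because the original batch
structure is a free parameter of the data, not of the method.

## Temporal clustering and enrichment

Replicate-averaged FPKM per time point is log2(FPKM+1)-transformed and row
z-scored; constant rows become all-zero vectors and are flagged
degenerate rather than dropped. Clustering is agglomerative with Euclidean
distance and Ward linkage, and the tree is cut at k = 6 — the method is
"hierarchical clustering" with the cluster count treated as a tunable
parameter (`k`), defaulting to the six temporal archetypes the analysis
expects. Labels are renumbered by descending cluster size so that label 1
is always the largest, making outputs stable across runs.

Gene-set enrichment is the exact hypergeometric upper tail
`P(X >= x)` with BH across sets. The universe defaults to expressed genes
(max FPKM ≥ 1 in any sample): a conservative, data-defined population;
it is an explicit argument because enrichment p-values are more sensitive
to the universe than to anything else in this computation.

## lncRNA analyses

"lncRNA" groups the six GENCODE non-coding classes (lincRNA, antisense,
sense_intronic, processed_transcript, sense_overlapping, TEC). Top-N
composition tests rank one comparison's DEGs by absolute linear
fold-change, breaking ties by smaller q and then lexicographic gene id so
the ranking is fully deterministic; the population for the hypergeometric
is all DEGs of that comparison (configurable — the alternative, all
annotated genes, gives much smaller p-values and answers a different
question). Pair correlations use log2(FPKM+1) across every sample of all
time points; the summary reports the share of tested pairs that are
significant (p < 0.05) and the share of significant pairs with positive
correlation, matching the "54 of 96 = 56%, 49 of 54 = 91%"-style
statements such studies print.

## ATAC computations

* **Tn5 offsets**: +4 bp on plus-strand cut sites, −5 bp on minus-strand
  ones. For a paired fragment the start is the plus-strand cut and the end
  the minus-strand cut, so a fragment shifts to `[start+4, end−5)`. A
  state flag forbids double application.
* **Fragment-size histogram**: 10 bp bins, 3-bin moving average, modes =
  local maxima with prominence ≥ 5% of the smoothed maximum (prominence is
  height above the higher of the two flanking valleys, walking out to the
  nearest higher bin). At the defaults this reports the sub-100 bp peak
  and the mono- and dinucleosome modes; the trinucleosome mode at 600 bp
  sits just below the prominence floor at the default mixture weights.
* **Consensus peaks**: the union of per-time-point peaks merged
  transitively while same-chromosome gaps are ≤ 100 bp. "Within 100 bp"
  is read inclusively (gap of exactly 100 merges). Presence is
  any-overlap of a source peak with the merged interval. The operation is
  order-invariant and idempotent by construction (it reduces to interval
  reduction with `min.gapwidth = gap + 1`).
* **Annotation** is decided by the peak midpoint against a priority list
  promoter-TSS > TTS > 5UTR > 3UTR > exon > intron > intergenic, with
  promoter-TSS = 1 kb upstream + 100 bp downstream of the TSS
  (strand-aware) and TTS its mirror image at the transcript end. UTR
  categories require UTR intervals on the gene models and otherwise never
  fire. Midpoint assignment makes the categories a partition — every peak
  gets exactly one label — at the cost of ignoring partial overlaps;
  `nearest_gene` and the signed, strand-oriented `dist_to_tss` are always
  reported.
* **Differential accessibility** reuses the NB machinery and applies the
  study's rule |log2FC| > 1.5 (strict) with **raw** p < 0.05 — unlike the
  RNA rule this is deliberately not FDR-adjusted, and the output flags the
  single-replicate regime as low-confidence.
* **SNP overlap** tests use M = all consensus peaks, K = SNP-containing
  peaks, n = class size, x = SNP-containing class members. The universe
  choice (consensus peaks rather than genome bins) is an argument.
* **Locus Mann–Whitney** compares per-OCR counts scaled to each sample's
  per-million total, exact when both sides have ≤ 8 OCRs without ties.
  Totals default to "already normalized" (1e6): normalizing by locus sums
  would erase exactly the locus-level differences the test looks for.
  Fully tied inputs return p = 1 by convention.

## Integration

The fold-change/fold-change correlation pairs each accessibility-changing
peak (p < 0.05, category promoter-TSS/exon/intron) with its annotated
nearest gene's expression log2FC. A gene with several qualifying peaks
contributes one point per peak; a best-peak-per-gene mode (max |access
FC|) is available. Signal matrices count fragment midpoints in 100 bp bins
over OCR center ± 5 kb, scaled per million fragments; k-means (10
restarts under a fixed seed, k defaulting to 3) groups rows. TSS
metaprofiles are strand-oriented so upstream is always left.

## Motif analysis

Scores are log2((p + 1e-4)/(b + 1e-4)) — the 1e-4 floor keeps scores
finite at zero probabilities — discretized to a grid of 1e-3 bits. The
null distribution of a word score under the 0-order background is computed
exactly on that grid by convolving per-position score distributions; the
reported p is the inclusive upper tail. The grid bounds the discretization
error of any p-value at the grid resolution; word scores are computed on
the same grid, so oracle tests against full 4^L enumeration agree exactly.
Scanning covers both strands, N bases contribute zero score, and BH is
applied per motif across all positions × sequences × strands with
retention at q < 0.1. The background defaults to base frequencies of the
scanned sequences (a uniform option exists). A practical consequence of
genome-scale BH: motifs shorter than ~10 positions cannot reach retention
on their own, which mirrors the behaviour of standard scanners.

The cluster × TF frequency matrix counts the percent of each cluster's
genes with ≥ 1 retained hit of any of the TF's motifs, then drops
unexpressed TFs (max FPKM < 1) and near-constant rows (MAD of the
frequency values < 0.05). The MAD is taken on the same scale as the
values: on the fraction scale a TF specific to a single cluster would
always fail the filter, which contradicts how such matrices are used.
"Most enriched motif per TF" for the promoter/enhancer comparison is the
motif with the largest summed class frequency, with deterministic
tie-breaking by motif id.

## The synthetic-data generator

The generator emulates the study's statistical structure, not its genome:

* 2,000 genes on four synthetic chromosomes (≥ 10 kb apart), biotype
  fractions allocated exactly (largest remainder): 80% coding, 20% across
  the six lncRNA classes; antisense/sense_intronic lncRNAs point to their
  nearest coding gene as the annotated regulatory target.
* 30% of genes carry one of six temporal archetypes (monotone down,
  down–up, high–high–down, up-at-D14-then-down, D14 peak, up-at-D28) with
  8-fold swings; the rest are flat nulls. Counts are NB with per-gene
  log-normal dispersion around 0.05 and 3/4/3 replicates.
* 10,000 ATAC peaks split exactly into presence classes (22% D0-specific,
  32% D14, 19% D28, 11% all-shared, remainder pairwise). Coding archetype
  genes get a promoter peak whose D0-vs-D28 accessibility log2FC shares a
  latent variable with the gene's expression log2FC at correlation
  `coupling_rho = 0.45`; distal peaks are intergenic by construction,
  emulating enhancer-like OCRs. ATAC counts use dispersion 0.005 —
  technical noise only, as the design has one sample per time point.
* Fragment sizes mix a truncated exponential below 100 bp (weight 0.55,
  origin 38 bp, scale 30 bp — the open-chromatin mass) with Gaussian
  nucleosome modes at exactly 200/440/600 bp (sd 25/40/50, weights
  0.25/0.12/0.08). Fragment midpoints fall in open peaks except for a 10%
  uniform background; at D0 the background rate is divided by
  `d0_access_boost = 1.5`, so global in-peak accessibility is highest in
  pluripotent cells in the fragment/signal-matrix domain.
* Enhancers cover 60% of D0-specific peaks (plus decoys); SNPs fall in
  peaks with per-bp uniform probability except a ×10 odds on D28-specific
  distal peaks; odds of 1 gives the calibration null.
* Motif sites are sampled base-by-base from the PWM and inserted at a
  random offset/strand per (cluster, motif) planting rate; every generator
  writes a machine-readable truth table, and identical configs (including
  the seed) give byte-identical outputs.

**What passing tests do and do not show.** The generator has independent
genes, no GC or mappability structure, no read-level errors, no
batch confounding by default, and its lncRNA–target pairs share no
planted co-expression. Calibration and recovery results on it demonstrate
the pipeline's statistical correctness under the assumed NB/mixture
models — not robustness to the artefacts of real sequencing data.

## Known limitations and numerical notes

* The p < 0.05 accessibility filter before the FC–FC correlation
  preferentially keeps large-|FC| peaks; this selection inflates the
  recovered correlation slightly above the planted value (about +0.03 at
  the default noise levels). The acceptance test therefore compares the
  mean over seeds against the planted 0.45 within the stated ±0.06.
* The normal Wald p is mildly anticonservative at 3–4 replicates; the
  calibration band in the tests (0.05 ± 0.02) reflects that deliberately.
* Hypergeometric and rank-test p-values are discrete, hence conservative;
  the SNP-null KS check uses simulation sizes with fine support so the
  discreteness does not dominate.
* Problem sizes in the test suite (600–8,000 genes, 2,000–15,000 peaks,
  200,000 fragments, 10–200 replicate simulations) were chosen as the
  smallest sizes at which the assertions concentrate well; they are the
  package's own study conditions, and all run on a single CPU in well
  under half an hour.
* Ties: DEG ranking breaks |FC| ties by q then gene id; k-means uses a
  fixed seed and 10 restarts; cluster labels are renumbered by size;
  merged intervals are emitted in coordinate order — all outputs are
  deterministic under a fixed seed.
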