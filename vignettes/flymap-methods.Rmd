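---
title: "Methods: metabolic profiling, crosstalk scoring and spectral quantification in flymap"
author: "flymap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic profiling, crosstalk scoring and spectral quantification in flymap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flymap` implements a single-nucleus metabolic analysis pipeline for
Drosophila tissues together with a gut-to-brain ligand–receptor (L–R)
crosstalk engine and a Raman/SRS spectral quantification suite. This
vignette explains the models and procedures, the parameters that matter and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. Every empirical statement here is one the package's test suite or
`scripts/acceptance.R` computes itself.

## The single-nucleus metabolic pipeline

### Quality control and normalization

Nuclei are filtered on the number of detected genes (raw count > 0),
retained when that number lies in a closed interval: 200–1,600 for brain
tissue and 200–3,000 for gut tissue (`qc_thresholds_for_tissue()`), gut
nuclei carrying inherently higher gene content. Both bounds are inclusive;
no doublet detection beyond the gene-count interval is attempted. Counts
are then normalized per nucleus to counts-per-10,000 and log1p-transformed
(`normalize_log1p()`): `value = ln(1 + count * 10^4 / total)`. The scale is
configurable; 10,000 is the convention for this data type. The
normalization conserves mass exactly: `sum(expm1(values))` equals the scale
for every nucleus.

### The metabolic matrix and clustering

`select_metabolic_genes()` restricts the matrix to the union of a pathway
catalog's gene sets — a KEGG-style collection of metabolic pathways (81
pathways in 11 categories in the emulated collection). Clustering then runs
entirely on this metabolic matrix: per-gene z-scaling clipped at ±10
(`scale_and_embed()`, the common convention for this workflow step), PCA,
and Leiden community detection on a shared-nearest-neighbor (SNN) graph
(`cluster_nuclei()`). The SNN graph uses k = 20 Euclidean nearest
neighbours (self included), Jaccard edge weights, and pruning below 1/15 —
exposed defaults, since the upstream workflow names its functions but not
its graph parameters. The Leiden objective is modularity with the
user-supplied resolution; 0.2 is the gut default and 0.1 the brain default.
Cluster labels are contiguous integers from 0, ordered by decreasing size,
and the seed is a required argument — there is no hidden random state.

The number of PCs worth keeping is diagnosed with `elbow_point()`, a
kneedle-style rule: the component maximizing the perpendicular drop below
the chord joining the first and last scree points. On strictly linear decay
(no knee) the convention is to return 1. The rule makes "an elbow at ~10
PCs" a computable quantity rather than a visual judgement.

### Occupancy and composition

`occupancy()` tabulates, per cluster and condition, the proportion of that
condition's nuclei, and reports the occupancy fold change
treated/control. A fold of 1.4 is "40% greater occupancy"; a fold of 2 is a
doubled cell ratio. Clusters absent from one condition are flagged
(`fold_defined = FALSE`) rather than dropped or given infinite folds.
`transfer_composition()` crosses a metabolic clustering with reference
cell-type labels (e.g. whole-transcriptome annotations) and reports the
percentage breakdown and dominant label per cluster.

### Pathway activity scores

`module_score()` implements bin-matched control scoring: genes are binned
into `n_bins = 24` quantile bins of dataset-average expression; each set
gene draws `n_ctrl = 100` control genes from its bin with replacement; the
score is the mean expression over set genes minus the mean over all control
draws. The defaults match the published defaults of the function this
contract emulates; the paper-level workflow names only the function, so the
parameters are recorded here and exposed. Scores are exactly invariant to
an additive constant on the normalized layer and exactly scale-equivariant.

Two deliberate numerical choices:

* **Reproducible arithmetic.** Set and control sums are accumulated
  sequentially in set/draw order with plain double-precision adds, so an
  independent re-implementation following the same recipe reproduces scores
  bit-for-bit. (Long-double accumulators, as used by `colSums()`, differ in
  the final ulp.)
* **Attenuation under broad perturbations.** Because control genes are
  matched on *dataset-wide* average expression, a perturbation that lifts a
  gene set in a large fraction of nuclei also lifts those genes' averages,
  moves them into higher bins (in the extreme, into bins populated mainly
  by themselves), and absorbs part of the planted shift. Recovery of a unit
  planted shift is essentially exact when the perturbed nuclei are a small
  fraction of the dataset and degrades as that fraction grows toward one
  half. This is a property of the scoring scheme itself, worth knowing when
  interpreting scores for dominant cell states.

`score_all_pathways()` scores every catalog pathway with the *same* seed,
so each column is independent of the rest of the catalog: permuting the
catalog permutes columns without changing content.

### Expression Power Index

Within each cluster, pathways are ranked by the Expression Power Index:
`EPI = f * max(m, 0)`, where `f` is the fraction of the cluster's nuclei
with module score > 0 (expression frequency) and `m` the mean score
(expression level). Two conventions are recorded where the source workflow
leaves them open: "expressing a pathway" means module score > 0, and the
level enters through `max(m, 0)` so that a pathway negative on average
cannot rank as active. Ties break alphabetically by pathway id.

### Differential expression

`wilcoxon_de()` is the DE contract used throughout: two-sided rank-sum
tests on the log-normalized layer for genes expressed in at least 10% of
either group, `log2FC = log2((mean(expm1(A)) + 1)/(mean(expm1(B)) + 1))`
(pseudocount 1 on de-logged means), Benjamini–Hochberg adjustment over the
tested genes. Fully tied genes get P = 1. Swapping the groups negates the
fold change and preserves P exactly.

One practical caveat the tests quantify: depth normalization couples genes.
Doubling a block of moderately expressed genes shifts every other gene's
normalized abundance down by the planted mass fraction (about 2% in the
test conditions), so raw-P positives among "null" genes run slightly above
the nominal level under strong plantings, while label permutation (a true
null) is calibrated. At the BH-FDR threshold used for discovery the
null-gene call rate is far below 5%.

### Pathway correlation modules

`pathway_correlation()` computes pairwise Pearson correlations of pathway
scores across all nuclei of one condition (not per cluster), with two-sided
P from the t-transform of r on n−2 degrees of freedom. Zero-variance
pathways yield missing correlations, reported rather than raised, imputed
as 0 only for dendrogram ordering and excluded from module statistics.
`order_by_hclust()` orders pathways by average-linkage agglomeration on
d = 1 − r. Significance dots use raw P < 0.05 per the display convention
this reproduces; a BH option exists behind a flag.

`detect_modules()` makes "correlation module" a numeric object: cut the
average-linkage tree at height 1 − r_threshold, keep groups with ≥ 3
members, mean pairwise r ≥ 0.3, and ≥ 80% of member pairs significant at
α = 0.05. These four defaults are this package's convention — the source
analysis delineates modules visually — and were chosen for null
calibration: with 20 independent pathway scores over 1,000 nuclei, zero
modules are detected in ≥ 95% of simulations, while planted factor blocks
at within-block r = 0.6 are recovered member-exactly. `compare_conditions()`
labels modules shared (best Jaccard ≥ 0.5 across conditions) or
condition-specific, distinguishing a conserved metabolic core from
treatment-induced coordination.

## Ligand–receptor crosstalk

The gut is the source tissue (ligands) and the brain the target
(receptors); the engine itself is direction-agnostic. For a curated pair
table (CSV: ligand, receptor, pathway), `lr_score()` uses a product
contract: mean log-normalized ligand expression over the source cluster
times mean receptor expression over the target cluster — monotone in both
inputs, zero when either side is silent. The upstream tool's internal edge
weight is not published, so this contract is validated by planted-truth
recovery and null calibration, not against external figures; an additive
variant is exposed via `method = "sum"`.

`pair_significance()` runs one-sided rank-sum enrichment tests of the
ligand in its source cluster versus all other same-tissue nuclei, and of
the receptor in its target cluster likewise; the pair P is the maximum of
the two (both sides must be enriched), which is uniform under the null.
`filter_pairs()` applies the display filter with strict inequalities:
P < 0.05 and both expression fractions > 0.10 ("more than 10% of nuclei").
Differential interaction is `delta = score(A) − score(B)`, positive meaning
upregulation in A; `aggregate_by_cluster()` counts significantly
differential pairs per cluster and omits clusters with fewer than 10,
listing them with the reason. `category_comparison()` compares member-pair
scores between conditions per signalling category with a two-sided
rank-sum test, flagging categories at P ≥ 0.05 as not shown and single-pair
categories with a small-n warning.

## Raman/SRS spectral quantification

Spectra are regridded to a uniform 1 cm⁻¹ array by linear interpolation
(`regrid()`; the start endpoint is always preserved, the end endpoint when
the span divides evenly), background-subtracted point-wise, optionally
baseline-corrected, vector-normalized to unit Euclidean norm, and averaged
within groups. Baseline correction is asymmetric least squares (λ = 1e5,
p = 0.01, 10 iterations) — the source workflow states only that "baseline
correction was applied", so a standard, fully parameterized algorithm is
the recorded default.

**Band ratios** (CD/CH 2,140/2,850 for newly synthesized lipids, D-lipid
2,176/2,850, unsaturation 3,012/2,850, lipid/protein 2,850/2,935) divide
mean intensities over ±2 cm⁻¹ windows, computed on regridded,
background-subtracted but otherwise *unprocessed* spectra — ratios are
taken before any normalization or baseline correction, and are exactly
invariant under positive scaling (so normalizing first would not change
them; the tests assert this identity). The windowed mean rather than a
single-point lookup makes the ratio robust to regridding phase; the
halfwidth is an argument.

**Lipid ordering** is quantified by A2885/A2850
(`area_ratio_2885_2850()`): a joint five-Gaussian decomposition of the CH
stretching region (2,800–3,050 cm⁻¹; initial centers 2,850, 2,871, 2,885,
2,927, 2,958 cm⁻¹; centers constrained to ±8 cm⁻¹, positive amplitudes
and widths) via bounded Levenberg–Marquardt least squares, returning the
fitted-area ratio of the 2,885 and 2,850 bands. Fitted areas are used
instead of fixed-window integration because the 2,871/2,885 bands overlap
heavily. Gaussian line shapes are the recorded choice (no line shape is
specified by the source). Decomposing a *single* noisy replicate at 1%
noise leaves up to ~30% error in this ratio — the overlapping bands make
the problem ill-conditioned — which is exactly why spectra are averaged
within groups before quantification; on a 20-replicate average the ratio is
recovered to within a few percent, the residual scatter reflecting the
same ill-conditioning attenuated by averaging.

**Half-height bandwidth** of the 1,295 cm⁻¹ (CH₂)ₙ twisting band
(`half_height_bandwidth()`): the local maximum nearest the requested
center within ±15 cm⁻¹ is refined by a parabola through the three top grid
points (the raw argmax is biased high under noise); the local baseline is
the line through the mean (wavenumber, intensity) of the flank bands
[center + 2·hw, center + 3·hw] and its mirror — band means are unbiased
under noise, exact for linear baselines, and the 2·hw offset keeps both
Gaussian and Lorentzian tails negligible; half-height crossings are found
by linear interpolation between adjacent grid points, scanning outward from
the peak. On noiseless Gaussians the measured width matches
2√(2 ln 2)·σ to well under 1%.

## The synthetic-data generator

The generator exists because the pipeline's deposited inputs (tens of
thousands of sequenced nuclei, raw spectra) cannot be re-derived at desk
scale; it produces every input with machine-readable ground truth.

* **Counts** are negative-binomial with gene baselines drawn log-normally
  (meanlog −0.5, sdlog 1 by default) and one shared dispersion (NB size 2,
  typical of nuclear transcriptome overdispersion) — the simplest model
  with closed-form means for oracles. Effects act multiplicatively on the
  mean: pathway programs (2^log2_effect on all genes of a pathway in a
  cell type/condition), L–R plantings (per-gene multipliers in the named
  source/target type), and correlated pathway blocks (a per-nucleus
  standard-normal latent factor shared by the block's genes, applied as the
  mean-preserving multiplier exp(loading·z − loading²/2)). Each nucleus's
  mean vector is renormalized to a library size drawn uniformly from
  `library_size_range` (default 1,000–3,000, consistent with nuclei
  detecting a few hundred to a few thousand genes), so expected library
  sizes are exact; the renormalization shrinks planted fold changes by the
  planted mass fraction (~1% in the test conditions).
* **Catalogs** control mean pairwise Jaccard overlap by sampling pathway
  genes from a restricted pool of size s̄(1+J)/(2J); overlap 0 partitions
  the universe disjointly.
* **Spectra** are sums of Gaussian or Lorentzian peaks over a polynomial
  baseline with additive Gaussian noise; the truth records analytic height,
  FWHM and area (Gaussian area = amplitude·σ·√(2π)).

Everything is seeded explicitly and byte-identical across runs for a fixed
seed. What the generator does **not** emulate: ambient RNA, doublets, batch
effects, UMI-level sequencing error, gene–gene correlation beyond the
planted blocks, realistic spectral instrument response. Passing recovery
tests therefore demonstrates that the pipeline's statistics behave
correctly under a faithful null and planted-signal model — not that they
are robust to every artifact of real tissue data.

### Problem sizes used by the tests and acceptance script

Recovery checks run at sizes where sampling error is well below the
planted effects: 3 cell types × 2 conditions with 600–2,000 nuclei for
clustering/EPI/occupancy (10–20 seeds), 2,000 nuclei × 20 pathways for
correlation modules, 100 vs 100 nuclei over a 2,000-gene transcriptome for
the DE contract (planted genes at baseline mean 4 — a few counts per
nucleus, the regime where differential genes are realistically detectable),
500 nuclei per cluster over 800 genes for L–R recovery, and 20-replicate
group averages for spectral metrics at 1–2% noise.

## Known limitations

* Leiden clustering depends on igraph's implementation; determinism is
  guaranteed per seed, but label *values* may change across igraph major
  versions (all tests compare partitions, not labels).
* The L–R score scale is arbitrary (product of log-normalized means);
  only comparisons — differences between conditions, ranks, correlations —
  are meaningful.
* `detect_modules()` assumes the dendrogram cut matches the correlation
  threshold; strongly unequal within-block correlations can split a true
  block at the cut height.
* The module-score attenuation described above means scores of very
  dominant cell states are conservative.
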