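# flymap

Single-nucleus metabolic profiling for Drosophila tissues, with a
gut-to-brain ligand–receptor crosstalk engine, a Raman/SRS spectral
quantification suite, and a synthetic-data generator that makes every
stage testable against planted ground truth.

## What problem this solves

Dietary and metabolic interventions remodel fly gut and brain tissues at
the level of individual cells. `flymap` turns single-nucleus RNA-seq
(snRNA-seq) count matrices into metabolic readouts:

* **Metabolic clustering.** Nuclei are clustered not on the whole
  transcriptome but on a *metabolic matrix* — the genes belonging to a
  KEGG-style catalog of metabolic pathways (e.g. 81 pathways in 11
  categories) — via per-gene z-scaling, PCA with a computable elbow rule,
  and Leiden community detection on a shared-nearest-neighbor graph.
* **Pathway activity scores.** Per-nucleus module scores s(c, p): mean
  log-normalized expression of pathway p's genes in nucleus c minus the
  mean of expression-bin-matched control genes.
* **Expression Power Index (EPI).** Within a cluster, pathways are ranked
  by `EPI = f · max(m, 0)`, the product of expression frequency
  (fraction of nuclei with s > 0) and expression level (mean s).
* **Occupancy comparison.** Per-cluster cell proportions between
  conditions and their fold change (1.4 = 40% greater occupancy), plus
  transfer of reference cell-type annotations onto metabolic clusters.
* **Correlation modules.** Pearson correlation of pathway scores across
  all nuclei of a condition, hierarchical ordering, raw-P significance
  masking, and numeric module detection (dendrogram cut with minimum
  size, mean-correlation and significance-fraction criteria), compared
  across conditions by Jaccard overlap.
* **Ligand–receptor crosstalk.** Product-of-means interaction scores for
  curated L–R pairs from gut (source) clusters to brain (target)
  clusters, enrichment-based pair significance, the
  P < 0.05 / >10%-expression filter, condition differences
  Δ = score(A) − score(B), per-cluster aggregation with a 10-pair
  omission rule, and category-level comparisons.
* **Raman/SRS spectra.** Regridding to 1 cm⁻¹, background subtraction,
  asymmetric-least-squares baseline correction, vector normalization,
  group averaging, band ratios (2,140/2,850, 2,176/2,850, 3,012/2,850,
  2,850/2,935), five-Gaussian CH-region decomposition for the
  A2885/A2850 lipid-ordering ratio, and the half-height bandwidth of the
  1,295 cm⁻¹ (CH₂)ₙ twisting band.

Expression data live in Bioconductor `SingleCellExperiment` objects;
counts read/write as 10x-style Matrix-Market directories, catalogs as
GMT, L–R tables as CSV, spectra as two-column TSV.

## Worked example

```r
library(flymap)

# catalog emulating the metabolic collection: 81 pathways, 11 categories
catalog <- generate_pathway_catalog(n_categories = 11, n_pathways = 81,
                                    genes_per_pathway = c(5, 40),
                                    gene_universe_size = 2000,
                                    overlap_fraction = 0.05, seed = 0)

# two-condition gut population: three cell types, pathway pw005
# upregulated 2-fold in cell type T1 under "880", and T3 doubling
# its occupancy
design <- population_design(
  n_nuclei = data.frame(
    cell_type = rep(c("T1", "T2", "T3"), 2),
    condition = rep(c("ctrl", "880"), each = 3),
    n = c(300, 500, 100, 300, 300, 200)),
  genes = sprintf("g%04d", 1:2000),
  pathway_programs = data.frame(cell_type = "T1", condition = "880",
                                pathway_id = "pw005", log2_effect = 1),
  seed = 1)
pop <- generate_cell_population(design, catalog)

sce    <- select_metabolic_genes(normalize_log1p(pop$sce), catalog)
scores <- score_all_pathways(sce, catalog, seed = 1)
epi    <- expression_power_index(scores, pop$truth$cell_type)
head(epi[epi$cluster == "T1", c("pathway", "frequency", "level", "epi", "rank")], 3)
#>  pathway frequency      level        epi rank
#>    pw005 0.6683333 0.14503709 0.09693312    1
#>    pw072 0.5833333 0.05896562 0.03439661    2
#>    pw056 0.6200000 0.05490714 0.03404243    3

occupancy(pop$truth$cell_type, pop$truth$condition,
          control = "ctrl", treated = "880")[, c(1, 4:6)]
#>  cluster prop_control prop_treated  fold
#>       T1    0.3333333        0.375 1.125
#>       T2    0.5555556        0.375 0.675
#>       T3    0.1111111        0.250 2.250
```

The planted pathway ranks first by EPI in its cell type, and the planted
occupancy doubling in T3 is recovered (fold 2.25 on one draw of 900 + 800
nuclei). The spectral side works the same way:

```r
ch <- generate_spectrum(spectrum_design(
  peaks = data.frame(center = c(2850, 2871, 2885, 2927, 2958),
                     amplitude = c(1.0, 0.4, 0.8, 0.7, 0.3),
                     fwhm = c(20, 18, 16, 22, 18)),
  noise_sd = 0.005, grid = c(2700, 3100, 1), seed = 4))
area_ratio_2885_2850(ch$spectrum)
#> [1] 0.6457245   # analytic truth: 0.640
```

See `vignettes/flymap-methods.Rmd` for the models, parameter defaults,
numerical choices and known limitations.

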