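#' Quality-control gene-count thresholds
#'
#' Closed-interval bounds on the number of detected genes per nucleus
#' (genes with raw count > 0). The defaults used in this pipeline are
#' 200-1,600 for brain tissue and 200-3,000 for gut tissue, whose nuclei
#' carry inherently higher gene content.
#'
#' @param min_genes lower bound (inclusive), > 0.
#' @param max_genes upper bound (inclusive), >= min_genes; may be `Inf`.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes, max_genes) {
  if (!(min_genes > 0 && min_genes <= max_genes))
    stop("need 0 < min_genes <= max_genes")
  structure(list(min_genes = min_genes, max_genes = max_genes),
            class = "qc_thresholds")
}

#' Default QC thresholds per tissue
#'
#' @param tissue `"brain"` (200-1,600 detected genes) or `"gut"`
#'   (200-3,000).
#' @return a [qc_thresholds()].
#' @export
qc_thresholds_for_tissue <- function(tissue = c("brain", "gut")) {
  tissue <- match.arg(tissue)
  if (tissue == "brain") qc_thresholds(200, 1600) else qc_thresholds(200, 3000)
}

#' Filter nuclei by detected-gene count
#'
#' Retains nuclei whose number of detected genes (raw count > 0) lies inside
#' the closed interval `[min_genes, max_genes]`; the gene set is unchanged.
#' A retention report is attached to the result's metadata.
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param thresholds a [qc_thresholds()].
#' @return the filtered SingleCellExperiment;
#'   `S4Vectors::metadata(.)$qc_report` holds `n_input`, `n_kept`,
#'   `n_removed` and the thresholds.
#' @export
filter_by_gene_count <- function(sce, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  counts <- SummarizedExperiment::assay(sce, "counts")
  detected <- Matrix::colSums(counts > 0)
  keep <- detected >= thresholds$min_genes & detected <= thresholds$max_genes
  out <- sce[, keep]
  S4Vectors::metadata(out)$qc_report <- list(
    n_input = ncol(sce), n_kept = sum(keep), n_removed = sum(!keep),
    min_genes = thresholds$min_genes, max_genes = thresholds$max_genes)
  out
}

#' Log-normalize counts (counts-per-`scale`, log1p)
#'
#' Per nucleus: `value = ln(1 + count * scale / total_counts)`, stored as the
#' `logcounts` assay.
#'
#' @param sce SingleCellExperiment with a `counts` assay; every nucleus must
#'   have total count > 0.
#' @param scale size-factor target (default 10,000 counts).
#' @return the SingleCellExperiment with a `logcounts` assay added.
#' @export
normalize_log1p <- function(sce, scale = 10000) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("nucleus with zero total count: ",
         paste(utils::head(colnames(counts)[totals == 0], 5), collapse = ", "))
  ln <- counts
  ln@x <- ln@x * rep.int(scale / totals, diff(ln@p))
  ln@x <- log1p(ln@x)
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  sce
}

#' Restrict a matrix to the metabolic gene set of a catalog
#'
#' The gene set becomes the union of the catalog's gene sets intersected
#' with the matrix genes (catalog order); the nucleus set is unchanged.
#' Catalog genes absent from the matrix are reported, not errors.
#'
#' @param sce SingleCellExperiment.
#' @param catalog a [pathway_catalog()].
#' @return the gene-subset SingleCellExperiment;
#'   `S4Vectors::metadata(.)$metabolic_report` lists `n_requested`,
#'   `n_present` and `missing_genes`.
#' @export
select_metabolic_genes <- function(sce, catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  requested <- catalog_gene_union(catalog)
  present <- intersect(requested, rownames(sce))
  if (length(present) == 0)
    stop("no catalog gene is present in the expression matrix")
  out <- sce[present, ]
  S4Vectors::metadata(out)$metabolic_report <- list(
    n_requested = length(requested), n_present = length(present),
    missing_genes = setdiff(requested, present))
  out
}

#' Select the top fraction of nuclei by a per-nucleus value
#'
#' Returns the `ceiling(fraction * n)` indices with the largest values;
#' ties broken by stable input order. Default fraction 0.10 implements the
#' top-10% selection rule used for single-nucleus level comparisons.
#'
#' @param values numeric per-nucleus values (>= 1 value).
#' @param fraction proportion in (0, 1], default 0.10.
#' @return integer indices into `values`, in decreasing-value order.
#' @export
top_decile_select <- function(values, fraction = 0.10) {
  if (length(values) < 1) stop("need at least one value")
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  k <- ceiling(fraction * length(values))
  ord <- order(values, decreasing = TRUE)  # radix order is stable
  ord[seq_len(k)]
}
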