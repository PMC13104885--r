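#' Per-nucleus module score for a gene set
#'
#' Bin-matched control scoring: all genes are binned into `n_bins` by their
#' average log-normalized expression; for every set gene, `n_ctrl` control
#' genes are sampled (with replacement) from its bin; the score of a nucleus
#' is the mean expression over the set genes minus the mean over all sampled
#' control genes (counting multiplicity). Deterministic for a fixed seed.
#'
#' Set genes are processed in the order given (after dropping genes absent
#' from the matrix), each consuming one `sample()` call of size `n_ctrl`
#' under `withr::with_seed(seed, ...)` — this fixes the algorithm precisely
#' enough to be reproduced independently.
#'
#' @param sce SingleCellExperiment with a `logcounts` assay.
#' @param gene_set character vector of gene symbols (>= 1 present).
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed integer seed (required).
#' @return numeric per-nucleus score, named by nucleus.
#' @export
module_score <- function(sce, gene_set, n_bins = 24, n_ctrl = 100, seed) {
  if (missing(seed)) stop("seed is required")
  x <- SummarizedExperiment::assay(sce, "logcounts")
  present <- gene_set[gene_set %in% rownames(x)]
  if (length(present) == 0)
    stop("no gene of the set is present in the matrix")
  avg <- Matrix::rowMeans(x)
  bins <- stats::setNames(expression_bins(avg, n_bins), rownames(x))
  draws <- integer(0)
  withr::with_seed(seed, {
    for (g in present) {
      pool <- which(bins == bins[[g]])
      draws <- c(draws, pool[sample.int(length(pool), n_ctrl, replace = TRUE)])
    }
  })
  # sequential accumulation in set/draw order keeps the arithmetic exactly
  # reproducible by a plain-loop re-implementation
  set_rows <- as.matrix(x[present, , drop = FALSE])
  set_sum <- numeric(ncol(x))
  for (i in seq_along(present)) set_sum <- set_sum + set_rows[i, ]
  need <- unique(draws)
  ctrl_rows <- as.matrix(x[need, , drop = FALSE])
  ctrl_sum <- numeric(ncol(x))
  for (d in draws) ctrl_sum <- ctrl_sum + ctrl_rows[match(d, need), ]
  stats::setNames(set_sum / length(present) - ctrl_sum / length(draws),
                  colnames(x))
}

# Quantile bins of average expression; ties can merge bins.
expression_bins <- function(avg, n_bins) {
  br <- unique(stats::quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Activity scores for every pathway of a catalog
#'
#' One [module_score()] column per pathway, in catalog order; pathways with
#' no gene present in the matrix are dropped with a warning. Each pathway is
#' scored with the same `seed`, so a pathway's column does not depend on the
#' rest of the catalog.
#'
#' @param sce SingleCellExperiment with a `logcounts` assay.
#' @param catalog a [pathway_catalog()].
#' @param n_bins,n_ctrl,seed as in [module_score()].
#' @return a `module_scores` matrix (nuclei x pathways) with attributes
#'   `n_bins`, `n_ctrl`, `seed`, `dropped` (pathway ids with no present
#'   gene).
#' @export
score_all_pathways <- function(sce, catalog, n_bins = 24, n_ctrl = 100, seed) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  if (missing(seed)) stop("seed is required")
  present <- vapply(catalog$genes,
                    function(g) any(g %in% rownames(sce)), TRUE)
  if (!any(present)) stop("no catalog pathway has genes in the matrix")
  if (any(!present))
    warning("dropping pathway(s) with no present gene: ",
            paste(catalog$pathway_id[!present], collapse = ", "))
  kept <- which(present)
  cols <- lapply(kept, function(i) {
    module_score(sce, catalog$genes[[i]], n_bins = n_bins, n_ctrl = n_ctrl,
                 seed = seed)
  })
  scores <- do.call(cbind, cols)
  colnames(scores) <- catalog$pathway_id[kept]
  structure(scores, class = c("module_scores", class(scores)),
            n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
            dropped = catalog$pathway_id[!present])
}

#' Dot-plot statistics: fraction expressing and normalized level per group
#'
#' Per (group, column): `fraction` = proportion of the group's nuclei with
#' value > 0; `mean_level` = group mean; `norm_level` = min-max
#' normalization of the group means across groups within each column
#' (constant columns get 0).
#'
#' @param values nuclei x pathways (or genes) numeric matrix.
#' @param groups per-nucleus group labels; every group non-empty.
#' @return data.frame with columns `group`, `pathway`, `fraction`,
#'   `mean_level`, `norm_level`.
#' @export
dotplot_stats <- function(values, groups) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(groups))
  if (any(table(groups) == 0)) stop("empty group")
  gl <- sort(unique(as.character(groups)))
  out <- do.call(rbind, lapply(gl, function(g) {
    v <- values[groups == g, , drop = FALSE]
    data.frame(group = g, pathway = colnames(values),
               fraction = colMeans(v > 0), mean_level = colMeans(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$norm_level <- stats::ave(out$mean_level, out$pathway, FUN = function(m) {
    rng <- range(m)
    if (diff(rng) == 0) rep(0, length(m)) else (m - rng[1]) / diff(rng)
  })
  out
}

#' Expression Power Index per (cluster, pathway)
#'
#' EPI = expression frequency x expression level: `f` is the fraction of the
#' cluster's nuclei with score > 0, `m` the mean score over the cluster's
#' nuclei, and `EPI = f * max(m, 0)` (a negative mean cannot make a pathway
#' "powerful"). Pathways are ranked per cluster by decreasing EPI, ties
#' broken alphabetically by pathway id.
#'
#' @param scores nuclei x pathways score matrix ([score_all_pathways()]).
#' @param assignment per-nucleus cluster ids, same nuclei/order.
#' @return data.frame with columns `cluster`, `pathway`, `frequency`,
#'   `level`, `epi`, `rank`.
#' @export
expression_power_index <- function(scores, assignment) {
  scores <- as.matrix(scores)
  assignment <- as.vector(assignment)
  stopifnot(nrow(scores) == length(assignment))
  out <- do.call(rbind, lapply(sort(unique(assignment)), function(k) {
    v <- scores[assignment == k, , drop = FALSE]
    if (nrow(v) == 0) stop("empty cluster: ", k)
    f <- colMeans(v > 0)
    m <- colMeans(v)
    epi <- f * pmax(m, 0)
    d <- data.frame(cluster = k, pathway = colnames(scores),
                    frequency = f, level = m, epi = epi,
                    stringsAsFactors = FALSE)
    d <- d[order(-d$epi, d$pathway), ]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum differential expression between two nucleus groups
#'
#' Tests every gene expressed (raw value > 0 on the log-normalized layer) in
#' at least `min_fraction` of either group: two-sided rank-sum P,
#' `log2FC = log2((mean(expm1(A)) + 1) / (mean(expm1(B)) + 1))`, and
#' Benjamini-Hochberg adjustment over the tested genes.
#'
#' @param sce SingleCellExperiment with a `logcounts` assay.
#' @param group_A,group_B disjoint non-empty nucleus index or name vectors.
#' @param min_fraction expression-fraction filter (default 0.10).
#' @return data.frame with columns `gene`, `log2fc`, `p`, `p_adj`,
#'   `frac_A`, `frac_B`, ordered by increasing `p`.
#' @export
wilcoxon_de <- function(sce, group_A, group_B, min_fraction = 0.10) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  if (is.character(group_A)) group_A <- match(group_A, colnames(x))
  if (is.character(group_B)) group_B <- match(group_B, colnames(x))
  if (length(group_A) == 0 || length(group_B) == 0)
    stop("both groups must be non-empty")
  if (length(intersect(group_A, group_B)) > 0)
    stop("groups must be disjoint")
  a <- as.matrix(x[, group_A, drop = FALSE])
  b <- as.matrix(x[, group_B, drop = FALSE])
  frac_a <- rowMeans(a > 0)
  frac_b <- rowMeans(b > 0)
  keep <- which(frac_a >= min_fraction | frac_b >= min_fraction)
  if (length(keep) == 0)
    return(data.frame(gene = character(), log2fc = numeric(), p = numeric(),
                      p_adj = numeric(), frac_A = numeric(),
                      frac_B = numeric()))
  p <- vapply(keep, function(i) {
    pv <- suppressWarnings(
      stats::wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value)
    if (is.na(pv)) 1 else pv   # fully tied gene: no evidence either way
  }, 1)
  log2fc <- log2((rowMeans(expm1(a[keep, , drop = FALSE])) + 1) /
                   (rowMeans(expm1(b[keep, , drop = FALSE])) + 1))
  out <- data.frame(gene = rownames(x)[keep], log2fc = log2fc, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    frac_A = frac_a[keep], frac_B = frac_b[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$p), ]
}
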