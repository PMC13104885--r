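#' Fraction of a cluster's nuclei expressing a gene
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param cells non-empty nucleus index or name vector.
#' @param gene gene symbol present in the matrix.
#' @return proportion of `cells` with raw count > 0.
#' @export
expression_fraction <- function(sce, cells, gene) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  if (!gene %in% rownames(counts)) stop("unknown gene: ", gene)
  if (length(cells) == 0) stop("empty cluster")
  mean(counts[gene, cells] > 0)
}

#' Ligand-receptor interaction score
#'
#' Product contract: mean log-normalized ligand expression over the source
#' (gut) cluster times mean log-normalized receptor expression over the
#' target (brain) cluster. Monotone in both inputs and zero when either
#' side is silent. An additive alternative (`method = "sum"`, mean of the
#' two means) is exposed for sensitivity checks.
#'
#' @param sce SingleCellExperiment with a `logcounts` assay.
#' @param source_cells,target_cells non-empty nucleus index/name vectors.
#' @param ligand,receptor gene symbols present in the matrix.
#' @param method `"product"` (default) or `"sum"`.
#' @return non-negative interaction score (a.u.).
#' @export
lr_score <- function(sce, source_cells, target_cells, ligand, receptor,
                     method = c("product", "sum")) {
  method <- match.arg(method)
  x <- SummarizedExperiment::assay(sce, "logcounts")
  for (g in c(ligand, receptor))
    if (!g %in% rownames(x)) stop("unknown gene: ", g)
  if (length(source_cells) == 0 || length(target_cells) == 0)
    stop("source and target clusters must be non-empty")
  ml <- mean(x[ligand, source_cells])
  mr <- mean(x[receptor, target_cells])
  if (method == "product") ml * mr else (ml + mr) / 2
}

#' Significance of a ligand-receptor interaction
#'
#' One-sided rank-sum enrichment tests: ligand expression in the source
#' cluster versus all other nuclei of the same tissue, and receptor
#' expression in the target cluster versus all other nuclei of its tissue.
#' The pair P-value is the maximum of the two (both sides must be
#' enriched).
#'
#' @param sce SingleCellExperiment with `logcounts` and a `tissue` colData
#'   column.
#' @param source_cells,target_cells nucleus index/name vectors; neither may
#'   cover its whole tissue.
#' @param ligand,receptor gene symbols.
#' @return pair P-value in [0, 1].
#' @export
pair_significance <- function(sce, source_cells, target_cells,
                              ligand, receptor) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  tissue <- SummarizedExperiment::colData(sce)$tissue
  if (is.null(tissue)) stop("colData must contain a 'tissue' column")
  idx <- function(cells) {
    if (is.character(cells)) match(cells, colnames(x)) else cells
  }
  one_side <- function(cells, gene) {
    cells <- idx(cells)
    tis <- unique(tissue[cells])
    if (length(tis) != 1) stop("cluster spans multiple tissues")
    rest <- setdiff(which(tissue == tis), cells)
    if (length(rest) == 0)
      stop("cluster covers the whole tissue; no reference nuclei")
    pv <- suppressWarnings(stats::wilcox.test(
      as.numeric(x[gene, cells]), as.numeric(x[gene, rest]),
      alternative = "greater", exact = FALSE)$p.value)
    if (is.na(pv)) 1 else pv
  }
  max(one_side(source_cells, ligand), one_side(target_cells, receptor))
}

#' Score a ligand-receptor pair table between cluster sets
#'
#' For every (source cluster, target cluster, pair) combination: the
#' interaction score, ligand/receptor expression fractions, and the pair
#' P-value.
#'
#' @param sce SingleCellExperiment with `counts`, `logcounts` and a
#'   `tissue` colData column.
#' @param pairs data.frame with columns `ligand`, `receptor`, `pathway`;
#'   pairs with genes absent from the matrix are skipped.
#' @param source_clusters named list of nucleus vectors (gut clusters).
#' @param target_clusters named list of nucleus vectors (brain clusters).
#' @param method scoring contract passed to [lr_score()].
#' @return data.frame (an L-R score table) with columns `source`, `target`,
#'   `ligand`, `receptor`, `pathway`, `score`, `lig_frac`, `rec_frac`, `p`.
#' @export
lr_score_table <- function(sce, pairs, source_clusters, target_clusters,
                           method = "product") {
  validate_lr_pairs(pairs)
  genes <- rownames(sce)
  keep <- pairs$ligand %in% genes & pairs$receptor %in% genes
  pairs <- pairs[keep, , drop = FALSE]
  rows <- list()
  for (s in names(source_clusters)) for (t in names(target_clusters)) {
    src <- source_clusters[[s]]; tgt <- target_clusters[[t]]
    for (i in seq_len(nrow(pairs))) {
      lig <- pairs$ligand[i]; rec <- pairs$receptor[i]
      rows[[length(rows) + 1]] <- data.frame(
        source = s, target = t, ligand = lig, receptor = rec,
        pathway = pairs$pathway[i],
        score = lr_score(sce, src, tgt, lig, rec, method = method),
        lig_frac = expression_fraction(sce, src, lig),
        rec_frac = expression_fraction(sce, tgt, rec),
        p = pair_significance(sce, src, tgt, lig, rec),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), target = character(),
               ligand = character(), receptor = character(),
               pathway = character(), score = numeric(),
               lig_frac = numeric(), rec_frac = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Filter an L-R score table on significance and expression fractions
#'
#' Keeps rows with pair P < `alpha` AND ligand fraction > `min_fraction`
#' AND receptor fraction > `min_fraction` (strict inequalities: "more than
#' 10% of nuclei", P-value below 0.05).
#'
#' @param table an [lr_score_table()] result with `p`, `lig_frac`,
#'   `rec_frac` columns.
#' @param alpha significance threshold (default 0.05).
#' @param min_fraction expression-fraction threshold (default 0.10).
#' @return the qualifying subset of `table`.
#' @export
filter_pairs <- function(table, alpha = 0.05, min_fraction = 0.10) {
  stopifnot(all(c("p", "lig_frac", "rec_frac") %in% names(table)))
  out <- table[table$p < alpha & table$lig_frac > min_fraction &
                 table$rec_frac > min_fraction, , drop = FALSE]
  rownames(out) <- NULL
  out
}

lr_key <- function(t) paste(t$source, t$target, t$ligand, t$receptor, sep = "|")

#' Differential L-R interaction levels between conditions
#'
#' `delta = score(A) - score(B)` per (source, target, pair) row; a positive
#' value indicates upregulation in condition A.
#'
#' @param table_A,table_B [lr_score_table()] results over the same
#'   (source, target, pair) universe.
#' @return `table_A` augmented with `score_B`, `p_B`, `lig_frac_B`,
#'   `rec_frac_B` and `delta` columns.
#' @export
differential_lr <- function(table_A, table_B) {
  ka <- lr_key(table_A); kb <- lr_key(table_B)
  if (!setequal(ka, kb) || length(ka) != length(kb))
    stop("the two tables cover different (source, target, pair) universes")
  m <- match(ka, kb)
  out <- table_A
  names(out)[names(out) == "score"] <- "score_A"
  names(out)[names(out) == "p"] <- "p_A"
  out$score_B <- table_B$score[m]
  out$p_B <- table_B$p[m]
  out$lig_frac_B <- table_B$lig_frac[m]
  out$rec_frac_B <- table_B$rec_frac[m]
  out$delta <- out$score_A - out$score_B
  out
}

#' Correlate L-R interaction scores between two conditions
#'
#' Pearson correlation over matched pair scores, plus the rows with the
#' largest absolute residuals from the least-squares line (candidate
#' condition-responsive interactions).
#'
#' @param table_A,table_B [lr_score_table()] results with >= 3 common rows.
#' @param n_outliers how many top-residual rows to flag (default 5).
#' @return list with `r`, `p`, and `outliers` (data.frame with the matched
#'   scores, residuals and residual ranks).
#' @export
correlate_conditions <- function(table_A, table_B, n_outliers = 5) {
  ka <- lr_key(table_A); kb <- lr_key(table_B)
  common <- intersect(ka, kb)
  if (length(common) < 3) stop("need at least 3 common rows")
  a <- table_A$score[match(common, ka)]
  b <- table_B$score[match(common, kb)]
  ct <- stats::cor.test(a, b)
  resid <- stats::resid(stats::lm(b ~ a))
  ord <- order(-abs(resid))
  out <- data.frame(key = common, score_A = a, score_B = b,
                    residual = resid,
                    rank = match(seq_along(common), ord),
                    stringsAsFactors = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value,
       outliers = out[ord[seq_len(min(n_outliers, nrow(out)))], ])
}

#' Aggregate significantly differential pairs per cluster
#'
#' Counts the (already filtered) differential pairs per source cluster and
#' per target cluster; clusters with fewer than `min_pairs` pairs are
#' omitted from the report and listed with the reason.
#'
#' @param differential a filtered [differential_lr()] table.
#' @param min_pairs omission threshold (default 10 pairs).
#' @return list with `source` and `target` count data.frames (columns
#'   `cluster`, `n_pairs`) and `omitted` (columns `side`, `cluster`,
#'   `n_pairs`, `reason`).
#' @export
aggregate_by_cluster <- function(differential, min_pairs = 10) {
  count_side <- function(col, side) {
    if (nrow(differential) == 0)
      tab <- integer(0)
    else
      tab <- table(differential[[col]])
    d <- data.frame(cluster = names(tab), n_pairs = as.vector(tab),
                    stringsAsFactors = FALSE)
    keep <- d$n_pairs >= min_pairs
    list(kept = d[keep, , drop = FALSE],
         omitted = if (any(!keep))
           data.frame(side = side, cluster = d$cluster[!keep],
                      n_pairs = d$n_pairs[!keep],
                      reason = sprintf("fewer than %d differential pairs",
                                       min_pairs),
                      stringsAsFactors = FALSE)
         else NULL)
  }
  s <- count_side("source", "source")
  t <- count_side("target", "target")
  omitted <- rbind(s$omitted, t$omitted)
  if (is.null(omitted))
    omitted <- data.frame(side = character(), cluster = character(),
                          n_pairs = integer(), reason = character())
  rownames(s$kept) <- rownames(t$kept) <- rownames(omitted) <- NULL
  list(source = s$kept, target = t$kept, omitted = omitted)
}

#' Category-level comparison of L-R interaction levels between conditions
#'
#' Per signalling-pathway category: the mean score per condition over the
#' member pairs and a two-sided rank-sum P between the conditions'
#' member-pair scores. Categories at P >= `alpha` are flagged `not_shown`;
#' single-pair categories carry a small-n warning flag.
#'
#' @param table_A,table_B [lr_score_table()] results over the same universe.
#' @param alpha display significance threshold (default 0.05).
#' @return data.frame with columns `category`, `n_pairs`, `mean_A`,
#'   `mean_B`, `p`, `not_shown`, `small_n`.
#' @export
category_comparison <- function(table_A, table_B, alpha = 0.05) {
  ka <- lr_key(table_A); kb <- lr_key(table_B)
  if (!setequal(ka, kb))
    stop("the two tables cover different universes")
  m <- match(ka, kb)
  cats <- table_A$pathway
  if (any(is.na(cats) | !nzchar(cats))) stop("unmapped pair (empty category)")
  out <- do.call(rbind, lapply(sort(unique(cats)), function(cc) {
    sel <- cats == cc
    a <- table_A$score[sel]
    b <- table_B$score[m][sel]
    pv <- if (sum(sel) >= 1 && (stats::sd(c(a, b)) > 0))
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    else 1
    if (is.na(pv)) pv <- 1
    data.frame(category = cc, n_pairs = sum(sel),
               mean_A = mean(a), mean_B = mean(b), p = pv,
               stringsAsFactors = FALSE)
  }))
  out$not_shown <- out$p >= alpha
  out$small_n <- out$n_pairs < 2
  if (any(out$small_n))
    warning("single-pair categor(ies): ",
            paste(out$category[out$small_n], collapse = ", "))
  rownames(out) <- NULL
  out
}
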