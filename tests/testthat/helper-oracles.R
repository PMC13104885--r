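# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately use plain dense loops, not the package's vectorized
# paths.

suppressPackageStartupMessages({
  library(SingleCellExperiment)
  library(SummarizedExperiment)
})

# Brute-force re-implementation of the binned-control module score.
oracle_module_score <- function(sce, gene_set, n_bins = 24, n_ctrl = 100,
                                seed) {
  x <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  present <- gene_set[gene_set %in% rownames(x)]
  avg <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) avg[i] <- mean(x[i, ])
  br <- unique(quantile(avg, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(avg, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bins) <- rownames(x)
  draws <- integer(0)
  withr::with_seed(seed, {
    for (g in present) {
      pool <- which(bins == bins[[g]])
      draws <- c(draws, pool[sample.int(length(pool), n_ctrl, replace = TRUE)])
    }
  })
  scores <- numeric(ncol(x))
  for (c in seq_len(ncol(x))) {
    set_sum <- 0
    for (g in present) set_sum <- set_sum + x[g, c]
    ctrl_sum <- 0
    for (d in draws) ctrl_sum <- ctrl_sum + x[d, c]
    scores[c] <- set_sum / length(present) - ctrl_sum / length(draws)
  }
  names(scores) <- colnames(x)
  scores
}

# Random count SCE with a log-normalized layer, for scoring fixtures.
make_test_sce <- function(n_genes = 200, n_cells = 50, seed = 99) {
  withr::with_seed(seed, {
    counts <- matrix(rnbinom(n_genes * n_cells, size = 2,
                             mu = rlnorm(n_genes, 0, 1)),
                     nrow = n_genes,
                     dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                     sprintf("c%04d", seq_len(n_cells))))
    counts[, colSums(counts) == 0][1, ] <- 1L   # guard zero-total cells
    sce <- SingleCellExperiment::SingleCellExperiment(assays = list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")))
    normalize_log1p(sce)
  })
}

# SCE from a dense logcounts matrix given directly (genes x cells).
sce_from_logcounts <- function(logm) {
  SingleCellExperiment::SingleCellExperiment(assays = list(
    counts = Matrix::Matrix(expm1(logm), sparse = TRUE),
    logcounts = Matrix::Matrix(logm, sparse = TRUE)))
}

# Score matrix with planted latent-factor correlation blocks at exact
# population correlation r (Gaussian factor model).
factor_block_scores <- function(n, block_sizes, r, n_pathways, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * n_pathways), n, n_pathways)
    j0 <- 0
    for (b in block_sizes) {
      f <- rnorm(n)
      for (j in j0 + seq_len(b))
        x[, j] <- sqrt(r) * f + sqrt(1 - r) * rnorm(n)
      j0 <- j0 + b
    }
    colnames(x) <- sprintf("pw%03d", seq_len(n_pathways))
    x
  })
}

# Standard 3-type, 2-condition metabolic population used by the
# profiling/scoring recovery tests: each cell type has its own 3-pathway
# program at log2 effect 1.5 (condition-independent), on a 20-pathway
# catalog over 1,500 genes.
make_typed_population <- function(seed, n_per_type = c(120, 100, 80),
                                  conditions = c("ctrl", "880"),
                                  extra_programs = NULL,
                                  type_effect = 1.5) {
  cat20 <- generate_pathway_catalog(4, 20, c(10, 25), 1500, 0.02, seed = 10)
  types <- c("T1", "T2", "T3")
  pp <- do.call(rbind, lapply(seq_along(types), function(i) {
    data.frame(cell_type = types[i], condition = "all",
               pathway_id = cat20$pathway_id[(i - 1) * 3 + 1:3],
               log2_effect = type_effect)
  }))
  if (!is.null(extra_programs)) pp <- rbind(pp, extra_programs)
  if (type_effect == 0) pp <- extra_programs
  des <- population_design(
    n_nuclei = data.frame(cell_type = rep(types, length(conditions)),
                          condition = rep(conditions, each = length(types)),
                          n = rep(n_per_type, length(conditions))),
    genes = sprintf("g%04d", 1:1500),
    pathway_programs = pp,
    library_size_range = c(1000, 3000), seed = seed)
  pop <- generate_cell_population(des, cat20)
  pop$catalog <- cat20
  pop
}

# small two-tissue SCE with named clusters for L-R tests; the gene baseline
# is drawn from mu_seed so that two conditions can share it while their
# counts differ
make_lr_sce <- function(seed = 1, n_per_cluster = 30, n_genes = 50,
                        lig_up = NULL, up_factor = 2, mu_seed = seed) {
  mu <- withr::with_seed(mu_seed, rlnorm(n_genes, 0, 1))
  withr::with_seed(seed, {
    clusters <- c(G1 = "gut", G2 = "gut", B1 = "brain", B2 = "brain")
    counts <- NULL; tissue <- c(); cluster <- c()
    for (k in names(clusters)) {
      m <- mu
      if (!is.null(lig_up) && k == lig_up$cluster)
        m[lig_up$gene_idx] <- m[lig_up$gene_idx] * up_factor
      block <- matrix(rnbinom(n_genes * n_per_cluster, size = 2, mu = m),
                      nrow = n_genes)
      counts <- cbind(counts, block)
      tissue <- c(tissue, rep(clusters[[k]], n_per_cluster))
      cluster <- c(cluster, rep(k, n_per_cluster))
    }
    rownames(counts) <- sprintf("g%03d", seq_len(n_genes))
    colnames(counts) <- sprintf("n%04d", seq_len(ncol(counts)))
    counts[1, colSums(counts) == 0] <- 1L
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
      colData = S4Vectors::DataFrame(tissue = tissue, cluster = cluster,
                                     row.names = colnames(counts)))
    normalize_log1p(sce)
  })
}

cluster_cells <- function(sce, k) which(SummarizedExperiment::colData(sce)$cluster == k)
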