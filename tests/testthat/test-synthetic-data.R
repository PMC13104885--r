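test_that("generated catalogs have the requested shape and are deterministic", {
  cat0 <- generate_pathway_catalog(11, 81, c(5, 40), 2000, 0.05, seed = 0)
  expect_s3_class(cat0, "pathway_catalog")
  expect_equal(nrow(cat0), 81)
  expect_equal(length(unique(cat0$category)), 11)
  expect_false(anyDuplicated(cat0$pathway_id) > 0)
  expect_true(all(vapply(cat0$genes, length, 1L) >= 5))
  expect_true(all(vapply(cat0$genes, length, 1L) <= 40))
  expect_identical(cat0, generate_pathway_catalog(11, 81, c(5, 40), 2000,
                                                  0.05, seed = 0))
  cat1 <- generate_pathway_catalog(11, 81, c(5, 40), 2000, 0.05, seed = 1)
  expect_false(identical(cat0$genes, cat1$genes))
})

test_that("a single pathway filling the universe is forced by the sizes", {
  cat1 <- generate_pathway_catalog(1, 1, c(3, 3), 3, 0, seed = 0)
  expect_equal(sort(cat1$genes[[1]]), sprintf("g%04d", 1:3))
})

test_that("mean pairwise Jaccard tracks the requested overlap", {
  cat0 <- generate_pathway_catalog(11, 81, c(5, 40), 2000, 0.05, seed = 0)
  # independent Jaccard computation
  js <- c()
  for (i in 1:80) for (j in (i + 1):81) {
    a <- cat0$genes[[i]]; b <- cat0$genes[[j]]
    js <- c(js, length(intersect(a, b)) / length(union(a, b)))
  }
  expect_lt(abs(mean(js) - 0.05), 0.02)
  # zero overlap: pathways disjoint
  catd <- generate_pathway_catalog(3, 10, c(5, 10), 500, 0, seed = 0)
  all_genes <- unlist(catd$genes)
  expect_equal(anyDuplicated(all_genes), 0L)
})

test_that("infeasible catalog sizes raise errors", {
  expect_error(generate_pathway_catalog(1, 2, c(50, 60), 30, 0.05, seed = 0),
               "universe")
  expect_error(generate_pathway_catalog(2, 10, c(40, 40), 100, 0, seed = 0),
               "disjoint")
})

test_that("generated populations are valid, deterministic NB counts", {
  pop <- make_typed_population(seed = 7, n_per_type = c(30, 25, 20))
  counts <- as.matrix(assay(pop$sce, "counts"))
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  expect_false(anyNA(counts))
  pop2 <- make_typed_population(seed = 7, n_per_type = c(30, 25, 20))
  expect_identical(counts, as.matrix(assay(pop2$sce, "counts")))
  pop3 <- make_typed_population(seed = 8, n_per_type = c(30, 25, 20))
  expect_false(identical(counts, as.matrix(assay(pop3$sce, "counts"))))
})

test_that("ground-truth occupancy echoes the design exactly", {
  cat2 <- generate_pathway_catalog(2, 4, c(5, 10), 200, 0, seed = 1)
  des <- population_design(
    n_nuclei = data.frame(cell_type = c("T1", "T2", "T1", "T2"),
                          condition = c("ctrl", "ctrl", "880", "880"),
                          n = c(100, 900, 140, 860)),
    genes = sprintf("g%04d", 1:200), seed = 2)
  pop <- generate_cell_population(des, cat2)
  occ <- pop$truth$occupancy
  expect_equal(occ$proportion[occ$condition == "ctrl" & occ$cell_type == "T1"],
               0.10)
  expect_equal(occ$proportion[occ$condition == "880" & occ$cell_type == "T1"],
               0.14)
  for (cond in unique(occ$condition))
    expect_equal(sum(occ$proportion[occ$condition == cond]), 1)
})

test_that("a planted log2 effect of 1 doubles mean raw counts of the pathway", {
  cat2 <- generate_pathway_catalog(2, 5, c(10, 20), 300, 0, seed = 2)
  des <- population_design(
    n_nuclei = data.frame(cell_type = "T1", condition = c("ctrl", "880"),
                          n = c(500, 500)),
    genes = sprintf("g%04d", 1:300),
    pathway_programs = data.frame(cell_type = "T1", condition = "880",
                                  pathway_id = "pw001", log2_effect = 1),
    library_size_range = c(500, 1500), seed = 1)
  pop <- generate_cell_population(des, cat2)
  g <- intersect(cat2$genes[[1]], rownames(pop$sce))
  cc <- as.matrix(assay(pop$sce, "counts")[g, ])
  ratio <- mean(cc[, pop$truth$condition == "880"]) /
    mean(cc[, pop$truth$condition == "ctrl"])
  expect_lt(abs(ratio - 2.0), 0.15)
})

test_that("effects referencing unknown pathways or genes are rejected", {
  cat2 <- generate_pathway_catalog(2, 4, c(5, 10), 200, 0, seed = 1)
  base <- list(n_nuclei = data.frame(cell_type = "T1", condition = "ctrl",
                                     n = 10),
               genes = sprintf("g%04d", 1:200))
  des <- population_design(base$n_nuclei, base$genes,
                           pathway_programs = data.frame(
                             cell_type = "T1", condition = "all",
                             pathway_id = "nope", log2_effect = 1))
  expect_error(generate_cell_population(des, cat2), "unknown pathway")
  des2 <- population_design(base$n_nuclei, base$genes,
                            lr_plantings = data.frame(
                              condition = "ctrl", source_type = "T1",
                              ligand = "absent_gene", target_type = "T1",
                              receptor = "g0001", log2_effect = 1))
  expect_error(generate_cell_population(des2, cat2), "unknown gene")
})

test_that("conditions with identical designs are statistically exchangeable", {
  cat2 <- generate_pathway_catalog(2, 4, c(5, 10), 100, 0, seed = 1)
  pvals <- vapply(1:100, function(s) {
    des <- population_design(
      n_nuclei = data.frame(cell_type = "T1", condition = c("A", "B"),
                            n = c(25, 25)),
      genes = sprintf("g%04d", 1:100), library_size_range = c(300, 800),
      seed = s)
    pop <- generate_cell_population(des, cat2)
    totals <- Matrix::colSums(assay(pop$sce, "counts"))
    suppressWarnings(wilcox.test(totals[pop$truth$condition == "A"],
                                 totals[pop$truth$condition == "B"],
                                 exact = FALSE)$p.value)
  }, 1)
  expect_gte(mean(pvals > 0.05), 0.95)
})

test_that("count-level correlated blocks elevate within-block score correlation", {
  cat20 <- generate_pathway_catalog(4, 20, c(10, 25), 1500, 0.02, seed = 10)
  des <- population_design(
    n_nuclei = data.frame(cell_type = "T1", condition = "ctrl", n = 800),
    genes = sprintf("g%04d", 1:1500),
    corr_blocks = list(list(pathway_ids = cat20$pathway_id[1:4],
                            loading = 0.8)),
    seed = 5)
  pop <- generate_cell_population(des, cat20)
  sce <- select_metabolic_genes(normalize_log1p(pop$sce), cat20)
  sc <- score_all_pathways(sce, cat20, seed = 5)
  r <- cor(sc)
  within <- r[1:4, 1:4][upper.tri(r[1:4, 1:4])]
  cross <- r[1:4, 11:20]
  expect_gt(mean(within), mean(cross) + 0.2)
})

test_that("generated L-R tables have the requested shape and determinism", {
  labs <- c("EGFR", "FGFR", "AstA")
  t3 <- generate_lr_table(3, labs, sprintf("g%03d", 1:100), seed = 0)
  expect_equal(nrow(t3), 3)
  expect_setequal(t3$pathway, labs)
  expect_true(all(t3$ligand != t3$receptor))
  expect_identical(t3, generate_lr_table(3, labs, sprintf("g%03d", 1:100),
                                         seed = 0))
  t0 <- generate_lr_table(0, labs, sprintf("g%03d", 1:100), seed = 0)
  expect_equal(nrow(t0), 0)
  expect_named(t0, c("ligand", "receptor", "pathway"))
  expect_error(generate_lr_table(60, labs, sprintf("g%03d", 1:100), seed = 0),
               "too small")
})

test_that("curated pair fixture round-trips through CSV byte-identically", {
  fixture <- system.file("extdata", "lr_pairs_demo.csv", package = "flymap")
  pairs <- read_lr_pairs(fixture)
  expect_true(all(c("vn", "pyr", "bnl") %in% pairs$ligand))
  tmp <- tempfile(fileext = ".csv")
  write_lr_pairs(pairs, tmp)
  expect_identical(readLines(tmp), readLines(fixture))
})

test_that("synthetic spectra match their analytic truth", {
  # no peaks, zero baseline/noise
  z <- generate_spectrum(spectrum_design(grid = c(1000, 1100, 1)))
  expect_true(all(z$spectrum$intensities == 0))
  # single Gaussian
  g <- generate_spectrum(spectrum_design(
    peaks = data.frame(center = 2850, amplitude = 1, fwhm = 20),
    grid = c(2700, 3000, 1)))
  expect_equal(g$spectrum$intensities[g$spectrum$wavenumbers == 2850], 1)
  expect_equal(g$truth$fwhm, 20)
  # two-Gaussian: trapezoid integral equals sum of analytic areas to 0.1%
  d2 <- spectrum_design(
    peaks = data.frame(center = c(2850, 2935), amplitude = c(1, 0.7),
                       fwhm = c(20, 16)),
    grid = c(2700, 3100, 1))
  s2 <- generate_spectrum(d2)
  w <- s2$spectrum$wavenumbers; y <- s2$spectrum$intensities
  trap <- sum(diff(w) * (head(y, -1) + tail(y, -1)) / 2)
  expect_lt(abs(trap - sum(s2$truth$area)) / sum(s2$truth$area), 0.001)
  # determinism of the noise
  dn <- spectrum_design(peaks = data.frame(center = 1295, amplitude = 1,
                                           fwhm = 14),
                        noise_sd = 0.01, grid = c(1200, 1400, 1), seed = 4)
  expect_identical(generate_spectrum(dn)$spectrum$intensities,
                   generate_spectrum(dn)$spectrum$intensities)
})
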