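#' Generate a synthetic pathway catalog
#'
#' Builds a gene-set collection shaped like the Drosophila KEGG metabolic
#' collection (by default 81 pathways in 11 categories) over a synthetic gene
#' universe. Pathway sizes are drawn uniformly from `genes_per_pathway`.
#' When `overlap_fraction > 0`, every pathway samples its genes from a shared
#' "hot pool" of size `m = s * (1 + J) / (2 * J)` (s = mean pathway size,
#' J = target overlap), which makes the expected pairwise Jaccard index of
#' two random gene sets approximately `overlap_fraction`. With
#' `overlap_fraction = 0` pathways are disjoint (the universe is partitioned).
#'
#' @param n_categories number of categories (>= 1).
#' @param n_pathways number of pathways (>= n_categories); assigned to
#'   categories round-robin so every category is non-empty.
#' @param genes_per_pathway integer range (length 2, or a single size) of
#'   genes per pathway.
#' @param gene_universe_size number of genes in the synthetic universe
#'   (symbols `g0001`, `g0002`, ...).
#' @param overlap_fraction target mean pairwise Jaccard overlap in [0, 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [pathway_catalog()].
#' @export
generate_pathway_catalog <- function(n_categories = 11, n_pathways = 81,
                                     genes_per_pathway = c(5, 40),
                                     gene_universe_size = 2000,
                                     overlap_fraction = 0.05, seed = 0) {
  if (length(genes_per_pathway) == 1)
    genes_per_pathway <- rep(genes_per_pathway, 2)
  stopifnot(n_categories >= 1, n_pathways >= n_categories,
            genes_per_pathway[1] >= 1,
            genes_per_pathway[1] <= genes_per_pathway[2],
            overlap_fraction >= 0, overlap_fraction < 1)
  if (gene_universe_size < genes_per_pathway[2])
    stop("gene universe smaller than the maximum pathway size")
  universe <- sprintf("g%04d", seq_len(gene_universe_size))
  withr::with_seed(seed, {
    size_range <- seq(genes_per_pathway[1], genes_per_pathway[2])
    sizes <- size_range[sample.int(length(size_range), n_pathways,
                                   replace = TRUE)]
    if (overlap_fraction == 0) {
      if (sum(sizes) > gene_universe_size)
        stop("gene universe too small for disjoint pathways of the requested sizes")
      pool <- sample(universe)
      ends <- cumsum(sizes)
      genes <- lapply(seq_len(n_pathways), function(i) {
        pool[seq(ends[i] - sizes[i] + 1, ends[i])]
      })
    } else {
      s_bar <- mean(genes_per_pathway)
      m <- round(s_bar * (1 + overlap_fraction) / (2 * overlap_fraction))
      m <- min(max(m, max(sizes)), gene_universe_size)
      hot <- sample(universe, m)
      genes <- lapply(sizes, function(s) sample(hot, s))
    }
    cats <- sprintf("category_%02d", seq_len(n_categories))
    pathway_catalog(
      pathway_id = sprintf("pw%03d", seq_len(n_pathways)),
      pathway_name = sprintf("synthetic pathway %03d", seq_len(n_pathways)),
      category = cats[((seq_len(n_pathways) - 1) %% n_categories) + 1],
      genes = genes
    )
  })
}

#' Design of a synthetic single-nucleus population
#'
#' Declares everything [generate_cell_population()] needs: per-(cell type,
#' condition) nucleus counts, gene-level negative-binomial baseline means, a
#' shared dispersion, multiplicative pathway programs, ligand-receptor
#' plantings, correlated pathway blocks, and the library-size range.
#'
#' @param n_nuclei data.frame with columns `cell_type`, `condition`, `n`
#'   (positive integers), one row per (cell type, condition) pair.
#' @param genes character vector of gene symbols in the simulated
#'   transcriptome.
#' @param baseline_mean positive numeric per gene; if `NULL`, drawn
#'   log-normally (meanlog -0.5, sdlog 1) from `seed`.
#' @param dispersion shared negative-binomial size parameter (> 0);
#'   default 2, typical of the overdispersion seen in nuclear transcriptomes.
#' @param pathway_programs data.frame (`cell_type`, `condition`,
#'   `pathway_id`, `log2_effect`) of multiplicative mean shifts applied to
#'   all genes of a pathway in the targeted cell type; `condition = "all"`
#'   applies in every condition, and likewise `cell_type = "all"`.
#' @param lr_plantings data.frame (`condition`, `source_type`, `ligand`,
#'   `target_type`, `receptor`, `log2_effect`) of per-gene mean multipliers:
#'   the ligand in the source type and the receptor in the target type, in
#'   the named condition.
#' @param corr_blocks list of blocks, each `list(pathway_ids =, loading =)`:
#'   a per-nucleus standard-normal latent factor shared by all genes of the
#'   block's pathways, applied as the mean-preserving multiplier
#'   `exp(loading * z - loading^2 / 2)`.
#' @param library_size_range length-2 positive numeric: per-nucleus expected
#'   library sizes are drawn uniformly from this range (default 1000-3000,
#'   consistent with nuclei carrying a few hundred to a few thousand
#'   detected genes).
#' @param seed integer seed.
#' @return an object of class `population_design`.
#' @export
population_design <- function(n_nuclei, genes, baseline_mean = NULL,
                              dispersion = 2,
                              pathway_programs = NULL, lr_plantings = NULL,
                              corr_blocks = list(),
                              library_size_range = c(1000, 3000), seed = 0) {
  stopifnot(is.data.frame(n_nuclei),
            all(c("cell_type", "condition", "n") %in% names(n_nuclei)),
            all(n_nuclei$n > 0), dispersion > 0,
            length(library_size_range) == 2,
            library_size_range[1] > 0,
            library_size_range[1] <= library_size_range[2])
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("gene symbols must be unique")
  if (is.null(baseline_mean)) {
    baseline_mean <- withr::with_seed(seed, {
      stats::rlnorm(length(genes), meanlog = -0.5, sdlog = 1)
    })
  }
  if (length(baseline_mean) != length(genes) || any(baseline_mean <= 0))
    stop("baseline_mean must be one positive value per gene")
  structure(list(n_nuclei = n_nuclei, genes = genes,
                 baseline_mean = stats::setNames(baseline_mean, genes),
                 dispersion = dispersion,
                 pathway_programs = pathway_programs,
                 lr_plantings = lr_plantings,
                 corr_blocks = corr_blocks,
                 library_size_range = library_size_range,
                 seed = seed),
            class = "population_design")
}

#' Generate a synthetic single-nucleus count population
#'
#' Counts are negative-binomial: gene g in nucleus c has mean
#' `mu[g, c] = m[g] * L[c] / sum(m)`, where `m` is the gene baseline times
#' all multiplicative effects applying to the nucleus (pathway programs,
#' ligand-receptor plantings, latent correlated-block factors) and `L[c]`
#' is drawn uniformly from the design's library-size range, so the expected
#' library size of every nucleus lies exactly in that range. A shared
#' dispersion (NB size) controls overdispersion.
#'
#' @param design a [population_design()].
#' @param catalog a [pathway_catalog()]; pathway programs and correlated
#'   blocks must reference its pathway ids.
#' @return list with `sce` (a SingleCellExperiment; colData columns
#'   `cell_type`, `condition`) and `truth` (per-nucleus labels, occupancy
#'   proportions per condition, the planted programs/plantings, and
#'   correlated-block membership).
#' @export
generate_cell_population <- function(design, catalog) {
  stopifnot(inherits(design, "population_design"),
            inherits(catalog, "pathway_catalog"))
  genes <- design$genes
  pp <- design$pathway_programs
  if (!is.null(pp) && nrow(pp) > 0) {
    bad <- setdiff(pp$pathway_id, catalog$pathway_id)
    if (length(bad))
      stop("pathway program references unknown pathway(s): ",
           paste(bad, collapse = ", "))
  }
  lr <- design$lr_plantings
  if (!is.null(lr) && nrow(lr) > 0) {
    bad <- setdiff(c(lr$ligand, lr$receptor), genes)
    if (length(bad))
      stop("L-R planting references unknown gene(s): ",
           paste(bad, collapse = ", "))
  }
  for (b in design$corr_blocks) {
    bad <- setdiff(b$pathway_ids, catalog$pathway_id)
    if (length(bad))
      stop("correlated block references unknown pathway(s): ",
           paste(bad, collapse = ", "))
  }
  pw_genes <- stats::setNames(catalog$genes, catalog$pathway_id)
  nn <- design$n_nuclei
  n_total <- sum(nn$n)
  G <- length(genes)

  withr::with_seed(design$seed, {
    counts <- matrix(0L, nrow = G, ncol = n_total,
                     dimnames = list(genes, NULL))
    cell_type <- character(n_total)
    condition <- character(n_total)
    col0 <- 0L
    for (i in seq_len(nrow(nn))) {
      ct <- nn$cell_type[i]; cond <- nn$condition[i]; n <- nn$n[i]
      m <- design$baseline_mean
      if (!is.null(pp) && nrow(pp) > 0) {
        hit <- (pp$cell_type == ct | pp$cell_type == "all") &
          (pp$condition == cond | pp$condition == "all")
        for (j in which(hit)) {
          gset <- intersect(pw_genes[[pp$pathway_id[j]]], genes)
          m[gset] <- m[gset] * 2^pp$log2_effect[j]
        }
      }
      if (!is.null(lr) && nrow(lr) > 0) {
        for (j in seq_len(nrow(lr))) {
          if (lr$condition[j] != cond && lr$condition[j] != "all") next
          if (lr$source_type[j] == ct)
            m[lr$ligand[j]] <- m[lr$ligand[j]] * 2^lr$log2_effect[j]
          if (lr$target_type[j] == ct)
            m[lr$receptor[j]] <- m[lr$receptor[j]] * 2^lr$log2_effect[j]
        }
      }
      # per-nucleus mean matrix for this group
      mu <- matrix(m, nrow = G, ncol = n)
      for (b in design$corr_blocks) {
        bg <- intersect(unique(unlist(pw_genes[b$pathway_ids])), genes)
        if (length(bg) == 0) next
        z <- stats::rnorm(n)
        fac <- exp(b$loading * z - b$loading^2 / 2)  # mean-one multiplier
        mu[match(bg, genes), ] <- mu[match(bg, genes), ] *
          rep(fac, each = length(bg))
      }
      L <- stats::runif(n, design$library_size_range[1],
                        design$library_size_range[2])
      mu <- sweep(mu, 2, L / colSums(mu), `*`)
      counts[, col0 + seq_len(n)] <-
        matrix(stats::rnbinom(G * n, size = design$dispersion, mu = mu),
               nrow = G)
      cell_type[col0 + seq_len(n)] <- ct
      condition[col0 + seq_len(n)] <- cond
      col0 <- col0 + n
    }
    colnames(counts) <- sprintf("nucleus_%05d", seq_len(n_total))
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                         "CsparseMatrix")),
      colData = S4Vectors::DataFrame(cell_type = cell_type,
                                     condition = condition,
                                     row.names = colnames(counts)))
    occ <- do.call(rbind, lapply(split(nn, nn$condition), function(d) {
      data.frame(condition = d$condition, cell_type = d$cell_type,
                 n = d$n, proportion = d$n / sum(d$n))
    }))
    rownames(occ) <- NULL
    truth <- list(cell_type = stats::setNames(cell_type, colnames(counts)),
                  condition = stats::setNames(condition, colnames(counts)),
                  occupancy = occ,
                  pathway_programs = pp,
                  lr_plantings = lr,
                  corr_blocks = design$corr_blocks)
    list(sce = sce, truth = truth)
  })
}

#' Generate a synthetic ligand-receptor pair table
#'
#' Samples `2 * n_pairs` distinct genes from the universe and pairs them as
#' ligand/receptor with a signalling-pathway label cycled from
#' `pathway_labels`.
#'
#' @param n_pairs number of pairs (0 allowed: header-only table).
#' @param pathway_labels character labels (e.g. `c("EGFR", "FGFR", "AstA")`).
#' @param gene_universe gene symbols to draw from (needs >= 2 * n_pairs).
#' @param seed integer seed.
#' @return data.frame with columns `ligand`, `receptor`, `pathway`.
#' @export
generate_lr_table <- function(n_pairs, pathway_labels, gene_universe,
                              seed = 0) {
  stopifnot(n_pairs >= 0, length(pathway_labels) >= 1 || n_pairs == 0)
  if (n_pairs == 0)
    return(data.frame(ligand = character(), receptor = character(),
                      pathway = character(), stringsAsFactors = FALSE))
  if (length(unique(gene_universe)) < 2 * n_pairs)
    stop("gene universe too small for ", n_pairs,
         " pairs with distinct ligand/receptor genes")
  withr::with_seed(seed, {
    picked <- sample(unique(gene_universe), 2 * n_pairs)
    out <- data.frame(
      ligand = picked[seq_len(n_pairs)],
      receptor = picked[n_pairs + seq_len(n_pairs)],
      pathway = rep_len(pathway_labels, n_pairs),
      stringsAsFactors = FALSE)
    validate_lr_pairs(out)
    out
  })
}

#' Design of a synthetic Raman spectrum
#'
#' @param peaks data.frame with columns `center` (cm^-1), `amplitude`
#'   (a.u., >= 0), `fwhm` (cm^-1, > 0) and optionally `shape` ("gaussian"
#'   default, or "lorentzian").
#' @param baseline_coeffs polynomial baseline coefficients, lowest order
#'   first (evaluated in the raw wavenumber).
#' @param noise_sd standard deviation of additive Gaussian noise (a.u.).
#' @param grid length-3 numeric `(start, stop, step)` in cm^-1.
#' @param seed integer seed for the noise.
#' @return object of class `spectrum_design`.
#' @export
spectrum_design <- function(peaks = NULL, baseline_coeffs = 0,
                            noise_sd = 0, grid = c(400, 3200, 1), seed = 0) {
  if (is.null(peaks))
    peaks <- data.frame(center = numeric(), amplitude = numeric(),
                        fwhm = numeric())
  stopifnot(is.data.frame(peaks),
            all(c("center", "amplitude", "fwhm") %in% names(peaks)),
            length(grid) == 3, grid[1] < grid[2], grid[3] > 0,
            noise_sd >= 0)
  if (nrow(peaks) > 0) {
    if (any(peaks$fwhm <= 0)) stop("peak fwhm must be positive")
    if (any(peaks$amplitude < 0)) stop("peak amplitudes must be non-negative")
    if (is.null(peaks$shape)) peaks$shape <- "gaussian"
    if (!all(peaks$shape %in% c("gaussian", "lorentzian")))
      stop("peak shape must be 'gaussian' or 'lorentzian'")
  }
  structure(list(peaks = peaks, baseline_coeffs = baseline_coeffs,
                 noise_sd = noise_sd, grid = grid, seed = seed),
            class = "spectrum_design")
}

#' Generate a synthetic Raman spectrum with analytic ground truth
#'
#' I(nu) = sum of peaks + polynomial baseline + Gaussian noise. Truth records
#' each peak's analytic height, FWHM and area (Gaussian:
#' `amplitude * sigma * sqrt(2*pi)` with `sigma = fwhm / (2*sqrt(2*log(2)))`;
#' Lorentzian: `amplitude * pi * fwhm / 2`).
#'
#' @param design a [spectrum_design()].
#' @return list with `spectrum` (a [raman_spectrum()]) and `truth`
#'   (the peak table with an `area` column).
#' @export
generate_spectrum <- function(design) {
  stopifnot(inherits(design, "spectrum_design"))
  nu <- seq(design$grid[1], design$grid[2], by = design$grid[3])
  y <- numeric(length(nu))
  pk <- design$peaks
  if (nrow(pk) > 0) {
    for (i in seq_len(nrow(pk))) {
      if (pk$shape[i] == "gaussian") {
        sig <- pk$fwhm[i] / (2 * sqrt(2 * log(2)))
        y <- y + pk$amplitude[i] * exp(-(nu - pk$center[i])^2 / (2 * sig^2))
      } else {
        gam <- pk$fwhm[i] / 2
        y <- y + pk$amplitude[i] * gam^2 / ((nu - pk$center[i])^2 + gam^2)
      }
    }
  }
  for (d in seq_along(design$baseline_coeffs))
    y <- y + design$baseline_coeffs[d] * nu^(d - 1)
  if (design$noise_sd > 0) {
    y <- y + withr::with_seed(design$seed,
                              stats::rnorm(length(nu), 0, design$noise_sd))
  }
  truth <- pk
  if (nrow(pk) > 0) {
    truth$area <- ifelse(
      pk$shape == "gaussian",
      pk$amplitude * (pk$fwhm / (2 * sqrt(2 * log(2)))) * sqrt(2 * pi),
      pk$amplitude * pi * pk$fwhm / 2)
  } else truth$area <- numeric(0)
  list(spectrum = raman_spectrum(nu, y), truth = truth)
}
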