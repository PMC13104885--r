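#' Scale genes and embed nuclei by principal components
#'
#' Per-gene z-scaling over nuclei (zero-variance genes become all-zero
#' rows), values clipped at +/- `clip`, then a principal-component
#' projection of the nuclei.
#'
#' @param sce SingleCellExperiment with a `logcounts` assay.
#' @param n_components number of components to retain
#'   (<= min(nuclei, genes)).
#' @param clip symmetric clipping bound on z-scores (default 10).
#' @return object of class `embedding`: list with `coords` (nuclei x
#'   components), `sdev` (all component standard deviations, decreasing)
#'   and `n_components`.
#' @export
scale_and_embed <- function(sce, n_components = 30, clip = 10) {
  x <- SummarizedExperiment::assay(sce, "logcounts")
  if (n_components > min(dim(x)))
    stop("n_components exceeds min(nuclei, genes)")
  x <- as.matrix(x)                      # genes x nuclei
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  coords <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(coords) <- colnames(sce)
  structure(list(coords = coords, sdev = pc$sdev,
                 n_components = n_components),
            class = "embedding")
}

#' Elbow point of a decreasing scree curve
#'
#' Kneedle criterion: the component maximizing the perpendicular drop from
#' the chord joining the first and last points of the scree curve
#' (index, sd). If no point falls below the chord (e.g. strictly linear
#' decay) the convention is to return 1.
#'
#' @param component_sds decreasing component standard deviations (>= 3).
#' @return integer index of the elbow component.
#' @export
elbow_point <- function(component_sds) {
  n <- length(component_sds)
  if (n < 3) stop("need at least 3 components")
  i <- seq_len(n)
  chord <- component_sds[1] +
    (component_sds[n] - component_sds[1]) * (i - 1) / (n - 1)
  drop <- chord - component_sds       # signed: positive below the chord
  tol <- 1e-9 * max(abs(component_sds))
  if (max(drop) <= tol) return(1L)    # linear decay: no knee
  which.max(drop)
}

#' Cluster nuclei on an embedding via an SNN graph and Leiden communities
#'
#' Builds a shared-nearest-neighbor graph (k nearest neighbours by Euclidean
#' distance in the embedding, edges weighted by the Jaccard overlap of
#' neighbourhoods, weights below `prune` dropped), then runs the Leiden
#' algorithm with the modularity objective at the given resolution.
#' Cluster ids are contiguous integers from 0, ordered by decreasing size.
#'
#' @param embedding an [scale_and_embed()] result (or any object with a
#'   `coords` matrix).
#' @param resolution positive resolution parameter (e.g. 0.2 for gut,
#'   0.1 for brain).
#' @param k_neighbors neighbourhood size (default 20); must be < n nuclei.
#' @param prune SNN Jaccard pruning threshold (default 1/15).
#' @param seed integer seed (required; clustering is deterministic given it).
#' @return object of class `cluster_assignment`: integer vector of cluster
#'   ids named by nucleus, with attributes `resolution`, `k_neighbors`,
#'   `seed`, `n_clusters`.
#' @export
cluster_nuclei <- function(embedding, resolution, k_neighbors = 20,
                           prune = 1 / 15, seed) {
  coords <- embedding$coords
  n <- nrow(coords)
  if (k_neighbors >= n)
    stop("k_neighbors must be smaller than the number of nuclei")
  if (missing(seed)) stop("seed is required")
  d <- as.matrix(stats::dist(coords))
  # k nearest neighbours including self (self is always nearest)
  nbr <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                               j = as.vector(t(nbr)), x = 1,
                               dims = c(n, n))
  shared <- Matrix::tcrossprod(memb)            # |N_i intersect N_j|
  jac <- methods::as(shared, "TsparseMatrix")
  jac@x <- jac@x / (2 * k_neighbors - jac@x)    # Jaccard of equal-size sets
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  cl <- withr::with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution,
                           weights = igraph::E(g)$weight,
                           n_iterations = 10)
  })
  raw <- igraph::membership(cl)
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  ids <- unname(relabel[as.character(raw)])
  names(ids) <- rownames(coords)
  structure(ids, class = "cluster_assignment", resolution = resolution,
            k_neighbors = k_neighbors, seed = seed,
            n_clusters = length(sizes))
}

#' Cluster occupancy and fold change between two conditions
#'
#' Per cluster and condition: nucleus count and the proportion of that
#' condition's nuclei; per cluster the occupancy fold change
#' `proportion(treated) / proportion(control)`. Clusters absent from one
#' condition are kept with `fold = NA` and `fold_defined = FALSE`.
#'
#' @param assignment per-nucleus cluster ids (a [cluster_nuclei()] result or
#'   any vector).
#' @param conditions per-nucleus condition labels, same length/order.
#' @param control,treated condition names to compare.
#' @return data.frame with columns `cluster`, `n_control`, `n_treated`,
#'   `prop_control`, `prop_treated`, `fold`, `fold_defined`.
#' @export
occupancy <- function(assignment, conditions, control, treated) {
  assignment <- as.vector(assignment)
  stopifnot(length(assignment) == length(conditions))
  if (!control %in% conditions) stop("unknown condition: ", control)
  if (!treated %in% conditions) stop("unknown condition: ", treated)
  clusters <- sort(unique(assignment))
  nc <- sum(conditions == control)
  nt <- sum(conditions == treated)
  out <- do.call(rbind, lapply(clusters, function(k) {
    a <- sum(assignment == k & conditions == control)
    b <- sum(assignment == k & conditions == treated)
    data.frame(cluster = k, n_control = a, n_treated = b,
               prop_control = a / nc, prop_treated = b / nt)
  }))
  out$fold_defined <- out$prop_control > 0 & out$prop_treated > 0
  out$fold <- ifelse(out$fold_defined, out$prop_treated / out$prop_control, NA)
  out[c("cluster", "n_control", "n_treated", "prop_control", "prop_treated",
        "fold", "fold_defined")]
}

#' Transfer reference cell-type labels onto metabolic clusters
#'
#' Per metabolic cluster, the percentage breakdown of reference labels
#' (e.g. whole-transcriptome cell-type annotations) and the dominant label.
#'
#' @param assignment per-nucleus cluster ids.
#' @param reference_labels per-nucleus cell-type labels, same length/order;
#'   no missing values.
#' @return data.frame with columns `cluster`, `label`, `n`, `percentage`,
#'   `dominant` (TRUE for the cluster's most frequent label).
#' @export
transfer_composition <- function(assignment, reference_labels) {
  assignment <- as.vector(assignment)
  stopifnot(length(assignment) == length(reference_labels))
  missing <- which(is.na(reference_labels) | !nzchar(reference_labels))
  if (length(missing))
    stop("missing reference labels for nuclei: ",
         paste(utils::head(missing, 10), collapse = ", "))
  out <- do.call(rbind, lapply(sort(unique(assignment)), function(k) {
    tab <- sort(table(reference_labels[assignment == k]), decreasing = TRUE)
    data.frame(cluster = k, label = names(tab), n = as.vector(tab),
               percentage = 100 * as.vector(tab) / sum(tab),
               dominant = seq_along(tab) == 1L)
  }))
  rownames(out) <- NULL
  out
}
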