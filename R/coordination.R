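#' Pathway-pathway Pearson correlation map
#'
#' Pairwise Pearson correlation of pathway activity scores over the nuclei
#' of one condition, with two-sided P-values from the t-transform of r on
#' n - 2 degrees of freedom. Zero-variance pathways yield missing (NA)
#' correlations, reported rather than raised.
#'
#' @param scores nuclei x pathways score matrix.
#' @param subset optional nucleus index/name/logical subset (>= 3 nuclei).
#' @param condition optional condition label to record.
#' @return object of class `correlation_map`: list with `r`, `p`
#'   (pathways x pathways), `n` (nuclei used), `condition`.
#' @export
pathway_correlation <- function(scores, subset = NULL, condition = NA) {
  scores <- as.matrix(scores)
  if (!is.null(subset)) scores <- scores[subset, , drop = FALSE]
  n <- nrow(scores)
  if (n < 3) stop("need at least 3 nuclei")
  if (ncol(scores) < 2) stop("need at least 2 pathways")
  sds <- apply(scores, 2, stats::sd)
  r <- suppressWarnings(stats::cor(scores))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  rr <- pmin(pmax(r, -1), 1)
  tt <- rr * sqrt((n - 2) / pmax(1 - rr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(r)[!is.na(diag(r))] <- 1
  diag(p) <- 0
  structure(list(r = r, p = p, n = n, condition = condition),
            class = "correlation_map")
}

# Average-linkage tree on distance 1 - r; missing r imputed as 0.
corr_hclust <- function(corr, warn = TRUE) {
  r <- corr$r
  if (anyNA(r)) {
    if (warn) warning("missing correlations imputed as 0 for ordering")
    r[is.na(r)] <- 0
    diag(r) <- 1
  }
  stats::hclust(stats::as.dist(1 - r), method = "average")
}

#' Hierarchical ordering of pathways by correlation
#'
#' Average-linkage agglomeration on the distance `1 - r`; the ordering is
#' the dendrogram leaf order. Missing correlations are imputed as 0 for
#' ordering only, with a warning.
#'
#' @param corr a [pathway_correlation()] map with >= 2 pathways.
#' @return integer permutation of the pathways (dendrogram leaf order),
#'   with the `hclust` tree attached as attribute `"tree"`.
#' @export
order_by_hclust <- function(corr) {
  stopifnot(inherits(corr, "correlation_map"))
  if (ncol(corr$r) < 2) stop("need at least 2 pathways")
  h <- corr_hclust(corr)
  structure(h$order, tree = h)
}

#' Significance mask for a correlation map
#'
#' TRUE where the off-diagonal P-value is below `alpha` (the dots of the
#' correlation heatmap); the diagonal and missing entries are never marked.
#'
#' @param corr a [pathway_correlation()] map.
#' @param alpha significance level (default 0.05, raw P, no multiplicity
#'   adjustment; set `adjust = "BH"` to mask on BH-adjusted P instead).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return logical pathways x pathways matrix.
#' @export
significance_mask <- function(corr, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(corr, "correlation_map"))
  adjust <- match.arg(adjust)
  p <- corr$p
  if (adjust == "BH") {
    off <- upper.tri(p)
    adj <- stats::p.adjust(p[off], method = "BH")
    p[off] <- adj
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  mask <- !is.na(p) & p < alpha
  diag(mask) <- FALSE
  mask
}

#' Detect correlation modules of coordinated pathways
#'
#' Cuts the average-linkage dendrogram at distance `1 - r_threshold` and
#' keeps the resulting groups with at least `min_size` members, mean
#' pairwise correlation >= `r_threshold`, and at least `sig_fraction` of
#' member pairs significant at `alpha`. Modules are returned in dendrogram
#' leaf order; pairs with missing correlations are excluded from the module
#' statistics.
#'
#' @param corr a [pathway_correlation()] map.
#' @param ordering an [order_by_hclust()] result for `corr` (recomputed if
#'   omitted).
#' @param min_size minimum module size (default 3).
#' @param r_threshold module correlation threshold (default 0.3).
#' @param sig_fraction minimum fraction of significant member pairs
#'   (default 0.8).
#' @param alpha significance level for member pairs (default 0.05).
#' @return list of modules, each a list with `pathways`, `mean_r`,
#'   `sig_fraction`; empty list when nothing qualifies.
#' @export
detect_modules <- function(corr, ordering = NULL, min_size = 3,
                           r_threshold = 0.3, sig_fraction = 0.8,
                           alpha = 0.05) {
  stopifnot(inherits(corr, "correlation_map"))
  if (is.null(ordering)) ordering <- order_by_hclust(corr)
  tree <- attr(ordering, "tree")
  if (is.null(tree)) tree <- corr_hclust(corr, warn = FALSE)
  groups <- stats::cutree(tree, h = 1 - r_threshold)
  leaf_pos <- match(seq_along(groups), as.vector(ordering))
  out <- list()
  for (gid in unique(groups[as.vector(ordering)])) {
    members <- which(groups == gid)
    if (length(members) < min_size) next
    r_sub <- corr$r[members, members]
    p_sub <- corr$p[members, members]
    off <- upper.tri(r_sub)
    rs <- r_sub[off]
    ps <- p_sub[off]
    ok <- !is.na(rs)
    if (!any(ok)) next
    mean_r <- mean(rs[ok])
    sf <- mean(ps[ok] < alpha)
    if (mean_r < r_threshold || sf < sig_fraction) next
    nm <- colnames(corr$r)[members]
    if (is.null(nm)) nm <- as.character(members)
    out[[length(out) + 1]] <- list(
      pathways = nm[order(leaf_pos[members])],
      members = members[order(leaf_pos[members])],
      mean_r = mean_r, sig_fraction = sf)
  }
  out
}

#' Compare correlation modules between two conditions
#'
#' Pairwise Jaccard overlap between module member sets across conditions;
#' a module is labeled `shared` when its best counterpart reaches Jaccard
#' >= `jaccard_threshold`, otherwise condition-specific. Detecting the same
#' core module in both conditions marks it as a conserved metabolic
#' framework; condition-only modules are treatment-induced.
#'
#' @param modules_A,modules_B [detect_modules()] results computed on the
#'   same pathway universe.
#' @param universe_A,universe_B optional character vectors of the pathway
#'   universes used (checked for equality when both given).
#' @param jaccard_threshold sharing threshold (default 0.5).
#' @return data.frame with columns `condition`, `module`, `size`,
#'   `best_jaccard`, `best_match`, `status` ("shared" or
#'   "condition_specific").
#' @export
compare_conditions <- function(modules_A, modules_B,
                               universe_A = NULL, universe_B = NULL,
                               jaccard_threshold = 0.5) {
  if (!is.null(universe_A) && !is.null(universe_B) &&
      !setequal(universe_A, universe_B))
    stop("module lists were computed on different pathway universes")
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  row_for <- function(mods, other, cond) {
    if (length(mods) == 0) return(NULL)
    do.call(rbind, lapply(seq_along(mods), function(i) {
      js <- if (length(other)) vapply(other, function(o) {
        jac(mods[[i]]$pathways, o$pathways)
      }, 1) else numeric(0)
      best <- if (length(js)) which.max(js) else NA_integer_
      bj <- if (length(js)) max(js) else 0
      data.frame(condition = cond, module = i,
                 size = length(mods[[i]]$pathways),
                 best_jaccard = bj, best_match = best,
                 status = if (bj >= jaccard_threshold) "shared"
                          else "condition_specific",
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(row_for(modules_A, modules_B, "A"),
               row_for(modules_B, modules_A, "B"))
  if (is.null(out))
    out <- data.frame(condition = character(), module = integer(),
                      size = integer(), best_jaccard = numeric(),
                      best_match = integer(), status = character())
  rownames(out) <- NULL
  out
}
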