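#' Pathway catalog
#'
#' A catalog of named pathways grouped into categories, each carrying an
#' ordered set of gene symbols. This is the in-memory form of a GMT gene-set
#' collection (e.g. the Drosophila KEGG metabolic pathways) and drives
#' metabolic-matrix extraction and pathway activity scoring.
#'
#' @param pathway_id character vector of unique short pathway identifiers.
#' @param pathway_name character vector of human-readable pathway names.
#' @param category character vector assigning each pathway to a category.
#' @param genes list of character vectors, one non-empty gene-symbol set per
#'   pathway (duplicates within a set are dropped, order preserved).
#'
#' @return An object of class `pathway_catalog`: a data.frame with columns
#'   `pathway_id`, `pathway_name`, `category` and a list-column `genes`.
#' @export
pathway_catalog <- function(pathway_id, pathway_name = pathway_id,
                            category, genes) {
  stopifnot(is.character(pathway_id), is.character(category), is.list(genes))
  n <- length(pathway_id)
  if (length(pathway_name) != n || length(category) != n || length(genes) != n)
    stop("pathway_id, pathway_name, category and genes must have equal length")
  if (anyDuplicated(pathway_id))
    stop("pathway_ids must be unique")
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (any(vapply(genes, length, 1L) == 0L))
    stop("every pathway gene set must be non-empty")
  cat <- data.frame(pathway_id = pathway_id,
                    pathway_name = pathway_name,
                    category = category,
                    stringsAsFactors = FALSE)
  cat$genes <- genes
  class(cat) <- c("pathway_catalog", "data.frame")
  cat
}

#' @export
print.pathway_catalog <- function(x, ...) {
  cat(sprintf("pathway_catalog: %d pathways in %d categories, %d genes in union\n",
              nrow(x), length(unique(x$category)),
              length(catalog_gene_union(x))))
  sizes <- vapply(x$genes, length, 1L)
  cat(sprintf("  gene-set sizes: %d-%d (median %.0f)\n",
              min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' Union of all genes in a catalog
#'
#' @param catalog a [pathway_catalog()].
#' @return character vector of unique gene symbols, in first-appearance order.
#' @export
catalog_gene_union <- function(catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  unique(unlist(catalog$genes, use.names = FALSE))
}

#' Mean pairwise Jaccard overlap between pathway gene sets
#'
#' @param catalog a [pathway_catalog()].
#' @return mean Jaccard index over all unordered pathway pairs (NA for a
#'   single-pathway catalog).
#' @export
catalog_mean_jaccard <- function(catalog) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  n <- nrow(catalog)
  if (n < 2) return(NA_real_)
  js <- numeric(0)
  for (i in seq_len(n - 1)) {
    gi <- catalog$genes[[i]]
    for (j in seq(i + 1, n)) {
      gj <- catalog$genes[[j]]
      js <- c(js, length(intersect(gi, gj)) / length(union(gi, gj)))
    }
  }
  mean(js)
}
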