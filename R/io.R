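#' Read a GMT gene-set file into a pathway catalog
#'
#' GMT layout: one pathway per line, tab-separated — identifier, description
#' (used here as the category), then the gene symbols.
#'
#' @param path path to a GMT file.
#' @return a [pathway_catalog()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad))
    stop("GMT line(s) with fewer than 3 fields: ", paste(which(bad), collapse = ", "))
  pathway_catalog(
    pathway_id = vapply(fields, `[[`, "", 1L),
    category   = vapply(fields, `[[`, "", 2L),
    genes      = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write a pathway catalog as GMT
#'
#' @param catalog a [pathway_catalog()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "pathway_catalog"))
  lines <- vapply(seq_len(nrow(catalog)), function(i) {
    paste(c(catalog$pathway_id[i], catalog$category[i], catalog$genes[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 10x-style Matrix-Market directory into a SingleCellExperiment
#'
#' Expects `matrix.mtx` (genes x nuclei triplet counts), `features.tsv`
#' (gene symbols, one per row), `barcodes.tsv` (nucleus ids), and optionally
#' `metadata.tsv` (tab-separated, one row per nucleus, first column the
#' barcode) whose remaining columns become colData.
#'
#' @param dir directory containing the files.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay.
#' @export
read_10x_counts <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stop("no matrix.mtx under ", dir)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  feats <- utils::read.delim(file.path(dir, "features.tsv"),
                             header = FALSE, stringsAsFactors = FALSE)
  bcs <- utils::read.delim(file.path(dir, "barcodes.tsv"),
                           header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m) || nrow(bcs) != ncol(m))
    stop("features/barcodes dimensions do not match matrix.mtx")
  rownames(m) <- feats[[1]]
  colnames(m) <- bcs[[1]]
  sce <- SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
  meta_path <- file.path(dir, "metadata.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, header = TRUE,
                              stringsAsFactors = FALSE)
    rownames(meta) <- meta[[1]]
    meta <- meta[colnames(m), -1, drop = FALSE]
    SummarizedExperiment::colData(sce) <- S4Vectors::DataFrame(meta)
  }
  sce
}

#' Write a SingleCellExperiment as a 10x-style Matrix-Market directory
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and, when colData is
#' present, `metadata.tsv` with the barcode as its first column.
#'
#' @param sce a SingleCellExperiment with a `counts` assay.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_10x_counts <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(m, "TsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  cd <- SummarizedExperiment::colData(sce)
  if (ncol(cd) > 0) {
    meta <- data.frame(barcode = colnames(m), as.data.frame(cd),
                       check.names = FALSE)
    utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a Raman spectrum from a two-column TSV
#'
#' Columns: wavenumber (cm^-1) and intensity (a.u.); no header required;
#' lines starting with `#` are comments.
#'
#' @param path input file.
#' @return a [raman_spectrum()].
#' @export
read_spectrum_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  # tolerate an optional non-numeric header line
  first <- strsplit(lines[1], "[\t ]+")[[1]]
  if (suppressWarnings(any(is.na(as.numeric(first[1:2]))))) lines <- lines[-1]
  d <- utils::read.table(text = lines, header = FALSE)
  raman_spectrum(d[[1]], d[[2]])
}

#' Write a Raman spectrum as a two-column TSV
#'
#' @param spectrum a [raman_spectrum()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  utils::write.table(
    data.frame(spectrum$wavenumbers, spectrum$intensities),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor pair table from CSV
#'
#' Expects the header `ligand,receptor,pathway`.
#'
#' @param path input CSV.
#' @return data.frame with columns `ligand`, `receptor`, `pathway`.
#' @export
read_lr_pairs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "pathway")
  if (!all(need %in% names(d)))
    stop("L-R pair CSV must have columns: ", paste(need, collapse = ", "))
  validate_lr_pairs(d[need])
  d[need]
}

#' Write a ligand-receptor pair table as CSV
#'
#' @param pairs data.frame with columns `ligand`, `receptor`, `pathway`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_lr_pairs <- function(pairs, path) {
  validate_lr_pairs(pairs)
  utils::write.csv(pairs[c("ligand", "receptor", "pathway")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_lr_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("ligand", "receptor", "pathway") %in% names(pairs)))
  if (nrow(pairs) > 0) {
    if (any(pairs$ligand == pairs$receptor))
      stop("ligand must differ from receptor within a pair")
    if (any(!nzchar(pairs$pathway)))
      stop("pathway labels must be non-empty")
  }
  invisible(pairs)
}
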