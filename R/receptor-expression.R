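# Receptor expression fractions from a sparse genes x cells count matrix
# (MatrixMarket MTX + gene / barcode sidecar lists).

#' Read a genes x cells count matrix
#'
#' Loads the standard MatrixMarket trio: the sparse counts, a gene list
#' (one symbol per line, or tab-separated with the symbol in the last
#' column as in CellRanger output), and a barcode list. Duplicate gene
#' symbols are resolved to the first occurrence with a warning.
#'
#' @param mtx_path path to the MatrixMarket file (genes in rows).
#' @param genes_path,barcodes_path sidecar lists.
#' @return A \code{Matrix::dgCMatrix} with gene rownames and barcode
#'   colnames.
#' @export
read_count_matrix <- function(mtx_path, genes_path, barcodes_path) {
  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  genes <- genes[[ncol(genes)]]
  barcodes <- readLines(barcodes_path)
  if (length(genes) != nrow(m) || length(barcodes) != ncol(m))
    stop_data(sprintf(
      "dimension mismatch: matrix %d x %d, %d genes, %d barcodes",
      nrow(m), ncol(m), length(genes), length(barcodes)))
  if (anyDuplicated(genes))
    warning("duplicate gene symbols; lookups resolve to the first occurrence")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a count matrix as the MatrixMarket trio
#'
#' @param m sparse matrix with gene rownames and barcode colnames.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_count_matrix <- function(m, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.tsv",
                                           "_barcodes.tsv")))
  Matrix::writeMM(m, paths[1])
  writeLines(rownames(m), paths[2])
  writeLines(colnames(m), paths[3])
  invisible(paths)
}

gene_row <- function(m, gene) {
  idx <- which(rownames(m) == gene)
  if (length(idx) == 0) stop_data("gene not found: ", gene)
  m[idx[1], ]
}

#' Fraction of cells expressing a gene
#'
#' A cell counts as expressing when its raw count exceeds \code{threshold}
#' (default: any nonzero count). Presence/absence at count > 0 is
#' invariant to any per-cell scaling or normalization of the counts.
#'
#' @param m count matrix from \code{\link{read_count_matrix}} or
#'   \code{\link{simulate_counts}}.
#' @param gene gene symbol.
#' @param threshold count threshold (strictly exceeded).
#' @return List: \code{gene}, \code{denominator} (description),
#'   \code{n_cells}, \code{n_positive}, \code{fraction}.
#' @export
expression_fraction <- function(m, gene, threshold = 0) {
  pos <- gene_row(m, gene) > threshold
  list(gene = gene, denominator = "all cells", n_cells = ncol(m),
       n_positive = sum(pos), fraction = mean(pos))
}

#' Co-expression fraction, optionally within a gene-defined subpopulation
#'
#' Fraction of the denominator population positive for \code{geneA}, or
#' for both \code{geneA} and \code{geneB}. With \code{within}, the
#' denominator is the cells positive for that gene (e.g. the fraction of
#' Crh+ cells expressing Esr1).
#'
#' @param m count matrix.
#' @param geneA,geneB gene symbols (\code{geneB} optional: both-positive
#'   fraction when given).
#' @param within optional gene restricting the denominator population.
#' @param threshold count threshold (strictly exceeded).
#' @return List as in \code{\link{expression_fraction}} with a
#'   \code{genes} field.
#' @export
coexpression_fraction <- function(m, geneA, geneB = NULL, within = NULL,
                                  threshold = 0) {
  posA <- gene_row(m, geneA) > threshold
  pos <- if (is.null(geneB)) posA
         else posA & (gene_row(m, geneB) > threshold)
  denom_desc <- "all cells"
  keep <- rep(TRUE, ncol(m))
  if (!is.null(within)) {
    keep <- gene_row(m, within) > threshold
    denom_desc <- paste0(within, "+ cells")
    if (!any(keep)) stop_data("empty denominator: no ", within, "+ cells")
  }
  list(genes = c(geneA, geneB), denominator = denom_desc,
       n_cells = sum(keep), n_positive = sum(pos & keep),
       fraction = sum(pos & keep) / sum(keep))
}
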