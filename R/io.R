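# Reading and writing count matrices and cell annotation tables.
#
# The in-memory convention throughout the package is cells x genes (sparse
# dgCMatrix for counts). On disk, MatrixMarket triplets default to the 10x
# genes x cells orientation; `orientation` overrides this.

#' Read a count matrix and cell annotations
#'
#' Accepts either a MatrixMarket triplet (`matrix.mtx` plus `genes.tsv` and
#' `barcodes.tsv` in the same directory) or a dense CSV with genes as columns
#' and a leading `cell_id` column. Cells present in only one of matrix and
#' annotation are dropped with a message reporting the count.
#'
#' @param matrix_path Path to `.mtx` or `.csv` matrix file.
#' @param annotation_path Path to a CSV with at least a `cell_id` column.
#' @param orientation For MTX input, orientation of the file on disk:
#'   `"genes_x_cells"` (10x convention, default) or `"cells_x_genes"`.
#' @return List with `counts` (sparse cells x genes dgCMatrix) and `cells`
#'   (data.frame of annotations aligned to the matrix rows).
#' @export
read_dataset <- function(matrix_path, annotation_path,
                         orientation = c("genes_x_cells", "cells_x_genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(matrix_path)) stopf("matrix file not found: %s", matrix_path)
  if (!file.exists(annotation_path)) stopf("annotation file not found: %s", annotation_path)

  if (grepl("\\.mtx$", matrix_path)) {
    m <- Matrix::readMM(matrix_path)
    dir <- dirname(matrix_path)
    genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                               header = FALSE, stringsAsFactors = FALSE)[[1L]]
    cells <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                               header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (orientation == "genes_x_cells") m <- Matrix::t(m)
    counts <- as_sparse(m)
    rownames(counts) <- cells
    colnames(counts) <- genes
  } else {
    df <- utils::read.csv(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
    counts <- as_sparse(as.matrix(df[, -1L, drop = FALSE]))
    rownames(counts) <- df[[1L]]
  }
  if (anyDuplicated(rownames(counts))) stopf("duplicate cell ids in matrix")
  if (anyDuplicated(colnames(counts))) stopf("duplicate gene ids in matrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stopf("raw counts must be non-negative integers")

  ann <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(ann)) stopf("annotation must have a cell_id column")
  if (anyDuplicated(ann$cell_id)) stopf("duplicate cell ids in annotation")

  shared <- intersect(rownames(counts), ann$cell_id)
  if (length(shared) == 0L) stopf("matrix and annotation share no cell ids")
  dropped <- (nrow(counts) - length(shared)) + (nrow(ann) - length(shared))
  if (dropped > 0L)
    warnf("%d cells present in only one of matrix/annotation were dropped", dropped)
  counts <- counts[shared, , drop = FALSE]
  ann <- ann[match(shared, ann$cell_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(counts = counts, cells = ann)
}

#' Write a count matrix and cell annotations
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` (genes x cells on disk,
#' 10x convention) and `cells.csv` into `dir`.
#'
#' @param counts Sparse or dense cells x genes count matrix with dimnames.
#' @param cells Annotation data.frame with a `cell_id` column.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(counts, cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as_sparse(Matrix::t(as_sparse(counts)))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' Log-normalize counts
#'
#' Library-size normalization followed by a natural-log transform:
#' `ln(1 + count / cell_total * scale)`, the standard normalization used for
#' per-cell scoring and differential expression. Cells with zero total get all
#' zeros with a warning.
#'
#' @param counts Cells x genes count matrix (sparse or dense).
#' @param scale Scale factor (default `1e4`).
#' @return Sparse cells x genes matrix of log-normalized values.
#' @examples
#' m <- matrix(c(1, 1, 2, 2), 2, dimnames = list(c("c1", "c2"), c("g1", "g2")))
#' lognormalize(m)  # both cells identical: ln(1 + 0.5e4)
#' @export
lognormalize <- function(counts, scale = 1e4) {
  counts <- as_sparse(counts)
  totals <- Matrix::rowSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warnf("%d cells have zero total counts; their normalized values are 0", sum(zero))
    totals[zero] <- 1  # avoids 0/0; numerators are all zero anyway
  }
  out <- counts
  # dgCMatrix is column-compressed; @i holds 0-based row (cell) indices, so
  # each stored value is divided by its own cell's total.
  out@x <- log1p(counts@x / totals[counts@i + 1L] * scale)
  out
}
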