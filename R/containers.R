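#' Construct a cell expression matrix container
#'
#' Bundles an integer gene x cell count matrix with per-cell metadata and
#' per-cell QC statistics. QC statistics (`n_features`, `total_counts`,
#' `pct_mito`) are always recomputed from the counts so they cannot drift
#' out of sync with the matrix. Mitochondrial genes are recognized by the
#' standard mouse `mt-` gene-id prefix (case-insensitive).
#'
#' @param counts gene x cell matrix of non-negative integers (dense or
#'   `Matrix` sparse). Rownames are gene ids; if absent, `gene_ids` must be
#'   given.
#' @param cells data.frame of per-cell metadata, one row per column of
#'   `counts`. Must contain `cell_id`; typical columns are `sample_id`,
#'   `sex` ("M"/"F"), `genotype` ("TG"/"WT"), `age_months`, `cell_type`.
#' @param gene_ids optional character vector of gene identifiers.
#' @return An object of class `CellExpressionMatrix`: a list with elements
#'   `counts` (sparse `dgCMatrix`), `gene_ids`, and `cells` (metadata with
#'   QC columns `n_features`, `total_counts`, `pct_mito`).
#' @export
cell_expression_matrix <- function(counts, cells, gene_ids = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) stop("gene ids required (rownames or `gene_ids`)")
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length != nrow(counts)")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  rownames(counts) <- gene_ids
  if (!is.data.frame(cells)) cells <- as.data.frame(cells)
  if (nrow(cells) != ncol(counts))
    stop("metadata rows (", nrow(cells), ") != matrix columns (", ncol(counts), ")")
  if (is.null(cells$cell_id)) cells$cell_id <- paste0("cell", seq_len(nrow(cells)))
  colnames(counts) <- cells$cell_id
  if (min(counts@x, 0) < 0) stop("counts must be non-negative")
  obj <- structure(list(counts = counts, gene_ids = gene_ids, cells = cells),
                   class = "CellExpressionMatrix")
  recompute_qc(obj)
}

#' Recompute per-cell QC statistics from the count matrix
#'
#' @param x a `CellExpressionMatrix`
#' @return `x` with `n_features`, `total_counts` and `pct_mito` refreshed.
#' @export
recompute_qc <- function(x) {
  stopifnot(inherits(x, "CellExpressionMatrix"))
  m <- x$counts
  x$cells$n_features <- Matrix::colSums(m > 0)
  x$cells$total_counts <- Matrix::colSums(m)
  mito <- is_mito_gene(x$gene_ids)
  mito_counts <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) else 0
  x$cells$pct_mito <- ifelse(x$cells$total_counts > 0,
                             100 * mito_counts / x$cells$total_counts, 0)
  x
}

is_mito_gene <- function(gene_ids) grepl("^mt-", gene_ids, ignore.case = TRUE)

#' @export
print.CellExpressionMatrix <- function(x, ...) {
  cat("CellExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  meta <- setdiff(colnames(x$cells), "cell_id")
  cat("  metadata:", paste(meta, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a cell expression matrix by cells and/or genes
#'
#' @param x a `CellExpressionMatrix`
#' @param cells logical/integer/character index over cells
#' @param genes logical/integer/character index over genes
#' @return the subsetted `CellExpressionMatrix` with QC recomputed.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "CellExpressionMatrix"))
  m <- x$counts
  meta <- x$cells
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, meta$cell_id)
    m <- m[, cells, drop = FALSE]
    meta <- meta[cells, , drop = FALSE]
    rownames(meta) <- NULL
  }
  cell_expression_matrix(m, meta, gene_ids = rownames(m))
}

#' Write a cell expression matrix as MatrixMarket plus TSV sidecars
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate format), `genes.tsv`
#' (one gene id per line) and `cells.tsv` (tab-separated metadata) into
#' `dir`, the conventional exchange layout for sparse count matrices.
#'
#' @param x a `CellExpressionMatrix`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(x, dir) {
  stopifnot(inherits(x, "CellExpressionMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(x$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cell expression matrix written by [write_cell_matrix()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`
#' @return a `CellExpressionMatrix`
#' @export
read_cell_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  cell_expression_matrix(m, cells, gene_ids = genes)
}
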