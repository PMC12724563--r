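#' Construct an expression matrix container
#'
#' Bundles a sparse non-negative integer count matrix (genes x cells) with
#' stable gene and cell identifiers and, once [normalize_counts()] has been
#' applied, a natural-log normalized layer of the same shape. Orderings are
#' explicit and never silently re-sorted.
#'
#' @param counts A genes x cells matrix of non-negative integer counts
#'   (base matrix or any [Matrix::Matrix] sparse class; stored as `dgCMatrix`).
#' @param gene_ids Character vector of unique gene identifiers
#'   (defaults to `rownames(counts)`).
#' @param cell_ids Character vector of unique cell identifiers
#'   (defaults to `colnames(counts)`).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `counts` (sparse `dgCMatrix`), `norm` (`NULL` until normalization),
#'   `gene_ids` and `cell_ids`.
#' @seealso [normalize_counts()], [filter_cells()], [read_expression_mtx()]
#' @export
expression_matrix <- function(counts,
                              gene_ids = rownames(counts),
                              cell_ids = colnames(counts)) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids must be supplied or present as dimnames")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    stop("counts dimensions do not match identifier lengths")
  }
  if (length(counts@x) && min(counts@x) < 0) stop("counts must be non-negative")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, norm = NULL, gene_ids = gene_ids,
         cell_ids = cell_ids),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (is.null(x$norm)) "raw counts" else "counts + normalized"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a count matrix from MatrixMarket with TSV sidecars
#'
#' Expects `matrix.mtx`, `genes.tsv` and `cells.tsv` inside `dir` (or explicit
#' paths). The sidecars are header-less single-column files giving the row and
#' column identifiers, in order, as produced by [write_expression_mtx()].
#'
#' @param dir Directory containing the three files.
#' @param mtx,genes,cells Optional explicit file paths overriding `dir`.
#' @return An [expression_matrix()] object.
#' @export
read_expression_mtx <- function(dir = ".",
                                mtx = file.path(dir, "matrix.mtx"),
                                genes = file.path(dir, "genes.tsv"),
                                cells = file.path(dir, "cells.tsv")) {
  m <- Matrix::readMM(mtx)
  gene_ids <- readLines(genes)
  cell_ids <- readLines(cells)
  expression_matrix(m, gene_ids = gene_ids, cell_ids = cell_ids)
}

#' Write a count matrix as MatrixMarket with TSV sidecars
#'
#' @param x An `ExpressionMatrix`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_expression_mtx <- function(x, dir) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  Matrix::writeMM(x$counts, paths[1])
  writeLines(x$gene_ids, paths[2])
  writeLines(x$cell_ids, paths[3])
  invisible(paths)
}

#' Read per-cell annotations from TSV
#'
#' The file must have columns `cell_id`, `stage`, `cell_type`,
#' `mito_fraction`, `n_genes_detected`.
#'
#' @param path TSV file path.
#' @return A data.frame of cell annotations.
#' @export
read_cell_annotations <- function(path) {
  annot <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotations(annot)
  annot
}

#' Write per-cell annotations to TSV
#' @param annot Annotation data.frame.
#' @param path Output file.
#' @export
write_cell_annotations <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_annotations <- function(annot, matrix = NULL) {
  required <- c("cell_id", "stage", "cell_type", "mito_fraction",
                "n_genes_detected")
  missing <- setdiff(required, names(annot))
  if (length(missing)) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(annot$cell_id)) stop("duplicate cell_id in annotations")
  if (any(annot$mito_fraction < 0 | annot$mito_fraction > 1)) {
    stop("mito_fraction must lie in [0, 1]")
  }
  if (any(annot$n_genes_detected < 0)) {
    stop("n_genes_detected must be non-negative")
  }
  if (!is.null(matrix)) {
    unknown <- setdiff(annot$cell_id, matrix$cell_ids)
    if (length(unknown)) {
      stop("annotation cell_id(s) absent from matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    uncovered <- setdiff(matrix$cell_ids, annot$cell_id)
    if (length(uncovered)) {
      stop("matrix cell(s) lack annotations: ",
           paste(utils::head(uncovered, 5), collapse = ", "))
    }
  }
  invisible(annot)
}
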