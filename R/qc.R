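#' Default ordered developmental stage set
#'
#' Five stages from late gastrula to post-neurula, ordered by developmental
#' time: HH5, HH7 (1 somite), HH8 (4 somites), HH9 (7 somites), HH11.
#'
#' @return Character vector of stage labels in developmental order.
#' @export
default_stage_order <- function() {
  c("HH5", "HH7_1som", "HH8_4som", "HH9_7som", "HH11")
}

#' Filter cells on detected-gene and mitochondrial-content caps
#'
#' Retains exactly the cells whose number of detected genes does not exceed
#' `max_genes` and whose mitochondrial fraction does not exceed `max_mito`.
#' The gene set and the order of surviving cells are unchanged, so the
#' operation is idempotent.
#'
#' The mitochondrial default of 0.004 reads a quality cutoff of "0.4%"
#' as a fraction of counts; it is unusually strict, so both caps are plain
#' arguments that callers can relax per sample.
#'
#' @param matrix An [expression_matrix()] object.
#' @param annot Cell annotation data.frame covering every cell of `matrix`.
#' @param max_genes Cap on `n_genes_detected` (default 5500).
#' @param max_mito Cap on `mito_fraction` (default 0.004).
#' @return A filtered `ExpressionMatrix`.
#' @export
filter_cells <- function(matrix, annot, max_genes = 5500, max_mito = 0.004) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  validate_annotations(annot, matrix)
  keep_ids <- annot$cell_id[annot$n_genes_detected <= max_genes &
                              annot$mito_fraction <= max_mito]
  keep <- matrix$cell_ids %in% keep_ids
  out <- expression_matrix(matrix$counts[, keep, drop = FALSE],
                           gene_ids = matrix$gene_ids,
                           cell_ids = matrix$cell_ids[keep])
  if (!is.null(matrix$norm)) out$norm <- matrix$norm[, keep, drop = FALSE]
  out
}

#' Library-size normalize counts to a natural-log layer
#'
#' Computes `norm[g, c] = ln(counts[g, c] / total_counts[c] * scale_factor + 1)`
#' and stores it alongside the untouched counts. This is the standard
#' log-normalization of single-cell toolkits (scale factor 1e4, pseudocount 1,
#' natural log), and preserves the within-cell rank order of genes.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param scale_factor Positive scale applied after library-size division.
#' @return The matrix with its `norm` layer populated.
#' @export
normalize_counts <- function(matrix, scale_factor = 1e4) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), scale_factor > 0)
  totals <- Matrix::colSums(matrix$counts)
  if (any(totals == 0)) {
    stop("cell(s) with zero total counts cannot be normalized: ",
         paste(utils::head(matrix$cell_ids[totals == 0], 5), collapse = ", "))
  }
  norm <- matrix$counts
  # scale each column's nonzero entries by its library size
  ncol_rep <- diff(norm@p)
  norm@x <- log1p(norm@x / rep.int(totals, ncol_rep) * scale_factor)
  matrix$norm <- norm
  matrix
}

#' Identity label for (stage, cell type) pairs
#' @param stage,cell_type Character vectors (recycled together).
#' @return Character labels of the form `stage|cell_type`.
#' @export
identity_label <- function(stage, cell_type) paste(stage, cell_type, sep = "|")

#' Build the stage x cell-type identity grid from annotations
#'
#' One identity per observed (stage, cell type) pair, sorted by the declared
#' stage order then by cell type. With the default cranial-ectoderm presence pattern --
#' an undecided pan-ectodermal population at the three earliest stages only,
#' the neural plate border at the 4-somite stage, neural crest at the
#' 7-somite stage and HH11, and non-neural ectoderm plus dorsal and ventral
#' neural domains at all five stages -- this yields 21 identities.
#'
#' @param annot Cell annotation data.frame with `stage` and `cell_type`.
#' @param stage_order Ordered character vector of allowed stages.
#' @return An `IdentityGrid`: a data.frame with columns `stage`, `cell_type`,
#'   `identity` (label) and `n_cells`, carrying `stage_order` as an attribute.
#' @export
build_identity_grid <- function(annot, stage_order = default_stage_order()) {
  if (!all(c("stage", "cell_type") %in% names(annot))) {
    stop("annotations need stage and cell_type columns")
  }
  bad <- setdiff(unique(annot$stage), stage_order)
  if (length(bad)) {
    stop("stage(s) outside the declared stage order: ",
         paste(bad, collapse = ", "))
  }
  tab <- as.data.frame(table(stage = annot$stage,
                             cell_type = annot$cell_type),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  ord <- order(match(tab$stage, stage_order), tab$cell_type)
  tab <- tab[ord, , drop = FALSE]
  grid <- data.frame(stage = tab$stage, cell_type = tab$cell_type,
                     identity = identity_label(tab$stage, tab$cell_type),
                     n_cells = tab$Freq, stringsAsFactors = FALSE,
                     row.names = NULL)
  attr(grid, "stage_order") <- stage_order
  class(grid) <- c("IdentityGrid", "data.frame")
  grid
}

#' Per-cell identity labels aligned with a matrix
#' @keywords internal
cell_identities <- function(matrix, annot) {
  idx <- match(matrix$cell_ids, annot$cell_id)
  if (anyNA(idx)) stop("annotations do not cover all matrix cells")
  identity_label(annot$stage[idx], annot$cell_type[idx])
}

# genes x identities indicator matrix used to vectorize per-group sums
identity_indicator <- function(matrix, annot, grid) {
  ids <- cell_identities(matrix, annot)
  col <- match(ids, grid$identity)
  if (anyNA(col)) {
    stop("cells with identities absent from the grid: ",
         paste(utils::head(unique(ids[is.na(col)]), 5), collapse = ", "))
  }
  Matrix::sparseMatrix(i = seq_along(col), j = col,
                       x = 1, dims = c(length(col), nrow(grid)),
                       dimnames = list(matrix$cell_ids, grid$identity))
}

#' Mean normalized expression per identity
#'
#' Arithmetic mean of the natural-log normalized layer over each identity's
#' cells.
#'
#' @param matrix A normalized `ExpressionMatrix`.
#' @param annot Cell annotations.
#' @param grid An [build_identity_grid()] result.
#' @return A dense genes x identities matrix.
#' @export
mean_expression_by_identity <- function(matrix, annot, grid) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is.null(matrix$norm)) stop("normalized layer missing; run normalize_counts()")
  ind <- identity_indicator(matrix, annot, grid)
  sizes <- Matrix::colSums(ind)
  if (any(sizes == 0)) {
    stop("empty identity: ", paste(grid$identity[sizes == 0], collapse = ", "))
  }
  sums <- as.matrix(matrix$norm %*% ind)
  sweep(sums, 2, sizes, "/")
}
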