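# Small in-code fixtures shared across test files.

# Expression bundle from an explicit normalized matrix: counts are a scaled
# integer shadow (only the norm layer matters for the ops under test).
make_norm_fixture <- function(norm, stages, cell_types,
                              stage_order = unique(stages)) {
  norm <- as.matrix(norm)
  if (is.null(rownames(norm))) {
    rownames(norm) <- sprintf("g%02d", seq_len(nrow(norm)))
  }
  if (is.null(colnames(norm))) {
    colnames(norm) <- sprintf("c%02d", seq_len(ncol(norm)))
  }
  counts <- round(expm1(norm) * 10)
  counts[counts == 0 & norm > 0] <- 1
  em <- expression_matrix(counts)
  em$norm <- methods::as(Matrix::Matrix(norm, sparse = TRUE), "CsparseMatrix")
  annot <- data.frame(
    cell_id = colnames(norm), stage = stages, cell_type = cell_types,
    mito_fraction = 0, n_genes_detected = colSums(counts > 0),
    stringsAsFactors = FALSE
  )
  grid <- build_identity_grid(annot, stage_order = stage_order)
  list(em = em, annot = annot, grid = grid)
}

# ActivityMatrix wrapper around a plain score matrix (for pattern tests).
fake_activity <- function(score, p = NULL) {
  structure(
    list(score = score,
         p_value = if (is.null(p)) score * 0 + 0.5 else p,
         p_adj = if (is.null(p)) score * 0 + 0.5 else p,
         n_used = stats::setNames(rep(5L, nrow(score)), rownames(score))),
    class = "ActivityMatrix"
  )
}

# Minimal grid straight from stage / cell-type vectors (one row each).
make_grid <- function(stages, cell_types, stage_order = unique(stages)) {
  annot <- data.frame(cell_id = sprintf("x%03d", seq_along(stages)),
                      stage = stages, cell_type = cell_types,
                      mito_fraction = 0, n_genes_detected = 1,
                      stringsAsFactors = FALSE)
  build_identity_grid(annot, stage_order = stage_order)
}

# A small, fast simulation configuration for property-style tests.
small_config <- function(seed, ...) {
  simulation_config(
    n_genes = 600, n_tfs = 10, targets_per_tf = 10,
    cells_per_identity = 30, n_planted = 5, seed = seed, ...
  )
}
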