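#' Tukey trimean
#'
#' `(Q1 + 2 * median + Q3) / 4` with linear-interpolation (type-7) quantiles:
#' a robust group average that stays at zero unless at least a quarter of the
#' group expresses the gene, which is the conservative averaging behind the
#' communication scores.
#'
#' @param values Non-empty numeric vector.
#' @return The trimean.
#' @export
trimean <- function(values) {
  if (!length(values)) stop("empty vector")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  (q[1] + 2 * q[2] + q[3]) / 4
}

#' Trimean expression of selected genes per identity
#'
#' @param matrix A normalized `ExpressionMatrix`.
#' @param annot Cell annotations.
#' @param grid Identity grid.
#' @param genes Genes to summarize; genes absent from the matrix produce a
#'   row of missing values with a warning.
#' @return A genes x identities matrix of trimeans.
#' @export
group_expression <- function(matrix, annot, grid, genes) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is.null(matrix$norm)) stop("normalized layer missing; run normalize_counts()")
  ids <- cell_identities(matrix, annot)
  rows <- match(genes, matrix$gene_ids)
  if (anyNA(rows)) {
    warning("gene(s) absent from matrix: ",
            paste(genes[is.na(rows)], collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = length(genes), ncol = nrow(grid),
                dimnames = list(genes, grid$identity))
  present <- which(!is.na(rows))
  if (length(present)) {
    sub <- as.matrix(matrix$norm[rows[present], , drop = FALSE])
    for (j in seq_len(nrow(grid))) {
      cells <- ids == grid$identity[j]
      out[present, j] <- apply(sub[, cells, drop = FALSE], 1, trimean)
    }
  }
  out
}

#' Multi-subunit receptor complex expression
#'
#' Geometric mean of the subunits' group-expression values; zero whenever
#' any subunit is absent, since an incomplete complex cannot signal.
#'
#' @param subunit_values Non-negative numeric vector, one value per subunit.
#' @return The complex-level expression value.
#' @export
complex_expression <- function(subunit_values) {
  stopifnot(all(subunit_values >= 0))
  if (any(subunit_values == 0)) return(0)
  exp(mean(log(subunit_values)))
}

#' Mass-action Hill interaction probability
#'
#' `P = L * R / (Kh + L * R)`: the saturating communication strength between
#' a sender's ligand level `L` and a receiver's receptor level `R`, with
#' half-saturation constant `Kh`. Bounded in `[0, 1)`, zero when either side
#' is zero, and monotone nondecreasing in each argument.
#'
#' @param L,R Non-negative expression levels (vectorized).
#' @param Kh Positive half-saturation constant (default 0.5).
#' @return Interaction probabilities.
#' @export
interaction_probability <- function(L, R, Kh = 0.5) {
  stopifnot(Kh > 0, all(L >= 0), all(R >= 0))
  lr <- L * R
  lr / (Kh + lr)
}

#' Read a ligand-receptor pair database from TSV
#'
#' Columns `ligand`, `receptor` (subunits separated by `;`) and `pathway`.
#'
#' @param path TSV file.
#' @return Data.frame with a `subunits` list-column and a `pair` label
#'   (`ligand->receptor`).
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lr_pairs(df)
}

#' @rdname read_lr_pairs
#' @param df Data.frame with columns `ligand`, `receptor`, `pathway`.
#' @export
lr_pairs <- function(df) {
  required <- c("ligand", "receptor", "pathway")
  if (!all(required %in% names(df))) {
    stop("pair table needs columns ligand, receptor, pathway")
  }
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)) ||
      any(!nzchar(df$pathway))) {
    stop("empty ligand / receptor / pathway label")
  }
  df$subunits <- strsplit(df$receptor, ";", fixed = TRUE)
  df$pair <- paste(df$ligand, df$receptor, sep = "->")
  if (anyDuplicated(df$pair)) stop("duplicate ligand-receptor pairs")
  df
}

# source x target x pair probability array from a gene x identity trimean
# matrix
communication_probability <- function(expr, pairs, Kh = 0.5) {
  ids <- colnames(expr)
  n <- length(ids)
  prob <- array(0, dim = c(n, n, nrow(pairs)),
                dimnames = list(source = ids, target = ids, pair = pairs$pair))
  for (k in seq_len(nrow(pairs))) {
    lig <- expr[pairs$ligand[k], ]
    rec <- apply(expr[pairs$subunits[[k]], , drop = FALSE], 2,
                 complex_expression)
    lig[is.na(lig)] <- 0
    rec[is.na(rec)] <- 0
    prob[, , k] <- interaction_probability(outer(lig, rec), 1, Kh = Kh)
  }
  prob
}

#' Ligand-receptor communication scoring with permutation significance
#'
#' For every (source identity, target identity, pair), the observed
#' interaction probability is the mass-action Hill score of the source's
#' trimean ligand expression against the target's receptor-complex
#' expression (geometric mean over subunits). The null is built by permuting
#' the cell-to-identity assignment `n_perm` times and recomputing; the
#' p-value uses the add-one estimator `(1 + #(perm >= obs)) / (1 + n_perm)`,
#' and entries with observed probability zero are assigned p = 1. The
#' retained set is `p < alpha` with positive probability.
#'
#' @param matrix A normalized `ExpressionMatrix`.
#' @param annot Cell annotations.
#' @param grid Identity grid; identities with fewer than 2 cells are excluded
#'   with a warning.
#' @param pairs Pair table from [lr_pairs()] / [read_lr_pairs()]. Pairs whose
#'   ligand or some receptor subunit is absent from the matrix are dropped
#'   with a warning.
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed fixing the permutations.
#' @param Kh Half-saturation constant (default 0.5).
#' @param alpha Retention threshold on the permutation p-value.
#' @return A `CommunicationTensor`: list with 3-d arrays `probability` and
#'   `p_value` (source x target x pair), logical `retained`, the `pairs`
#'   table and the identity labels.
#' @export
permutation_test <- function(matrix, annot, grid, pairs, n_perm = 100,
                             seed = 1, Kh = 0.5, alpha = 0.05) {
  stopifnot(n_perm >= 1)
  small <- grid$n_cells < 2
  if (any(small)) {
    warning("identities with fewer than 2 cells excluded: ",
            paste(grid$identity[small], collapse = ", "))
    grid <- grid[!small, , drop = FALSE]
  }
  genes <- unique(c(pairs$ligand, unlist(pairs$subunits)))
  absent <- setdiff(genes, matrix$gene_ids)
  if (length(absent)) {
    drop <- vapply(seq_len(nrow(pairs)), function(k) {
      pairs$ligand[k] %in% absent || any(pairs$subunits[[k]] %in% absent)
    }, logical(1))
    warning("pair(s) with genes absent from the matrix dropped: ",
            paste(pairs$pair[drop], collapse = ", "))
    pairs <- pairs[!drop, , drop = FALSE]
    genes <- setdiff(genes, absent)
  }
  if (!nrow(pairs)) stop("no usable ligand-receptor pairs")

  ids <- cell_identities(matrix, annot)
  use <- ids %in% grid$identity
  sub <- as.matrix(matrix$norm[match(genes, matrix$gene_ids), use,
                               drop = FALSE])
  rownames(sub) <- genes
  labels <- ids[use]

  grp_trimean <- function(lab) {
    out <- matrix(NA_real_, nrow = nrow(sub), ncol = nrow(grid),
                  dimnames = list(genes, grid$identity))
    for (j in seq_len(nrow(grid))) {
      cells <- lab == grid$identity[j]
      out[, j] <- apply(sub[, cells, drop = FALSE], 1, trimean)
    }
    out
  }

  obs <- communication_probability(grp_trimean(labels), pairs, Kh = Kh)
  exceed <- array(0L, dim = dim(obs))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- communication_probability(grp_trimean(sample(labels)), pairs,
                                      Kh = Kh)
    exceed <- exceed + (perm >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  p[obs == 0] <- 1
  structure(
    list(probability = obs, p_value = p,
         retained = p < alpha & obs > 0,
         pairs = pairs, identities = grid$identity, alpha = alpha),
    class = "CommunicationTensor"
  )
}

#' @export
print.CommunicationTensor <- function(x, ...) {
  cat(sprintf(
    "CommunicationTensor: %d identities x %d pairs (%d retained entries)\n",
    length(x$identities), nrow(x$pairs), sum(x$retained)))
  invisible(x)
}

#' Aggregate retained communication over a pathway
#'
#' Sums the retained interaction probabilities of the pathway's pairs into a
#' source x target matrix; sender strength is its row sums and receiver
#' strength its column sums, so total sender mass, receiver mass and matrix
#' mass coincide.
#'
#' @param tensor A `CommunicationTensor` from [permutation_test()].
#' @param pathway Pathway label present in the tensor's pair table.
#' @return List with `matrix` (source x target), `sender_strength`,
#'   `receiver_strength`.
#' @export
aggregate_pathway <- function(tensor, pathway) {
  stopifnot(inherits(tensor, "CommunicationTensor"))
  k <- which(tensor$pairs$pathway == pathway)
  if (!length(k)) stop("unknown pathway: ", pathway)
  kept <- tensor$probability * tensor$retained
  if (!any(tensor$retained[, , k, drop = FALSE])) {
    stop("pathway ", pathway, " has no retained pairs")
  }
  m <- apply(kept[, , k, drop = FALSE], c(1, 2), sum)
  list(matrix = m, sender_strength = rowSums(m),
       receiver_strength = colSums(m))
}

#' Write a communication tensor as long-format TSV
#'
#' Columns: source, target, ligand, receptor, pathway, probability, p_value.
#'
#' @param tensor A `CommunicationTensor`.
#' @param path Output file.
#' @param drop_zero Omit zero-probability entries (default TRUE).
#' @export
write_communication <- function(tensor, path, drop_zero = TRUE) {
  idx <- which(!drop_zero | tensor$probability > 0, arr.ind = TRUE)
  df <- data.frame(
    source = tensor$identities[idx[, 1]],
    target = tensor$identities[idx[, 2]],
    ligand = tensor$pairs$ligand[idx[, 3]],
    receptor = tensor$pairs$receptor[idx[, 3]],
    pathway = tensor$pairs$pathway[idx[, 3]],
    probability = tensor$probability[idx],
    p_value = tensor$p_value[idx],
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
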