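#' Natural-log fold change between two groups of normalized values
#'
#' Fold change on de-logged means with a pseudocount:
#' `ln(mean(exp(x_in) - 1) + 1) - ln(mean(exp(x_out) - 1) + 1)`, the
#' convention of current single-cell toolkits for log-normalized layers.
#' Antisymmetric in its arguments and invariant to cell order.
#'
#' @param norm_in,norm_out Non-empty numeric vectors of normalized expression.
#' @return A single natural-log fold change.
#' @export
compute_lfc <- function(norm_in, norm_out) {
  if (!length(norm_in) || !length(norm_out)) stop("both groups must be non-empty")
  log1p(mean(expm1(norm_in))) - log1p(mean(expm1(norm_out)))
}

#' Fraction of cells with detectable expression
#' @param norm Non-empty numeric vector of normalized expression.
#' @return Fraction of entries strictly greater than zero.
#' @export
pct_expressed <- function(norm) {
  if (!length(norm)) stop("empty vector")
  mean(norm > 0)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Mid-ranks are used for ties. By default the p-value comes from the normal
#' approximation with tie-corrected variance and no continuity correction;
#' when the smaller group has at most `exact_max_n` observations and the
#' number of group labelings is enumerable, an exact mode is used instead:
#' the tie-free case goes through the closed-form Wilcoxon distribution and
#' tied data through complete enumeration of labelings.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact `TRUE`/`FALSE` to force a mode, or `NA` (default) to enable
#'   the exact mode automatically for small groups.
#' @param exact_max_n Largest min-group size for automatic exact mode.
#' @return List with `statistic` (the U statistic of `x`) and `p_value`.
#' @export
rank_sum_test <- function(x, y, exact = NA, exact_max_n = 7) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(all_v)) == 1L) {
    return(list(statistic = n1 * n2 / 2, p_value = 1))
  }
  ties <- anyDuplicated(all_v) > 0L
  n_comb <- choose(n1 + n2, min(n1, n2))
  do_exact <- if (is.na(exact)) {
    min(n1, n2) <= exact_max_n && n_comb <= 2e5
  } else {
    isTRUE(exact)
  }
  if (do_exact && n_comb > 2e5) {
    stop("exact mode infeasible for these group sizes")
  }
  if (do_exact) {
    if (!ties) {
      # closed-form exact null distribution of U
      lower <- stats::pwilcox(u, n1, n2)
      upper <- 1 - stats::pwilcox(u - 1, n1, n2)
      p <- min(1, 2 * min(lower, upper))
    } else {
      p <- exact_u_enumeration(r, n1, n2, u)
    }
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    tie_tab <- table(all_v)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = u, p_value = min(1, p))
}

# two-sided permutation p for U over all labelings, symmetric about n1*n2/2
exact_u_enumeration <- function(r, n1, n2, u_obs) {
  n <- n1 + n2
  k <- min(n1, n2)
  combs <- utils::combn(n, k)
  rs <- colSums(matrix(r[combs], nrow = k))
  u_all <- rs - k * (k + 1) / 2
  mu <- n1 * n2 / 2
  # observed U of x expressed on the enumerated (smaller) group's scale
  dev_obs <- abs(u_obs - mu)
  mean(abs(u_all - mu) >= dev_obs - 1e-9)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, monotone and capped at 1.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' One-vs-rest marker detection per identity
#'
#' For each identity of the grid, contrasts its cells against all other cells.
#' A gene is kept when `max(pct_in, pct_out) >= min_pct` and
#' `|lfc| >= logfc_threshold`; the rank-sum p-value is computed only for kept
#' genes, with Benjamini-Hochberg adjustment across kept genes within each
#' identity. Identities with fewer than three cells are skipped with a
#' warning.
#'
#' @param matrix A normalized `ExpressionMatrix`.
#' @param annot Cell annotations.
#' @param grid Identity grid from [build_identity_grid()].
#' @param logfc_threshold Minimum absolute natural-log fold change.
#' @param min_pct Minimum detection fraction in the better-detected group.
#' @return A data.frame of marker records: `gene`, `stage`, `cell_type`,
#'   `identity`, `lfc`, `pct_in`, `pct_out`, `p_value`, `p_adj`.
#' @export
find_markers <- function(matrix, annot, grid, logfc_threshold = 0.2,
                         min_pct = 0.25) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is.null(matrix$norm)) stop("normalized layer missing; run normalize_counts()")
  ind <- identity_indicator(matrix, annot, grid)
  sizes <- Matrix::colSums(ind)
  expm1_mat <- matrix$norm
  expm1_mat@x <- expm1(expm1_mat@x)
  grp_expm1 <- as.matrix(expm1_mat %*% ind)
  tot_expm1 <- Matrix::rowSums(expm1_mat)
  detected <- matrix$norm
  detected@x <- as.numeric(detected@x > 0)
  grp_det <- as.matrix(detected %*% ind)
  tot_det <- Matrix::rowSums(detected)
  n_cells <- length(matrix$cell_ids)
  ids <- cell_identities(matrix, annot)

  res <- vector("list", nrow(grid))
  for (j in seq_len(nrow(grid))) {
    n_in <- sizes[j]
    n_out <- n_cells - n_in
    if (n_in < 3) {
      warning("identity ", grid$identity[j], " has fewer than 3 cells; skipped")
      next
    }
    lfc <- log1p(grp_expm1[, j] / n_in) -
      log1p((tot_expm1 - grp_expm1[, j]) / n_out)
    pct_in <- grp_det[, j] / n_in
    pct_out <- (tot_det - grp_det[, j]) / n_out
    keep <- pmax(pct_in, pct_out) >= min_pct & abs(lfc) >= logfc_threshold
    if (!any(keep)) next
    in_cells <- ids == grid$identity[j]
    sub <- as.matrix(matrix$norm[keep, , drop = FALSE])
    pv <- apply(sub, 1, function(v) {
      rank_sum_test(v[in_cells], v[!in_cells])$p_value
    })
    res[[j]] <- data.frame(
      gene = matrix$gene_ids[keep],
      stage = grid$stage[j], cell_type = grid$cell_type[j],
      identity = grid$identity[j],
      lfc = unname(lfc[keep]),
      pct_in = unname(pct_in[keep]), pct_out = unname(pct_out[keep]),
      p_value = unname(pv), p_adj = unname(bh_adjust(pv)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene = character(), stage = character(),
                      cell_type = character(), identity = character(),
                      lfc = numeric(), pct_in = numeric(), pct_out = numeric(),
                      p_value = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Assemble the genes x identities log-fold-change matrix
#'
#' Rows are the union of marker genes; columns follow the grid. Cells not
#' tested or not passing the marker filters in an identity are filled with 0
#' (`fill_policy = "zero"`, no evidence of change) or `NA`
#' (`fill_policy = "missing"`).
#'
#' @param markers Marker data.frame from [find_markers()].
#' @param grid Identity grid.
#' @param fill_policy `"zero"` or `"missing"`.
#' @return A numeric matrix with gene rownames and identity colnames.
#' @export
build_lfc_matrix <- function(markers, grid, fill_policy = c("zero", "missing")) {
  fill_policy <- match.arg(fill_policy)
  if (anyDuplicated(markers[c("gene", "identity")])) {
    stop("duplicate (gene, identity) marker records")
  }
  genes <- sort(unique(markers$gene))
  fill <- if (fill_policy == "zero") 0 else NA_real_
  m <- matrix(fill, nrow = length(genes), ncol = nrow(grid),
              dimnames = list(genes, grid$identity))
  if (nrow(markers)) {
    m[cbind(match(markers$gene, genes),
            match(markers$identity, grid$identity))] <- markers$lfc
  }
  m
}

#' Write / read marker tables as TSV
#' @param markers Marker data.frame.
#' @param path File path.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a log-fold-change matrix as TSV with identity columns
#' @param lfc Matrix from [build_lfc_matrix()].
#' @param path File path.
#' @export
write_lfc_matrix <- function(lfc, path) {
  df <- data.frame(gene = rownames(lfc), lfc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfc_matrix
#' @export
read_lfc_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}
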