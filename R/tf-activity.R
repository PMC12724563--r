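#' Construct a signed TF-target regulon network
#'
#' Edges carry a nonzero weight, typically +1 (activation) or -1
#' (repression), giving each transcription factor a signed weight vector over
#' its targets (its regulon). Duplicate (tf, target) pairs are rejected.
#'
#' @param edges Data.frame with columns `source` (TF), `target` and `weight`.
#' @param min_targets Minimum number of targets that must map into the gene
#'   universe for a TF to be scored (default 5).
#' @return A `RegulonNetwork` object.
#' @export
regulon_network <- function(edges, min_targets = 5) {
  required <- c("source", "target", "weight")
  if (!all(required %in% names(edges))) {
    stop("edges need columns source, target, weight")
  }
  if (anyDuplicated(edges[c("source", "target")])) {
    stop("duplicate (tf, target) edges")
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight == 0)) {
    stop("edge weights must be finite and nonzero")
  }
  structure(list(edges = edges[required], min_targets = min_targets),
            class = "RegulonNetwork")
}

#' Read a regulon network from TSV (columns source, target, weight)
#' @param path TSV file.
#' @param min_targets Passed to [regulon_network()].
#' @export
read_regulon_network <- function(path, min_targets = 5) {
  regulon_network(utils::read.delim(path, stringsAsFactors = FALSE),
                  min_targets = min_targets)
}

#' Write a regulon network to TSV
#' @param network A `RegulonNetwork`.
#' @param path Output file.
#' @export
write_regulon_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Univariate linear-model activity score
#'
#' Regresses the contrast's gene-level log-fold-changes on a TF's regulon
#' weight vector (weight for targets, 0 for every other gene of the
#' universe). The activity score is the t-statistic of the slope,
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `r` the Pearson correlation, and
#' the p-value the two-sided Student-t tail with `n - 2` degrees of freedom.
#' A positive score means the TF's canonical downstream program is up.
#'
#' Degenerate inputs follow a fixed convention: zero variance in either
#' vector gives score 0 with p 1; a numerically perfect fit
#' (`1 - r^2 < 1e-12`) is capped at +/- 1e6 with the smallest representable
#' tail, so toy cases stay finite.
#'
#' @param weights_x Numeric regulon weight vector over the gene universe.
#' @param lfc_y Numeric log-fold-change vector over the same universe.
#' @param min_n Smallest usable universe (default 7: the default regulon-size
#'   floor plus the two regression degrees of freedom).
#' @return List with `score` and `p_value`.
#' @export
ulm_score <- function(weights_x, lfc_y, min_n = 7) {
  n <- length(weights_x)
  if (length(lfc_y) != n) stop("vectors must share the gene universe")
  if (n < min_n) stop("universe too small for a univariate fit")
  sx <- stats::sd(weights_x)
  sy <- stats::sd(lfc_y)
  if (sx == 0 || sy == 0) return(list(score = 0, p_value = 1))
  r <- stats::cor(weights_x, lfc_y)
  if (1 - r^2 < 1e-12) {
    return(list(score = sign(r) * 1e6, p_value = .Machine$double.xmin))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(score = t, p_value = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Infer the TF x identity activity matrix
#'
#' Scores every TF of the network against every identity column of the
#' log-fold-change matrix with [ulm_score()], using the LFC gene universe.
#' Target symbols are matched case-insensitively (the regulon resource is
#' human-derived while the expression data may use another species' casing);
#' an optional two-column alias table (`from`, `to`) is applied first. TFs
#' with fewer than `min_targets` mapped targets are dropped and reported in
#' the `dropped` attribute.
#'
#' @param lfc Genes x identities matrix from [build_lfc_matrix()].
#' @param network A [regulon_network()].
#' @param alias Optional data.frame with columns `from`, `to` renaming
#'   network targets into the expression namespace.
#' @return An `ActivityMatrix`: list with `score` and `p_value`
#'   (TFs x identities matrices), `n_used` (mapped targets per scored TF) and
#'   a `dropped` attribute naming unscored TFs.
#' @export
activity_matrix <- function(lfc, network, alias = NULL) {
  stopifnot(inherits(network, "RegulonNetwork"))
  edges <- network$edges
  if (!is.null(alias)) {
    hit <- match(edges$target, alias$from)
    edges$target[!is.na(hit)] <- alias$to[hit[!is.na(hit)]]
  }
  universe <- rownames(lfc)
  row_idx <- match(tolower(edges$target), tolower(universe))
  edges$row <- row_idx
  tfs <- unique(edges$source)
  n_used <- vapply(split(!is.na(row_idx), edges$source)[tfs], sum, integer(1))
  eligible <- tfs[n_used >= network$min_targets]
  if (!length(eligible)) {
    stop("no TF has >= ", network$min_targets, " targets in the LFC universe ",
         "(", length(universe), " genes; best TF maps ",
         if (length(n_used)) max(n_used) else 0, " targets)")
  }
  n <- length(universe)
  score <- p_value <- matrix(
    NA_real_, nrow = length(eligible), ncol = ncol(lfc),
    dimnames = list(eligible, colnames(lfc))
  )
  for (tf in eligible) {
    e <- edges[edges$source == tf & !is.na(edges$row), , drop = FALSE]
    x <- numeric(n)
    x[e$row] <- e$weight
    for (j in seq_len(ncol(lfc))) {
      y <- lfc[, j]
      ok <- !is.na(y)
      fit <- ulm_score(x[ok], y[ok], min_n = network$min_targets + 2)
      score[tf, j] <- fit$score
      p_value[tf, j] <- fit$p_value
    }
  }
  structure(
    list(score = score, p_value = p_value,
         p_adj = apply(p_value, 2, bh_adjust),
         n_used = n_used[eligible]),
    dropped = setdiff(tfs, eligible),
    class = "ActivityMatrix"
  )
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat(sprintf("ActivityMatrix: %d TFs x %d identities (%d masked entries)\n",
              nrow(x$score), ncol(x$score), sum(is.na(x$score))))
  invisible(x)
}

#' Mask activity scores where the TF itself is not expressed
#'
#' Entries are set to missing wherever the TF's mean normalized expression in
#' that identity is at or below `threshold` (default 0: the TF must be
#' detectably transcribed for its inferred activity to be interpretable).
#' TFs absent from the expression matrix are masked everywhere with a
#' warning; rows that end up entirely masked are dropped.
#'
#' @param activity An `ActivityMatrix`.
#' @param mean_expr Genes x identities matrix from
#'   [mean_expression_by_identity()].
#' @param threshold Expression value that must be exceeded.
#' @return The masked `ActivityMatrix`.
#' @export
retain_expressed <- function(activity, mean_expr, threshold = 0) {
  stopifnot(inherits(activity, "ActivityMatrix"))
  tfs <- rownames(activity$score)
  cols <- match(colnames(activity$score), colnames(mean_expr))
  if (anyNA(cols)) stop("expression matrix lacks identity column(s)")
  rows <- match(tolower(tfs), tolower(rownames(mean_expr)))
  if (anyNA(rows)) {
    warning("TF(s) absent from expression matrix, masked everywhere: ",
            paste(tfs[is.na(rows)], collapse = ", "))
  }
  expr <- matrix(-Inf, nrow = length(tfs), ncol = ncol(activity$score))
  has <- !is.na(rows)
  expr[has, ] <- mean_expr[rows[has], cols, drop = FALSE]
  mask <- expr <= threshold
  activity$score[mask] <- NA_real_
  activity$p_value[mask] <- NA_real_
  activity$p_adj[mask] <- NA_real_
  keep <- rowSums(!is.na(activity$score)) > 0
  activity$score <- activity$score[keep, , drop = FALSE]
  activity$p_value <- activity$p_value[keep, , drop = FALSE]
  activity$p_adj <- activity$p_adj[keep, , drop = FALSE]
  activity$n_used <- activity$n_used[keep]
  activity
}

#' Write an activity matrix as a long-format TSV
#'
#' Columns: tf, stage, cell_type, score, p_value, p_adj, n_used. Masked
#' entries are omitted.
#'
#' @param activity An `ActivityMatrix`.
#' @param grid Identity grid giving the stage / cell-type decomposition.
#' @param path Output file.
#' @export
write_activity <- function(activity, grid, path) {
  idx <- which(!is.na(activity$score), arr.ind = TRUE)
  id <- colnames(activity$score)[idx[, 2]]
  g <- match(id, grid$identity)
  df <- data.frame(
    tf = rownames(activity$score)[idx[, 1]],
    stage = grid$stage[g], cell_type = grid$cell_type[g],
    score = activity$score[idx], p_value = activity$p_value[idx],
    p_adj = activity$p_adj[idx],
    n_used = unname(activity$n_used[idx[, 1]]),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$tf, match(df$stage, attr(grid, "stage_order"))), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
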