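#' Four-way quadrant classification of expression versus activity
#'
#' Crosses an activity threshold (default 0, separating positive from
#' negative inferred activity) with a log-scale expression threshold
#' (default 1) to label every unmasked (TF, identity) entry as one of
#' `high_expr_high_act`, `high_expr_low_act`, `low_expr_high_act` or
#' `low_expr_low_act`. Both boundaries are strict: a value exactly on a
#' threshold falls in the "low" class.
#'
#' @param activity An `ActivityMatrix`.
#' @param mean_expr Genes x identities expression matrix.
#' @param grid Identity grid.
#' @param act_thresh,expr_thresh Strict lower bounds for the "high" classes.
#' @return A data.frame with one row per unmasked entry: `tf`, `stage`,
#'   `cell_type`, `label`, `activity`, `expression`.
#' @export
quadrant_classify <- function(activity, mean_expr, grid,
                              act_thresh = 0, expr_thresh = 1) {
  stopifnot(inherits(activity, "ActivityMatrix"))
  score <- activity$score
  expr <- aligned_expression(score, mean_expr)
  idx <- which(!is.na(score) & !is.na(expr), arr.ind = TRUE)
  act <- score[idx]
  ex <- expr[idx]
  label <- ifelse(ex > expr_thresh,
                  ifelse(act > act_thresh, "high_expr_high_act",
                         "high_expr_low_act"),
                  ifelse(act > act_thresh, "low_expr_high_act",
                         "low_expr_low_act"))
  g <- match(colnames(score)[idx[, 2]], grid$identity)
  data.frame(tf = rownames(score)[idx[, 1]],
             stage = grid$stage[g], cell_type = grid$cell_type[g],
             label = label, activity = act, expression = ex,
             stringsAsFactors = FALSE)
}

# expression rows aligned (case-insensitively) onto the activity layout
aligned_expression <- function(score, mean_expr) {
  rows <- match(tolower(rownames(score)), tolower(rownames(mean_expr)))
  cols <- match(colnames(score), colnames(mean_expr))
  if (anyNA(cols)) stop("expression matrix lacks identity column(s)")
  expr <- matrix(NA_real_, nrow = nrow(score), ncol = ncol(score),
                 dimnames = dimnames(score))
  has <- !is.na(rows)
  expr[has, ] <- mean_expr[rows[has], cols, drop = FALSE]
  expr
}

#' TFs with stage-continuous activity in one cell type
#'
#' Within a cell type present at two or more stages, returns the TFs whose
#' mean expression is above zero and whose activity stays strictly positive
#' (`positive` list) or strictly negative (`negative` list) at every stage
#' where the cell type exists; a masked entry or an activity of exactly zero
#' at any stage disqualifies a TF from both lists.
#'
#' @param activity An `ActivityMatrix`.
#' @param mean_expr Genes x identities expression matrix.
#' @param grid Identity grid.
#' @param cell_type Cell-type label to scan.
#' @return List with character vectors `positive` and `negative`.
#' @export
continuous_patterns <- function(activity, mean_expr, grid, cell_type) {
  stopifnot(inherits(activity, "ActivityMatrix"))
  ids <- grid$identity[grid$cell_type == cell_type]
  if (!length(ids)) stop("unknown cell type: ", cell_type)
  if (length(ids) < 2) stop("cell type present at fewer than 2 stages")
  score <- activity$score[, ids, drop = FALSE]
  expr <- aligned_expression(activity$score, mean_expr)[, ids, drop = FALSE]
  ok_expr <- rowSums(is.na(expr) | expr <= 0) == 0
  usable <- rowSums(is.na(score)) == 0 & ok_expr
  list(
    positive = rownames(score)[usable & rowSums(score > 0) == length(ids)],
    negative = rownames(score)[usable & rowSums(score < 0) == length(ids)]
  )
}

#' TFs exclusively active in one cell type at a stage
#'
#' A TF is exclusive in cell type `c` at a stage when its activity is
#' strictly positive in `c` and non-positive (<= 0) in every other cell type
#' present at that stage; at most one focal cell type per TF can satisfy
#' this. Masked entries in neighbours are ignored (the comparison runs over
#' the available scores); a masked focal entry never qualifies.
#'
#' @param activity An `ActivityMatrix`.
#' @param grid Identity grid.
#' @param stage Stage with at least two cell types.
#' @return Data.frame of pattern records: `tf`, `stage`, `cell_type`,
#'   `label` (`"exclusive"`), `support` (JSON-encoded named score list).
#' @export
exclusive_active <- function(activity, grid, stage) {
  score <- stage_scores(activity, grid, stage)
  pos <- !is.na(score) & score > 0
  nonpos <- is.na(score) | score <= 0
  focal_count <- rowSums(pos)
  hit <- focal_count == 1 & rowSums(nonpos) == ncol(score) - 1
  pattern_records(score, hit, pos, "exclusive", stage)
}

#' TFs with gradient activity in one cell type at a stage
#'
#' A TF is gradient-active in cell type `c` when its activity exceeds `high`
#' in `c` while every other cell type present at the stage stays inside the
#' closed intermediate band `[low, high]`. Masked neighbours are ignored.
#'
#' @inheritParams exclusive_active
#' @param high Strict threshold for the focal cell type (default 1).
#' @param low Lower bound of the neighbours' intermediate band (default 0).
#' @return Data.frame of `"gradient"` pattern records.
#' @export
gradient_active <- function(activity, grid, stage, high = 1, low = 0) {
  score <- stage_scores(activity, grid, stage)
  focal <- !is.na(score) & score > high
  mid <- is.na(score) | (score >= low & score <= high)
  hit <- rowSums(focal) == 1 & rowSums(mid) == ncol(score) - 1
  pattern_records(score, hit, focal, "gradient", stage)
}

stage_scores <- function(activity, grid, stage) {
  stopifnot(inherits(activity, "ActivityMatrix"))
  ids <- grid$identity[grid$stage == stage]
  if (length(ids) < 2) stop("stage ", stage, " has fewer than 2 cell types")
  score <- activity$score[, ids, drop = FALSE]
  colnames(score) <- grid$cell_type[match(ids, grid$identity)]
  score
}

pattern_records <- function(score, hit, focal, label, stage) {
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) {
    return(data.frame(tf = character(), stage = character(),
                      cell_type = character(), label = character(),
                      support = character(), stringsAsFactors = FALSE))
  }
  rows <- which(hit)
  data.frame(
    tf = rownames(score)[rows],
    stage = stage,
    cell_type = colnames(score)[apply(focal[rows, , drop = FALSE], 1, which)],
    label = label,
    support = apply(score[rows, , drop = FALSE], 1, function(v) {
      jsonlite::toJSON(as.list(v), auto_unbox = TRUE, digits = NA)
    }),
    stringsAsFactors = FALSE
  )
}

#' Top and bottom k TFs per stage by cell-type-averaged activity
#'
#' Averages each TF's scores over the cell types present at a stage (masked
#' entries excluded from the mean), then takes the k highest and k lowest
#' averages. Ties break by TF symbol so the selection is deterministic. If
#' fewer than k TFs are scored at a stage, all are returned with a warning.
#'
#' @param activity An `ActivityMatrix`.
#' @param grid Identity grid.
#' @param k Number of TFs per list (default 5).
#' @return Data.frame with `tf`, `stage`, `label` (`"top_k"` / `"bottom_k"`),
#'   `mean_score`.
#' @export
top_bottom_by_stage <- function(activity, grid, k = 5) {
  stopifnot(inherits(activity, "ActivityMatrix"))
  out <- lapply(attr(grid, "stage_order"), function(st) {
    ids <- grid$identity[grid$stage == st]
    if (!length(ids)) return(NULL)
    score <- activity$score[, ids, drop = FALSE]
    avg <- rowMeans(score, na.rm = TRUE)
    avg <- avg[!is.nan(avg)]
    if (!length(avg)) return(NULL)
    kk <- k
    if (length(avg) < k) {
      warning("stage ", st, ": only ", length(avg), " scored TFs (k = ", k, ")")
      kk <- length(avg)
    }
    ord <- order(-avg, names(avg))
    top <- ord[seq_len(kk)]
    ord_b <- order(avg, names(avg))
    bottom <- ord_b[seq_len(kk)]
    rbind(
      data.frame(tf = names(avg)[top], stage = st, label = "top_k",
                 mean_score = unname(avg[top]), stringsAsFactors = FALSE),
      data.frame(tf = names(avg)[bottom], stage = st, label = "bottom_k",
                 mean_score = unname(avg[bottom]), stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Order selected TFs by mean expression over a set of identities
#'
#' @param selected Character vector of TF symbols.
#' @param mean_expr Genes x identities expression matrix.
#' @param identities Identity labels defining the scope (default: all
#'   columns).
#' @return `selected` reordered by descending mean expression, ties broken
#'   by symbol.
#' @export
rank_by_expression <- function(selected, mean_expr,
                               identities = colnames(mean_expr)) {
  rows <- match(tolower(selected), tolower(rownames(mean_expr)))
  if (anyNA(rows)) {
    stop("selected TF(s) absent from expression matrix: ",
         paste(selected[is.na(rows)], collapse = ", "))
  }
  avg <- rowMeans(mean_expr[rows, identities, drop = FALSE])
  selected[order(-avg, selected)]
}

#' Gene-set over-representation by one-sided Fisher exact test
#'
#' Tests each set of the collection for enrichment of the selected genes on
#' the 2x2 membership table against the collection's universe, one-sided in
#' the enrichment direction, with Benjamini-Hochberg adjustment across sets.
#'
#' @param selected Non-empty character vector, a subset of the universe.
#' @param collection List with `sets` (named list of character vectors) and
#'   `universe` (character vector), e.g. from [read_gmt()].
#' @return Data.frame: `set`, `n_set`, `n_overlap`, `odds_ratio`, `p_value`,
#'   `p_adj`.
#' @export
enrich_gene_sets <- function(selected, collection) {
  if (!length(selected)) stop("empty selection")
  universe <- unique(collection$universe)
  selected <- unique(selected)
  if (length(setdiff(selected, universe))) {
    stop("selected genes outside the universe")
  }
  res <- lapply(names(collection$sets), function(nm) {
    set <- intersect(unique(collection$sets[[nm]]), universe)
    a <- length(intersect(set, selected))
    b <- length(setdiff(set, selected))
    c_ <- length(setdiff(selected, set))
    d <- length(universe) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                             alternative = "greater")
    data.frame(set = nm, n_set = length(set), n_overlap = a,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Read a gene-set collection from GMT text
#'
#' One set per line: name, description, then member genes, tab-separated.
#' The universe defaults to the union of all sets unless given.
#'
#' @param path GMT file.
#' @param universe Optional character vector overriding the default universe.
#' @return List with `sets` and `universe`, for [enrich_gene_sets()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (is.null(universe)) universe <- unique(unlist(sets))
  list(sets = sets, universe = universe)
}
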