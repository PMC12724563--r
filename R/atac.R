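#' Read genomic intervals from BED
#'
#' Thin wrapper over `rtracklayer::import.bed()`; returns a `GRanges` (the
#' package's interval container; BED's 0-based half-open coordinates are
#' converted to the 1-based closed convention on read). Strand is carried
#' but ignored by all overlap operations here.
#'
#' @param path BED file (3+ columns).
#' @return A [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read motif occurrences from GFF
#'
#' Imports a GFF of motif hits (e.g. a motif scanner's output) and attaches a
#' `tf` metadata column taken from the attribute named by `tf_attribute`
#' (default `motif_id`), optionally renamed through a two-column alias table
#' (`from`, `to`) mapping motif identifiers to TF symbols.
#'
#' @param path GFF file.
#' @param tf_attribute Attribute key holding the motif / TF identifier.
#' @param alias Optional data.frame with columns `from`, `to`.
#' @return A `GRanges` with a `tf` metadata column.
#' @export
read_motif_gff <- function(path, tf_attribute = "motif_id", alias = NULL) {
  gr <- rtracklayer::import(path)
  meta <- S4Vectors::mcols(gr)
  if (!tf_attribute %in% names(meta)) {
    stop("GFF attribute '", tf_attribute, "' not found; available: ",
         paste(names(meta), collapse = ", "))
  }
  tf <- as.character(meta[[tf_attribute]])
  if (!is.null(alias)) {
    hit <- match(tf, alias$from)
    tf[!is.na(hit)] <- alias$to[hit[!is.na(hit)]]
  }
  S4Vectors::mcols(gr)$tf <- tf
  gr
}

#' Intervals of `a` overlapping `b` by at least `min_overlap` bases
#'
#' Keeps the members of `a` that overlap any member of `b` on the same
#' chromosome by `min_overlap` or more bases, preserving the order of `a`
#' and never duplicating entries. Strand is ignored.
#'
#' @param a,b `GRanges` objects.
#' @param min_overlap Minimum overlap width in bases (default 5).
#' @return The qualifying subset of `a`.
#' @export
intersect_min_overlap <- function(a, b, min_overlap = 5) {
  stopifnot(min_overlap >= 1)
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  a[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Count fragments overlapping each interval
#'
#' @param fragments `GRanges` of sequenced fragments.
#' @param intervals `GRanges` of target intervals (e.g. motif occurrences).
#' @param min_overlap Minimum overlap in bases for a fragment to count
#'   (default 1).
#' @return Integer vector of per-interval fragment counts.
#' @export
count_reads_per_interval <- function(fragments, intervals, min_overlap = 1) {
  GenomicRanges::countOverlaps(intervals, fragments,
                               minoverlap = min_overlap,
                               ignore.strand = TRUE)
}

#' Build a per-TF motif occurrence table with read counts
#'
#' Restricts motif occurrences to open-chromatin peaks (overlap of at least
#' `min_overlap` bases, mirroring an interval intersection at a 5 bp cutoff)
#' and counts overlapping fragments per surviving occurrence.
#'
#' @param motifs `GRanges` with a `tf` metadata column
#'   (see [read_motif_gff()]).
#' @param peaks `GRanges` of accessible peaks.
#' @param fragments `GRanges` of ATAC fragments.
#' @param min_overlap Minimum motif/peak overlap in bases (default 5).
#' @return Data.frame: `tf`, `chrom`, `start`, `end`, `read_count` (one row
#'   per retained occurrence).
#' @export
motif_occurrence_table <- function(motifs, peaks, fragments, min_overlap = 5) {
  kept <- intersect_min_overlap(motifs, peaks, min_overlap = min_overlap)
  reads <- count_reads_per_interval(fragments, kept)
  data.frame(
    tf = S4Vectors::mcols(kept)$tf,
    chrom = as.character(GenomicRanges::seqnames(kept)),
    start = GenomicRanges::start(kept), end = GenomicRanges::end(kept),
    read_count = as.integer(reads),
    stringsAsFactors = FALSE
  )
}

#' Motif-occupancy summary statistics for one TF
#'
#' Four statistics over a TF's motif occurrences: the number of occurrences;
#' the summed reads over occurrences with strictly more than `read_threshold`
#' reads; the maximum read count; and the mean of the `top_k` largest read
#' counts (all counts when fewer than `top_k` occurrences exist). An empty
#' table reports zero occurrences and missing values for the rest.
#'
#' @param read_counts Integer vector of per-occurrence read counts.
#' @param read_threshold Strict lower bound for the sum statistic
#'   (default 99).
#' @param top_k Number of highest peaks averaged (default 5).
#' @return One-row data.frame: `n_occurrences`, `sum_reads_over_threshold`,
#'   `max_reads`, `mean_top_k`.
#' @export
occupancy_summary <- function(read_counts, read_threshold = 99, top_k = 5) {
  if (!length(read_counts)) {
    return(data.frame(n_occurrences = 0L,
                      sum_reads_over_threshold = NA_real_,
                      max_reads = NA_real_, mean_top_k = NA_real_))
  }
  stopifnot(all(read_counts >= 0))
  srt <- sort(read_counts, decreasing = TRUE)
  data.frame(
    n_occurrences = length(read_counts),
    sum_reads_over_threshold = sum(read_counts[read_counts > read_threshold]),
    max_reads = max(read_counts),
    mean_top_k = mean(srt[seq_len(min(top_k, length(srt)))])
  )
}

#' Occupancy summaries for every TF of an occurrence table
#'
#' @param table Data.frame with columns `tf` and `read_count`
#'   (see [motif_occurrence_table()] or [generate_atac()]).
#' @inheritParams occupancy_summary
#' @return Data.frame with one row per TF, columns as in
#'   [occupancy_summary()] plus `tf`.
#' @export
occupancy_summaries <- function(table, read_threshold = 99, top_k = 5) {
  out <- lapply(split(table$read_count, table$tf), occupancy_summary,
                read_threshold = read_threshold, top_k = top_k)
  res <- do.call(rbind, out)
  res <- cbind(tf = names(out), res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Contrast occupancy statistics between activity-sign groups
#'
#' Two-sided Mann-Whitney rank-sum test ([rank_sum_test()]) on each of the
#' four occupancy statistics between TFs with positive and TFs with negative
#' inferred activity. The choice of test is this package's; the comparison
#' asks whether motif accessibility differs between the sign groups at all.
#'
#' @param summaries Data.frame from [occupancy_summaries()].
#' @param positive_tfs,negative_tfs Disjoint character vectors of TF symbols.
#' @return Data.frame: `statistic_name`, `u`, `p_value`, `n_positive`,
#'   `n_negative`.
#' @export
compare_activity_groups <- function(summaries, positive_tfs, negative_tfs) {
  if (length(intersect(positive_tfs, negative_tfs))) {
    stop("positive and negative TF groups overlap")
  }
  stats_cols <- c("n_occurrences", "sum_reads_over_threshold",
                  "max_reads", "mean_top_k")
  pos <- summaries[summaries$tf %in% positive_tfs, , drop = FALSE]
  neg <- summaries[summaries$tf %in% negative_tfs, , drop = FALSE]
  if (!nrow(pos) || !nrow(neg)) stop("both groups must be non-empty")
  out <- lapply(stats_cols, function(sc) {
    xp <- pos[[sc]][!is.na(pos[[sc]])]
    xn <- neg[[sc]][!is.na(neg[[sc]])]
    ts <- rank_sum_test(xp, xn)
    data.frame(statistic_name = sc, u = ts$statistic, p_value = ts$p_value,
               n_positive = length(xp), n_negative = length(xn),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
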