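# Independent oracles coded separately from the package internals.

# Two-sided rank-sum p by exhaustive enumeration of group labelings.
# Works with ties via mid-ranks; deviations measured from the null mean.
oracle_rank_sum_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - length(idx) * (length(idx) + 1) / 2
  mu <- n1 * (n - n1) / 2
  obs_dev <- abs(u_of(seq_len(n1)) - mu)
  sets <- utils::combn(n, n1)
  devs <- apply(sets, 2, function(idx) abs(u_of(idx) - mu))
  mean(devs >= obs_dev - 1e-9)
}

# Least-squares slope t-statistic through R's own linear-model fitter.
oracle_ols_t <- function(x, y) {
  unname(summary(stats::lm(y ~ x))$coefficients["x", "t value"])
}

# O(n*m) interval scan; intervals given 1-based closed as in GRanges.
oracle_overlap_width <- function(s1, e1, s2, e2) {
  pmin(e1, e2) - pmax(s1, s2) + 1
}

oracle_intersect_keep <- function(a_df, b_df, min_overlap) {
  keep <- logical(nrow(a_df))
  for (i in seq_len(nrow(a_df))) {
    for (j in seq_len(nrow(b_df))) {
      if (a_df$chrom[i] == b_df$chrom[j] &&
          oracle_overlap_width(a_df$start[i], a_df$end[i],
                               b_df$start[j], b_df$end[j]) >= min_overlap) {
        keep[i] <- TRUE
        break
      }
    }
  }
  keep
}

oracle_count_overlaps <- function(frag_df, int_df, min_overlap) {
  out <- integer(nrow(int_df))
  for (i in seq_len(nrow(int_df))) {
    for (j in seq_len(nrow(frag_df))) {
      if (int_df$chrom[i] == frag_df$chrom[j] &&
          oracle_overlap_width(int_df$start[i], int_df$end[i],
                               frag_df$start[j], frag_df$end[j]) >=
          min_overlap) {
        out[i] <- out[i] + 1L
      }
    }
  }
  out
}

# One-sided enrichment p as an explicit hypergeometric tail sum.
oracle_hyper_p <- function(overlap, set_size, selected_size, universe_size) {
  ks <- overlap:min(set_size, selected_size)
  sum(choose(set_size, ks) *
        choose(universe_size - set_size, selected_size - ks)) /
    choose(universe_size, selected_size)
}

# Step-up BH from the formula, without p.adjust.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Trimean via hand-rolled type-7 interpolation.
oracle_trimean <- function(v) {
  s <- sort(v)
  n <- length(s)
  qat <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
  }
  (qat(0.25) + 2 * qat(0.5) + qat(0.75)) / 4
}

granges_from_df <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1000,
                             max_width = 50) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE) - 1L,
             stringsAsFactors = FALSE)
}
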