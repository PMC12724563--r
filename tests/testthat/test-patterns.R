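two_stage_grid <- function() {
  make_grid(rep(c("HH5", "HH11"), each = 2), rep(c("a", "b"), 2),
            stage_order = c("HH5", "HH11"))
}

test_that("quadrant labels follow the strict 0 / 1 thresholds", {
  score <- matrix(c(1.5, -0.5, 0.4, 0), nrow = 4,
                  dimnames = list(paste0("TF", 1:4), "HH5|a"))
  expr <- matrix(c(2, 2, 0.5, 1), nrow = 4,
                 dimnames = list(paste0("TF", 1:4), "HH5|a"))
  grid <- make_grid("HH5", "a")
  q <- quadrant_classify(fake_activity(score), expr, grid)
  got <- setNames(q$label, q$tf)
  expect_equal(got[["TF1"]], "high_expr_high_act")
  expect_equal(got[["TF2"]], "high_expr_low_act")
  expect_equal(got[["TF3"]], "low_expr_high_act")
  # exactly on both boundaries falls in the low/low class
  expect_equal(got[["TF4"]], "low_expr_low_act")
})

test_that("quadrant labels partition the unmasked entries", {
  set.seed(30)
  grid <- two_stage_grid()
  score <- matrix(rnorm(6 * 4), nrow = 6,
                  dimnames = list(paste0("TF", 1:6), grid$identity))
  score[sample(length(score), 5)] <- NA
  expr <- matrix(runif(6 * 4, 0, 2), nrow = 6, dimnames = dimnames(score))
  q <- quadrant_classify(fake_activity(score), expr, grid)
  expect_equal(nrow(q), sum(!is.na(score)))
  expect_equal(sum(table(q$label)), sum(!is.na(score)))
})

test_that("continuous activity requires a constant sign at every stage", {
  grid <- make_grid(rep(default_stage_order(), 2),
                    rep(c("a", "b"), each = 5),
                    stage_order = default_stage_order())
  ids_a <- grid$identity[grid$cell_type == "a"]
  score <- matrix(0.1, nrow = 3, ncol = nrow(grid),
                  dimnames = list(c("TFpos", "TFdip", "TFneg"),
                                  grid$identity))
  score["TFpos", ids_a] <- c(0.5, 1.2, 0.3, 0.8, 0.2)
  score["TFdip", ids_a] <- c(0.5, 1.2, -0.1, 0.8, 0.2)
  score["TFneg", ids_a] <- -c(0.5, 1.2, 0.3, 0.8, 0.2)
  expr <- score * 0 + 1
  out <- continuous_patterns(fake_activity(score), expr, grid, "a")
  expect_equal(out$positive, "TFpos")
  expect_equal(out$negative, "TFneg")
  expect_error(continuous_patterns(fake_activity(score), expr, grid, "zz"),
               "unknown cell type")

  # expression gate: a single non-expressed stage disqualifies
  expr2 <- expr
  expr2["TFpos", "HH5|a"] <- 0
  out2 <- continuous_patterns(fake_activity(score), expr2, grid, "a")
  expect_equal(out2$positive, character())

  # random matrices equal the brute-force all-stages scan
  set.seed(31)
  for (i in 1:10) {
    sc <- matrix(rnorm(40, sd = 1), nrow = 4,
                 dimnames = list(paste0("T", 1:4), grid$identity))
    ex <- matrix(sample(c(0, 1), 40, replace = TRUE), nrow = 4,
                 dimnames = dimnames(sc))
    res <- continuous_patterns(fake_activity(sc), ex, grid, "b")
    ids <- grid$identity[grid$cell_type == "b"]
    brute_pos <- rownames(sc)[apply(sc[, ids] > 0 & ex[, ids] > 0, 1, all)]
    brute_neg <- rownames(sc)[apply(sc[, ids] < 0 & ex[, ids] > 0, 1, all)]
    expect_equal(res$positive, brute_pos)
    expect_equal(res$negative, brute_neg)
  }
})

test_that("exclusive activity needs one positive and non-positive neighbours", {
  grid <- make_grid(rep("HH9_7som", 4), letters[1:4],
                    stage_order = "HH9_7som")
  sc <- rbind(TFx = c(0.8, -0.2, -0.1, 0),
              TFn = c(0.8, 0.2, -0.1, 0))
  colnames(sc) <- grid$identity
  ex <- exclusive_active(fake_activity(sc), grid, "HH9_7som")
  expect_equal(ex$tf, "TFx")
  expect_equal(ex$cell_type, "a")
  # support is reproducible back into the stored scores
  expect_equal(unlist(jsonlite::fromJSON(ex$support)),
               c(a = 0.8, b = -0.2, c = -0.1, d = 0))

  set.seed(32)
  for (i in 1:20) {
    sc <- matrix(rnorm(5 * 4), nrow = 5,
                 dimnames = list(paste0("T", 1:5), grid$identity))
    got <- exclusive_active(fake_activity(sc), grid, "HH9_7som")
    for (r in 1:5) {
      pos <- which(sc[r, ] > 0)
      is_excl <- length(pos) == 1 && all(sc[r, -pos] <= 0)
      expect_equal(paste0("T", r) %in% got$tf, is_excl)
    }
    expect_lte(max(table(factor(got$tf, levels = paste0("T", 1:5)))), 1)
  }
})

test_that("gradient activity needs one high and an intermediate band", {
  grid <- make_grid(rep("HH5", 4), letters[1:4])
  sc <- rbind(TFg = c(1.2, 0.5, 0.9, 0.1),
              TFtwo = c(1.2, 1.1, 0.5, 0.3))
  colnames(sc) <- grid$identity
  gr <- gradient_active(fake_activity(sc), grid, "HH5")
  expect_equal(gr$tf, "TFg")
  expect_equal(gr$cell_type, "a")

  # exclusive and gradient can only co-occur with all-zero neighbours
  set.seed(33)
  for (i in 1:50) {
    row <- matrix(round(rnorm(4, 0.5, 1), 2), nrow = 1,
                  dimnames = list("T1", grid$identity))
    both <- nrow(exclusive_active(fake_activity(row), grid, "HH5")) > 0 &&
      nrow(gradient_active(fake_activity(row), grid, "HH5")) > 0
    if (both) {
      focal <- which.max(row)
      expect_true(all(row[-focal] == 0))
    }
  }
  zero_nb <- matrix(c(1.5, 0, 0, 0), nrow = 1,
                    dimnames = list("T1", grid$identity))
  expect_equal(nrow(exclusive_active(fake_activity(zero_nb), grid, "HH5")), 1)
  expect_equal(nrow(gradient_active(fake_activity(zero_nb), grid, "HH5")), 1)
})

test_that("stage top/bottom lists sort by cell-type-averaged score", {
  grid <- make_grid(rep("HH5", 2), c("a", "b"))
  sc <- matrix(rep(c(3, 2, 1, 0, -1, -2), 2), nrow = 6,
               dimnames = list(paste0("TF", 1:6), grid$identity))
  tb <- top_bottom_by_stage(fake_activity(sc), grid, k = 2)
  expect_setequal(tb$tf[tb$label == "top_k"], c("TF1", "TF2"))
  expect_setequal(tb$tf[tb$label == "bottom_k"], c("TF6", "TF5"))
  # k = all TFs covers everything
  tb_all <- top_bottom_by_stage(fake_activity(sc), grid, k = 6)
  expect_setequal(unique(tb_all$tf), paste0("TF", 1:6))
  # random matrices match a sort oracle, masked entries excluded
  set.seed(34)
  for (i in 1:10) {
    s <- matrix(rnorm(12), nrow = 6, dimnames = dimnames(sc))
    s[sample(12, 2)] <- NA
    tb <- top_bottom_by_stage(fake_activity(s), grid, k = 3)
    avg <- rowMeans(s, na.rm = TRUE)
    avg <- avg[!is.nan(avg)]
    expect_equal(tb$tf[tb$label == "top_k"],
                 names(avg)[order(-avg, names(avg))][1:3])
  }
  expect_warning(top_bottom_by_stage(fake_activity(sc), grid, k = 10),
                 "only 6")
})

test_that("expression ranking is descending with symbol tie-break", {
  expr <- matrix(c(0.2, 5, 1), nrow = 3,
                 dimnames = list(c("TFa", "TFb", "TFc"), "HH5|a"))
  expect_equal(rank_by_expression(c("TFa", "TFb", "TFc"), expr),
               c("TFb", "TFc", "TFa"))
  expect_equal(rank_by_expression("TFb", expr), "TFb")
  set.seed(35)
  e <- matrix(runif(20), nrow = 10,
              dimnames = list(paste0("T", sprintf("%02d", 1:10)),
                              c("HH5|a", "HH5|b")))
  sel <- sample(rownames(e), 6)
  got <- rank_by_expression(sel, e)
  avg <- rowMeans(e)[sel]
  expect_equal(got, sel[order(-avg, sel)])
})

test_that("enrichment equals the hypergeometric tail", {
  coll <- list(sets = list(s1 = c("g1", "g2")),
               universe = paste0("g", 1:4))
  res <- enrich_gene_sets(c("g1", "g2"), coll)
  expect_equal(res$p_value, 1 / 6)
  # degenerate table
  coll2 <- list(sets = list(s1 = character()), universe = paste0("g", 1:4))
  expect_equal(enrich_gene_sets("g1", coll2)$p_value, 1)
  expect_error(enrich_gene_sets(character(), coll), "empty")
  expect_error(enrich_gene_sets("zz", coll), "outside the universe")

  set.seed(36)
  for (i in 1:20) {
    universe <- paste0("g", 1:12)
    set <- sample(universe, sample(1:8, 1))
    sel <- sample(universe, sample(1:8, 1))
    res <- enrich_gene_sets(sel, list(sets = list(s = set),
                                      universe = universe))
    expect_equal(res$p_value,
                 oracle_hyper_p(length(intersect(set, sel)), length(set),
                                length(sel), 12),
                 tolerance = 1e-12)
  }
})

test_that("GMT collections read as named sets over a union universe", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg3\tg4"), path)
  coll <- read_gmt(path)
  expect_equal(names(coll$sets), c("setA", "setB"))
  expect_setequal(coll$universe, paste0("g", 1:4))
  expect_equal(coll$sets$setB, c("g3", "g4"))
})
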