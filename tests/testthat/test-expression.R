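test_that("normalisation scales cells to a fixed total and log-transforms", {
  counts <- matrix(c(1, 0, 3, 2, 4, 0), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  sce <- normalize_expression(expression_matrix(counts), scale_total = 10)
  # spreadsheet-style oracle: per-cell totals 4 and 6
  expected <- log1p(cbind(c1 = c(1, 0, 3) / 4 * 10, c2 = c(2, 4, 0) / 6 * 10))
  rownames(expected) <- rownames(counts)
  expect_equal(SummarizedExperiment::assay(sce, "logcounts"), expected)

  # a cell expressing a single gene ends at log(1 + scale_total)
  one <- matrix(c(7, 0), nrow = 2, dimnames = list(c("a", "b"), "c1"))
  n1 <- normalize_expression(expression_matrix(one), scale_total = 100)
  expect_equal(SummarizedExperiment::assay(n1, "logcounts")["a", "c1"],
               log(1 + 100))

  zero <- matrix(c(0, 0), nrow = 2, dimnames = list(c("a", "b"), "cellX"))
  expect_error(normalize_expression(expression_matrix(zero)), "cellX")
})

test_that("expression matrix validates ids, values and metadata", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g1"), c("c1", "c2")))
  expect_error(expression_matrix(m), "duplicate gene")
  m2 <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("c1", "c1")))
  expect_error(expression_matrix(m2), "duplicate cell")
  m3 <- matrix(c(-1, 1, 1, 1), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(expression_matrix(m3), "non-negative")
  m4 <- matrix(c(0.5, 1, 1, 1), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  expect_error(expression_matrix(m4), "integer")
  expect_silent(expression_matrix(m4, normalized = TRUE))
  expect_error(
    expression_matrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("c1", "c2"))),
                      data.frame(pseudotime = c(0.5, 1.2),
                                 row.names = c("c1", "c2"))),
    "pseudotime")
})

test_that("fibroblast marker score is a mean z-score with threshold mask", {
  # all cells identical -> all scores zero
  m <- matrix(2L, 3, 4, dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  sce <- normalize_expression(expression_matrix(m))
  fs <- fibroblast_score(sce, c("g1", "g2"))
  expect_equal(fs$score, rep(0, 4))

  # one clearly high cell passes a threshold of 1, the rest do not
  m2 <- matrix(1L, 2, 5, dimnames = list(c("g1", "g2"), paste0("c", 1:5)))
  m2[, 5] <- 50L
  sce2 <- expression_matrix(log1p(m2), normalized = TRUE)
  fs2 <- fibroblast_score(sce2, c("g1", "g2"), threshold = 1)
  expect_equal(fs2$is_fibroblast, c(rep(FALSE, 4), TRUE))

  expect_error(fibroblast_score(sce, c("nope1", "nope2")), "marker")
  expect_warning(fibroblast_score(sce, c("g1", "missing")), "missing")
})

test_that("fibroblast classifier recovers planted fibroblasts", {
  b <- simulate_expression_cohort(cohort_sim_config(
    n_datasets = 1, n_cells_per_group = 120, n_other_cells = 80, seed = 11))
  sce <- normalize_expression(b$matrices[[1]])
  fs <- fibroblast_score(sce, fibroblast_marker_panel())
  truth <- SummarizedExperiment::colData(sce)$is_fibroblast
  recall <- sum(fs$is_fibroblast & truth) / sum(truth)
  precision <- sum(fs$is_fibroblast & truth) / sum(fs$is_fibroblast)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("rank-sum test matches exhaustive enumeration and wilcox.test", {
  # no ties, small: exact path must equal the enumeration oracle exactly
  set.seed(42)
  for (rep in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- rnorm(n1); b <- rnorm(n2)
    ts <- rank_sum_test(a, b)
    expect_equal(ts$method, if (n1 * n2 <= 64) "exact" else "normal")
    if (ts$method == "exact")
      expect_equal(ts$p, enum_ranksum_p(a, b), tolerance = 1e-12)
    # cross-check U and p against the standard implementation
    w <- suppressWarnings(stats::wilcox.test(a, b))
    expect_equal(ts$U, unname(w$statistic))
    expect_equal(ts$p, w$p.value, tolerance = 1e-10)
  }
  # with ties / larger n: normal approximation within 0.02 of enumeration
  for (rep in 1:10) {
    a <- sample(1:5, 8, replace = TRUE)
    b <- sample(1:5, 8, replace = TRUE)
    ts <- rank_sum_test(a, b)
    expect_lt(abs(ts$p - enum_ranksum_p(a, b)), 0.02)
  }
  # n1 = n2 = 9 exceeds the exact switch: still close to full enumeration
  a <- rnorm(9); b <- rnorm(9) + 0.5
  ts <- rank_sum_test(a, b)
  expect_equal(ts$method, "normal")
  expect_lt(abs(ts$p - enum_ranksum_p(a, b)), 0.02)
})

test_that("rank-sum handles degenerate and directed cases", {
  expect_equal(rank_sum_test(c(3, 3, 3), c(3, 3, 3))$p, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
  # a = [1,2], b = [3,4]: U = 0; exhaustive two-sided p = 2 * 1/6
  ts <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(ts$U, 0)
  expect_equal(ts$p, 2 / 6)
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), "less")$p, 1 / 6)
  g <- rank_sum_test(c(3, 4), c(1, 2), "greater")
  expect_equal(g$U, 4)
  expect_equal(g$p, 1 / 6)
})

test_that("differential TF screen calls planted TFs and validates inputs", {
  b <- simulate_expression_cohort(cohort_sim_config(n_datasets = 1, seed = 3))
  sce <- normalize_expression(b$matrices[[1]])
  universe <- c(b$truth$common_up_tfs, b$truth$private_up_tfs[[1]],
                paste0("TF", 10:20))
  de <- differential_tfs(sce, universe)
  expect_true(all(c("HIF1A", "PRRX1") %in% de$up))
  expect_true(all(b$truth$private_up_tfs[[1]] %in% de$up))
  expect_true(all(de$table$p >= 0 & de$table$p <= 1))
  expect_true(all(de$table$p_adj >= de$table$p))
  n1 <- sum(SummarizedExperiment::colData(sce)$group %in% "CAF")
  n2 <- sum(SummarizedExperiment::colData(sce)$group %in% "NF")
  expect_true(all(de$table$U >= 0 & de$table$U <= n1 * n2))

  expect_error(differential_tfs(sce, c("NOT1", "NOT2")), "overlap")
  few <- sce[, c(which(SummarizedExperiment::colData(sce)$group %in% "NF")[1:2],
                 which(SummarizedExperiment::colData(sce)$group %in% "CAF"))]
  expect_error(differential_tfs(few, universe), "NF")
})

test_that("common up-set intersection is exact, commutative and monotone", {
  s <- list(c("A", "B", "C"), c("A", "B"), c("A", "B", "D"))
  expect_equal(common_upregulated(s), c("A", "B"))
  expect_equal(common_upregulated(rev(s)), c("A", "B"))
  expect_equal(common_upregulated(c(s, list(character(0)))), character(0))
  expect_error(common_upregulated(s[1]), "at least 2")
  # monotone non-increasing as sets are added
  set.seed(1)
  pool <- LETTERS
  sets <- replicate(6, sample(pool, 15), simplify = FALSE)
  prev <- common_upregulated(sets[1:2])
  for (k in 3:6) {
    cur <- common_upregulated(sets[1:k])
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # idempotent
  expect_equal(common_upregulated(list(prev, prev)), prev)
})

test_that("expressing fraction counts detection per group", {
  counts <- matrix(0L, 1, 10, dimnames = list("HIF1A", paste0("c", 1:10)))
  counts[1, 1:3] <- 5L
  sce <- toy_sce(counts, group = rep(c("CAF", "NF"), each = 5))
  fr <- expressing_fraction(sce, "HIF1A")
  expect_equal(unname(fr["CAF"]), 3 / 5)
  expect_equal(unname(fr["NF"]), 0)
  zero <- toy_sce(matrix(0L, 1, 4, dimnames = list("g", paste0("c", 1:4))),
                  group = rep(c("CAF", "NF"), 2))
  expect_equal(unname(expressing_fraction(zero, "g")), c(0, 0))
  expect_error(expressing_fraction(sce, "ABSENT"), "ABSENT")
})

test_that("expressing fraction estimates planted detection rates", {
  set.seed(5)
  n <- 500
  counts <- matrix(0L, 2, 2 * n)
  counts[1, ] <- c(rbinom(n, 1, 0.6), rbinom(n, 1, 0.2)) * 3L
  counts[2, ] <- 1L   # keeps libraries non-zero
  dimnames(counts) <- list(c("HIF1A", "ref"), paste0("c", 1:(2 * n)))
  sce <- toy_sce(counts, group = rep(c("CAF", "NF"), each = n))
  fr <- expressing_fraction(sce, "HIF1A")
  expect_lt(abs(fr[["CAF"]] - 0.6), 0.05)
  expect_lt(abs(fr[["NF"]] - 0.2), 0.05)
})

test_that("pseudotime correlation returns Fisher-z CI and detects exact linearity", {
  pt <- seq(0, 1, length.out = 20)
  vals <- matrix(2 * pt + 1, 1, 20,
                 dimnames = list("g", paste0("c", 1:20)))
  sce <- expression_matrix(vals, data.frame(pseudotime = pt,
                                            row.names = colnames(vals)),
                           normalized = TRUE)
  pc <- pseudotime_correlation(sce, "g")
  expect_equal(pc$r, 1.0)

  cons <- expression_matrix(matrix(1, 1, 20,
                                   dimnames = dimnames(vals)),
                            data.frame(pseudotime = pt,
                                       row.names = colnames(vals)),
                            normalized = TRUE)
  expect_error(pseudotime_correlation(cons, "g"), "variance")
})

test_that("independent gene: correlation small and CI covers zero ~95% of runs", {
  set.seed(7)
  hits <- 0; small <- 0
  for (i in 1:100) {
    pt <- runif(200)
    vals <- matrix(rlnorm(200), 1, 200,
                   dimnames = list("g", paste0("c", 1:200)))
    sce <- expression_matrix(vals, data.frame(pseudotime = pt,
                                              row.names = colnames(vals)),
                             normalized = TRUE)
    pc <- pseudotime_correlation(sce, "g")
    if (pc$ci[1] <= 0 && pc$ci[2] >= 0) hits <- hits + 1
    if (abs(pc$r) < 0.2) small <- small + 1
  }
  expect_gte(hits, 89)   # ~95% coverage, binomial slack
  expect_equal(small, 100)
})
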