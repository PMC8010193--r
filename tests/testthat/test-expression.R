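toy_expr <- function(n_genes = 5, n_samples = 3, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("s%d", seq_len(n_samples))))
}

test_that("a gene set occupying the top ranks attains the maximal score", {
  # brute force over all C(5,2) placements of a 2-gene set in a 5-gene sample
  x <- matrix(c(5, 4, 3, 2, 1), ncol = 1,
              dimnames = list(sprintf("g%d", 1:5), "s1"))
  for (alpha in c(0, 0.25, 1)) {
    scores <- combn(5, 2, function(idx)
      ssgsea_score(x, sprintf("g%d", idx), alpha = alpha))
    top <- unname(ssgsea_score(x, c("g1", "g2"), alpha = alpha))
    expect_equal(max(scores), top, tolerance = 1e-12)
  }
})

test_that("scores are invariant to monotone per-sample transforms", {
  e <- toy_expr(20, 4, seed = 2)
  s1 <- ssgsea_score(e, c("g3", "g7", "g11"))
  s2 <- ssgsea_score(exp(e), c("g3", "g7", "g11"))
  e3 <- e; e3[, 2] <- e3[, 2]^3   # odd power, monotone, one sample only
  s3 <- ssgsea_score(e3, c("g3", "g7", "g11"))
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(s1, s3, tolerance = 1e-12)
})

test_that("scores are invariant to gene reordering of the matrix", {
  e <- toy_expr(15, 3, seed = 4)
  set.seed(5)
  e2 <- e[sample(nrow(e)), , drop = FALSE]
  expect_equal(ssgsea_score(e, c("g2", "g9")),
               ssgsea_score(e2, c("g2", "g9")), tolerance = 1e-12)
})

test_that("alpha = 0 equals the unweighted hand running sum on 5 genes", {
  x <- matrix(c(2.0, -1.0, 0.5, 3.0, -2.0), ncol = 1,
              dimnames = list(sprintf("g%d", 1:5), "s1"))
  # ranking desc: g4, g1, g3, g2, g5; set = {g1, g2}
  # in-set ECDF steps: 0, 1/2, 1/2, 1, 1 ; out steps: 1/3, 1/3, 2/3, 2/3, 1
  hand <- (0 - 1/3) + (1/2 - 1/3) + (1/2 - 2/3) + (1 - 2/3) + (1 - 1)
  expect_equal(unname(ssgsea_score(x, c("g1", "g2"), alpha = 0)), hand,
               tolerance = 1e-12)
})

test_that("scoring rejects degenerate gene sets", {
  e <- toy_expr(6, 2)
  expect_error(ssgsea_score(e, c("zz1", "zz2")), "no genes")
  expect_error(ssgsea_score(e, rownames(e)), "whole matrix")
  expect_error(ssgsea_score(e, "g1", alpha = -1), "alpha")
})

test_that("celltype_scores collects per-set errors without failing", {
  e <- toy_expr(30, 5, seed = 6)
  sets <- list(A = c("g1", "g2"), B = c("g5", "g9", "g12"),
               absent = c("nope1", "nope2"))
  res <- celltype_scores(e, sets)
  expect_equal(rownames(res$scores), c("A", "B"))
  expect_equal(ncol(res$scores), 5)
  expect_named(res$errors, "absent")
})

test_that("purity proxy decreases when immune genes are spiked", {
  e <- toy_expr(40, 6, seed = 7)
  immune <- c("g1", "g2", "g3")
  stromal <- c("g10", "g11", "g12")
  p0 <- purity_proxy(e, immune, stromal)
  e2 <- e
  e2[immune, 3] <- e2[immune, 3] + 10   # push immune genes to the top
  p1 <- purity_proxy(e2, immune, stromal)
  expect_lt(p1[3] - mean(p1), p0[3] - mean(p0))
  # identical samples score equally
  e3 <- cbind(e[, 1, drop = FALSE], e[, 1, drop = FALSE], e[, 2, drop = FALSE])
  colnames(e3) <- c("a", "b", "c")
  p3 <- purity_proxy(e3, immune, stromal)
  expect_equal(unname(p3["a"]), unname(p3["b"]), tolerance = 1e-12)
  expect_error(purity_proxy(e[, 1, drop = FALSE], immune, stromal),
               "two samples")
})

test_that("diff_by_group matches the textbook pooled-variance computation", {
  res <- diff_by_group(c(1, 2, 3, 4, 5, 6),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
  expect_equal(res$df, 4)

  # swap group labels: t negates, p unchanged
  swap <- diff_by_group(c(1, 2, 3, 4, 5, 6),
                        c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(swap$t, -res$t, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)

  # identical groups
  same <- diff_by_group(rep(c(1, 2), 4), rep(c(TRUE, FALSE), each = 4))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # both groups constant, different means
  expect_warning(deg <- diff_by_group(c(1, 1, 2, 2),
                                      c(TRUE, TRUE, FALSE, FALSE)), "constant")
  expect_equal(deg$p, 0)
})

test_that("genewise t equals stats::t.test on every gene", {
  e <- toy_expr(25, 12, seed = 8)
  grp <- rep(c(TRUE, FALSE), 6)
  de <- diff_expression(e, grp)
  for (g in sample(rownames(e), 8)) {
    ht <- t.test(e[g, grp], e[g, !grp], var.equal = TRUE)
    row <- de[de$gene == g, ]
    expect_equal(row$t, unname(ht$statistic), tolerance = 1e-10)
    expect_equal(row$p, ht$p.value, tolerance = 1e-10)
    expect_equal(row$log2_fc, mean(e[g, !grp]) - mean(e[g, grp]),
                 tolerance = 1e-12)
  }
  expect_true(all(de$stars %in% c("ns", "*", "**", "***")))
})

test_that("stars map the conventional significance thresholds", {
  expect_equal(stars_for_p(c(0.5, 0.04, 0.009, 0.0009)),
               c("ns", "*", "**", "***"))
})

test_that("rank_diff_genes filters, orders and truncates", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   t = c(5, -4, 1, 3),
                   p = c(0.001, 0.002, 0.5, 0.01),
                   log2_fc = c(1.2, -2.0, 0.1, 0.5),
                   stars = c("***", "**", "ns", "*"))
  top <- rank_diff_genes(de, k = 10)
  expect_equal(top$gene, c("b", "a", "d"))   # by |lfc|, c not significant
  top2 <- rank_diff_genes(de, k = 2)
  expect_equal(nrow(top2), 2)
  none <- rank_diff_genes(de[de$p > 0.4, , drop = FALSE], k = 5)
  expect_equal(nrow(none), 0)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g4"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_identical(read_gmt(f), sets)
})
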