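test_that("liebermeister_p reproduces enumerated hypergeometric tails", {
  # (3,1,1,3) positive: augmented N=10 with margins 5/5, P(X >= 4) = 26/252
  expect_equal(liebermeister_p(3, 1, 1, 3), 26 / 252, tolerance = 1e-12)
  # perfectly concordant: single-term tail 1/C(12,6)
  expect_equal(liebermeister_p(5, 0, 0, 5), 1 / choose(12, 6),
               tolerance = 1e-12)
  # perfectly discordant: complement of the symmetric case
  expect_equal(liebermeister_p(0, 5, 5, 0), 1 - 1 / choose(12, 6),
               tolerance = 1e-12)
  expect_error(liebermeister_p(-1, 0, 0, 1), "non-negative")
})

test_that("liebermeister_p negative direction mirrors the lower tail", {
  tabs <- all_tables(8)
  for (r in sample(nrow(tabs), 60)) {
    t <- tabs[r, ]
    expect_equal(liebermeister_p(t[1], t[2], t[3], t[4], "negative"),
                 oracle_hyper_tail(t[1], t[2], t[3], t[4], "negative"),
                 tolerance = 1e-12)
  }
})

test_that("p_to_z matches the normal quantile and clamps underflow", {
  expect_equal(p_to_z(0.5), 0)
  expect_equal(p_to_z(0.025), qnorm(0.975), tolerance = 1e-10)
  expect_equal(p_to_z(0.975), -qnorm(0.975), tolerance = 1e-10)
  expect_equal(p_to_z(0.025, -1), -qnorm(0.975), tolerance = 1e-10)
  expect_warning(z <- p_to_z(c(0, 1)), "clamped")
  expect_equal(z, c(8, -8))
})

test_that("BH threshold follows the step-up rule", {
  expect_equal(bh_fdr_threshold(c(0.001, 0.2, 0.9), 0.05), 0.001)
  expect_equal(bh_fdr_threshold(c(0.01, 0.02, 0.03), 0.05), 0.03)
  expect_true(is.na(bh_fdr_threshold(rep(0.9, 5), 0.05)))
  expect_error(bh_fdr_threshold(numeric(0)), "empty")
})

test_that("BH threshold agrees with p.adjust step-up on random vectors", {
  set.seed(1)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)   # mix of null-ish and signal-ish
    p[p == 0] <- 1e-12
    thr <- bh_fdr_threshold(p, 0.05)
    adj <- p.adjust(p, "BH")
    if (is.na(thr)) {
      expect_false(any(adj <= 0.05))
    } else {
      # the declared set must be exactly the BH-adjusted discoveries
      expect_identical(p <= thr, adj <= 0.05)
    }
  }
})

test_that("coverage filter applies a strict 5% rule", {
  # derived by enumerating counts k = 0..125 against k/125 > 0.05:
  # k = 6 (4.8%) is excluded, k = 7 (5.6%) is the first kept
  n <- 125
  kept <- which(vapply(0:n, function(k) k / n > 0.05, logical(1))) - 1L
  expect_equal(min(kept), 7)

  coh <- random_cohort(20, shape = c(5, 5, 5), seed = 5, p = 0.3)
  cm <- voxel_coverage_mask(coh, 0.25)
  counts <- colSums(coh$mat)
  expect_identical(as.vector(cm), counts / 20 > 0.25)
  expect_error(voxel_coverage_mask(coh, 0), "0, 1")
})

test_that("voxel_table matches a naive per-sample loop", {
  coh <- random_cohort(30, shape = c(5, 5, 5), seed = 8, p = 0.3)
  set.seed(2)
  labels <- rbinom(30, 1, 0.5) == 1
  for (rep in 1:5) {
    vox <- sample(5, 3, replace = TRUE)
    tab <- voxel_table(coh, labels, vox)
    a <- b <- cc <- d <- 0
    for (s in 1:30) {
      les <- cohort_mask(coh, s)$voxels[vox[1], vox[2], vox[3]] == 1
      if (les && labels[s]) a <- a + 1
      if (les && !labels[s]) b <- b + 1
      if (!les && labels[s]) cc <- cc + 1
      if (!les && !labels[s]) d <- d + 1
    }
    expect_identical(c(tab$a, tab$b, tab$c, tab$d),
                     as.integer(c(a, b, cc, d)))
  }
  # degenerate margins
  all_pos <- voxel_table(coh, rep(TRUE, 30), c(1, 1, 1))
  expect_equal(all_pos$b + all_pos$d, 0)
  expect_error(voxel_table(coh, labels[-1], c(1, 1, 1)), "length")
})

test_that("run_vlsm rejects degenerate labels and empty coverage", {
  coh <- random_cohort(10, seed = 4, p = 0.2)
  expect_error(run_vlsm(coh, rep(TRUE, 10)), "both label classes")
  expect_error(run_vlsm(coh, c(TRUE, rep(FALSE, 9))), "both label classes")
  cfg <- vlsm_config(min_lesion_fraction = 0.999)
  expect_error(run_vlsm(random_cohort(8, seed = 6, p = 0.05),
                        rep(c(TRUE, FALSE), 4), cfg), "coverage")
})

test_that("run_vlsm is invariant to sample ordering", {
  sim <- simulate_cohort(sim_config(grid_shape = c(24, 24, 24),
                                    n_pos = 20, n_neg = 20,
                                    hotspot_center = c(9, 9, 9),
                                    hotspot_radius = 5,
                                    n_genes = 400, emt_set_size = 10,
                                    n_planted_up = 2, n_celltypes = 2,
                                    seed = 31))
  coh <- sim$lesions
  labels <- sim$truth$labels
  res1 <- run_vlsm(coh, labels)
  set.seed(99)
  perm <- sample(length(labels))
  coh2 <- structure(list(grid = coh$grid, sample_ids = coh$sample_ids[perm],
                         mat = coh$mat[perm, , drop = FALSE]),
                    class = "lesion_cohort")
  res2 <- run_vlsm(coh2, labels[perm])
  expect_equal(res1$p_map, res2$p_map)
  expect_identical(res1$sig_mask, res2$sig_mask)
  expect_equal(res1$fdr_p_threshold, res2$fdr_p_threshold)
})

test_that("vlsm result maps respect their declared structure", {
  sim <- simulate_cohort(sim_config(grid_shape = c(24, 24, 24),
                                    n_pos = 25, n_neg = 25,
                                    hotspot_center = c(9, 9, 9),
                                    hotspot_radius = 5,
                                    n_genes = 400, emt_set_size = 10,
                                    n_planted_up = 2, n_celltypes = 2,
                                    seed = 13))
  res <- run_vlsm(sim$lesions, sim$truth$labels)
  expect_true(all(res$sig_mask[!res$analyzed_mask] == FALSE))
  expect_true(all(is.na(res$p_map[!res$analyzed_mask])))
  if (!is.na(res$fdr_p_threshold))
    expect_true(all(res$p_map[res$sig_mask] <= res$fdr_p_threshold))
  expect_equal(sum(res$clusters$n_voxels), sum(res$sig_mask))
  # p in (0,1], z signed consistently
  p <- res$p_map[res$analyzed_mask]
  expect_true(all(p > 0 & p <= 1))
})

test_that("vlsm maps and cluster tables round-trip to disk", {
  sim <- simulate_cohort(sim_config(grid_shape = c(24, 24, 24),
                                    n_pos = 25, n_neg = 25,
                                    hotspot_center = c(9, 9, 9),
                                    hotspot_radius = 5,
                                    n_genes = 400, emt_set_size = 10,
                                    n_planted_up = 2, n_celltypes = 2,
                                    seed = 13))
  res <- run_vlsm(sim$lesions, sim$truth$labels)
  dir <- tempfile()
  paths <- write_vlsm_result(res, dir)
  expect_true(all(file.exists(paths)))
  sig <- read_mask(paths[["sig"]])
  expect_identical(sig$voxels == 1, res$sig_mask)
  cl <- read.csv(paths[["clusters"]])
  expect_equal(nrow(cl), nrow(res$clusters))
})
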