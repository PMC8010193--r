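test_that("cohen_kappa matches hand-computed agreement fixtures", {
  # agreement matrix [[20,5],[10,15]]: p_o = 35/50, p_e = (30*25 + 20*25)/50^2
  a <- c(rep("x", 25), rep("y", 25))
  b <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  expect_equal(cohen_kappa(a, b), 0.40, tolerance = 1e-12)

  # identical ratings with >= 2 categories
  expect_equal(cohen_kappa(a, a), 1)

  # balanced chance-level agreement [[25,25],[25,25]] scaled
  a2 <- rep(c("x", "y"), each = 50)
  b2 <- rep(c("x", "y", "x", "y"), each = 25)
  expect_equal(cohen_kappa(a2, b2), 0, tolerance = 1e-12)

  expect_warning(k <- cohen_kappa(rep("x", 5), rep("x", 5)), "undefined")
  expect_equal(k, 1)
})

test_that("kappa is invariant under category relabeling", {
  set.seed(3)
  a <- sample(letters[1:4], 60, replace = TRUE)
  b <- sample(letters[1:4], 60, replace = TRUE)
  relab <- setNames(letters[4:1], letters[1:4])
  expect_equal(cohen_kappa(a, b), cohen_kappa(relab[a], relab[b]))
})

test_that("kappa grading follows the published thresholds", {
  expect_equal(kappa_grade(0.923), "excellent")
  expect_equal(kappa_grade(0.842), "excellent")
  expect_equal(kappa_grade(0.6), "good")
  expect_equal(kappa_grade(0.8), "good")
  expect_equal(kappa_grade(0.59), "poor")
  expect_equal(kappa_grade(c(0.9, 0.7, 0.1)),
               c("excellent", "good", "poor"))
})

test_that("VOI discrepancy rule flags >5% relative volume difference", {
  expect_equal(voi_discrepancy(1000, 1000), "accept")
  expect_equal(voi_discrepancy(1000, 1060), "recheck")  # ratio 0.06
  expect_equal(voi_discrepancy(1000, 1040), "accept")   # ratio 0.04
  expect_equal(voi_discrepancy(1060, 1000), "recheck")  # symmetric
  expect_error(voi_discrepancy(0, 10), "positive")
})

test_that("vasari_filter keeps striking enhancement in temporal lobe", {
  s <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                  vasari_f1 = c(2, 2, 1, 1, 2),
                  vasari_f5 = c(7, 6, 8, 7, NA),
                  multilobe_temporal = c(0, 0, 1, 0, 0))
  kept <- vasari_filter(s)
  expect_setequal(as.character(kept), c("a", "c"))
  # F5 = 6 ("68-95%") excluded, indeterminate (9) excluded
  s$vasari_f5[2] <- 9
  expect_false("b" %in% vasari_filter(s))
  # without the temporal requirement only F5 matters
  expect_setequal(as.character(vasari_filter(s, require_temporal = FALSE)),
                  c("a", "c", "d"))
  expect_equal(length(vasari_filter(s[0, , drop = FALSE])), 0)
})

test_that("membership classification matches a naive intersection loop", {
  coh <- random_cohort(25, shape = c(6, 6, 6), seed = 15, p = 0.25)
  set.seed(16)
  region <- array(rbinom(6^3, 1, 0.2) == 1, dim = c(6, 6, 6))
  mem <- classify_membership(coh, region)
  for (i in 1:25) {
    ov <- sum(cohort_mask(coh, i)$voxels == 1 & region)
    expect_equal(mem$overlap_voxels[i], ov)
    expect_equal(mem$in_area[i], ov >= 1)
    expect_equal(mem$overlap_fraction[i],
                 ov / mask_volume(cohort_mask(coh, i)))
  }
  # full containment and empty intersection
  sub_region <- array(TRUE, dim = c(6, 6, 6))
  memf <- classify_membership(coh, sub_region)
  expect_true(all(memf$overlap_fraction == 1))
  meme <- classify_membership(coh, array(FALSE, dim = c(6, 6, 6)))
  expect_true(all(!meme$in_area))
})

test_that("membership is monotone in the overlap threshold", {
  coh <- random_cohort(25, shape = c(6, 6, 6), seed = 17, p = 0.25)
  set.seed(18)
  region <- array(rbinom(6^3, 1, 0.3) == 1, dim = c(6, 6, 6))
  prev <- classify_membership(coh, region, min_overlap_voxels = 1)$in_area
  for (thr in c(2, 4, 8)) {
    cur <- classify_membership(coh, region, min_overlap_voxels = thr)$in_area
    expect_true(all(prev | !cur))   # raising threshold never adds members
    prev <- cur
  }
})

test_that("contingency_report recomputes margins and percentages exactly", {
  rep <- contingency_report(contingency_table(22, 11, 30, 62))
  expect_equal(unname(rep$margins),
               c(33, 92, 52, 73, 125))
  expect_equal(unname(rep$cells), c(22, 11, 30, 62))
  expect_equal(sum(rep$cells), unname(rep$margins["n"]))
  expect_equal(unname(rep$odds_ratio), 22 * 62 / (11 * 30),
               tolerance = 1e-12)
  # percentages recompute from cells
  expect_equal(unname(rep$row_percent["a"]), round(100 * 22 / 33))

  # membership form agrees with the direct-cell form
  mem <- data.frame(sample_id = sprintf("s%d", 1:10),
                    in_area = c(rep(TRUE, 4), rep(FALSE, 6)))
  lab <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r2 <- contingency_report(mem, lab)
  expect_equal(unname(r2$cells), c(3, 1, 2, 4))

  # collapsed margins
  r3 <- contingency_report(contingency_table(10, 0, 0, 0))
  expect_equal(unname(r3$margins), c(10, 0, 10, 0, 10))
})

test_that("chi-square matches the closed form n(ad-bc)^2/(margins)", {
  tabs <- list(c(22, 11, 30, 62), c(10, 10, 10, 10), c(5, 1, 2, 9))
  for (t in tabs) {
    res <- chi2_test(contingency_table(t[1], t[2], t[3], t[4]))
    n <- sum(t)
    closed <- n * (t[1] * t[4] - t[2] * t[3])^2 /
      ((t[1] + t[2]) * (t[3] + t[4]) * (t[1] + t[3]) * (t[2] + t[4]))
    expect_equal(res$statistic, closed, tolerance = 1e-10)
    expect_equal(res$df, 1)
  }
  prop <- chi2_test(contingency_table(10, 10, 10, 10))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  expect_error(chi2_test(contingency_table(5, 0, 3, 0)), "margin")
})

test_that("location_summary reproduces lobe-level percentages", {
  # cohort structured like a published subtype-by-location table:
  # single temporal 38/223, multi-including-temporal 130/223, other 55/223
  counts <- rbind(proneural = c(10, 32, 10),
                  mesenchymal = c(16, 34, 23),
                  neural = c(4, 29, 7),
                  classical = c(8, 35, 15))
  rows <- list()
  for (st in rownames(counts)) {
    n <- counts[st, ]
    rows[[st]] <- data.frame(
      subtype = st,
      vasari_f1 = c(rep(2, n[1]), rep(2, n[2]), rep(1, n[3])),
      multilobe_temporal = c(rep(0, n[1]), rep(1, n[2]), rep(0, n[3])),
      side = "left")
  }
  samples <- do.call(rbind, rows)
  samples$sample_id <- sprintf("s%03d", seq_len(nrow(samples)))
  loc <- location_summary(samples)
  expect_equal(unname(loc$n["total"]), 223)
  expect_equal(unname(loc$percent["single_temporal", "total"]), 17.04)
  expect_equal(unname(loc$temporal_involvement["total"]), 75.34)
  expect_equal(unname(loc$percent["other", "mesenchymal"]), 31.51)
  expect_equal(unname(loc$counts["multi_temporal", "total"]), 130)

  empty <- location_summary(samples[0, , drop = FALSE])
  expect_true(all(empty$counts == 0))
})
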