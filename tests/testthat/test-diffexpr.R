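test_that("size factors match the median-of-ratios hand computation", {
  m <- matrix(c(2, 4, 6, 12, 10, 20), nrow = 3, byrow = TRUE)
  sf <- size_factors(m)
  # every ratio is 1/sqrt(2) or sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # identical samples -> all factors 1
  m2 <- matrix(rep(c(5, 9, 100), 3), nrow = 3)
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  # homogeneity: scaling one sample by c scales its factor by c,
  # relative to the other samples (the overall scale is set by the
  # geometric-mean reference, which the scaling also shifts)
  m3 <- m
  m3[, 2] <- m3[, 2] * 5
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3[2] / sf3[1]), unname(5 * sf[2] / sf[1]))
  # all-zero overlap is a domain error
  expect_error(size_factors(matrix(c(1, 0, 0, 1), 2)), "positive counts")
})

test_that("bh_adjust matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(88)
  for (i in 1:25) {
    p <- runif(sample(2:60, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  # monotone on sorted input; NA passthrough; bounds checked
  p <- sort(runif(20))
  expect_false(is.unsorted(bh_adjust(p)))
  expect_equal(is.na(bh_adjust(c(0.1, NA, 0.9))), c(FALSE, TRUE, FALSE))
  expect_error(bh_adjust(c(0.1, 1.7)), "\\[0, 1\\]")
  # padj >= pval always
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("dispersion estimation recovers known regimes", {
  set.seed(21)
  n <- 60
  groups <- rep(c("a", "b"), each = n / 2)
  f <- rep(1, n)
  # Poisson genes: gene-wise estimate collapses toward the floor
  pois <- matrix(rpois(200 * n, 100), 200, n)
  dp <- estimate_dispersions(pois, f, groups)
  expect_lt(median(dp$alpha_gene), 0.02)
  # constant counts: zero variance -> floored gene estimate
  const <- matrix(7, 5, n)
  dc <- estimate_dispersions(rbind(const, pois[1:50, ]), f, groups)
  expect_equal(unname(dc$alpha_gene[1:5]), rep(1e-8, 5))
  # NB with true alpha = 0.1 at mu = 100, n = 30/group: median final
  # alpha recovered within a factor of two
  nb <- matrix(rnbinom(400 * n, mu = 100, size = 10), 400, n)
  dn <- estimate_dispersions(nb, f, groups)
  expect_gt(median(dn$alpha), 0.05)
  expect_lt(median(dn$alpha), 0.2)
  # all-zero gene flagged NA
  dz <- estimate_dispersions(rbind(0, pois[1:20, ]), f, groups)
  expect_true(is.na(dz$alpha[1]))
})

test_that("wald test is exact on degenerate and symmetric inputs", {
  set.seed(5)
  base <- matrix(rnbinom(300 * 4, mu = 60, size = 8), 300, 4)
  # identical groups (duplicated samples): log2fc numerically zero
  counts <- cbind(base, base)
  groups <- rep(c("young", "old"), each = 4)
  de <- nb_wald_test(counts, factor(groups, c("young", "old")))
  expect_lt(max(abs(de$log2fc), na.rm = TRUE), 1e-6)
  # internal consistency: wald = log2fc/se, p = 2 pnorm(-|wald|),
  # DEG flag honors both thresholds
  ok <- de$converged
  expect_equal(de$wald[ok], de$log2fc[ok] / de$se[ok])
  expect_equal(de$pval[ok], 2 * pnorm(-abs(de$wald[ok])))
  expect_true(all(de$padj[ok] >= de$pval[ok]))
  expect_equal(de$is_deg,
               !is.na(de$padj) & de$padj < 0.05 & abs(de$log2fc) >= 1)
  expect_error(nb_wald_test(counts, rep("one", 8)), "two groups")
})

test_that("log2fc estimates are scale invariant via size factors", {
  s <- small_study()
  counts <- s$counts[rowMeans(s$counts) > 5, ]
  groups <- factor(s$meta$age_group, c("6m", "28m"))
  de1 <- nb_wald_test(counts, groups)
  scaled <- counts
  scaled[, 3] <- scaled[, 3] * 4L
  de2 <- nb_wald_test(scaled, groups)
  sf1 <- attr(de1, "size_factors"); sf2 <- attr(de2, "size_factors")
  expect_equal(unname((sf2[3] / sf2[1]) / (sf1[3] / sf1[1])), 4,
               tolerance = 1e-6)
  ok <- de1$converged & de2$converged
  expect_lt(median(abs(de2$log2fc[ok] - de1$log2fc[ok])), 0.05)
})

test_that("normalized_log2 and fold-change helpers are exact", {
  m <- matrix(c(0L, 7L, 3L, 15L), 2, 2)
  nl <- normalized_log2(m, c(1, 1))
  expect_equal(nl[1, 1], 0)
  expect_equal(nl[2, 1], 3)
  # doubling a count strictly increases the transformed value
  expect_true(all(normalized_log2(m * 2L, c(1, 1)) >= nl))
  expect_gt(normalized_log2(matrix(14L), 1)[1], 3)
  expect_error(normalized_log2(m, c(1, -1)), "positive")

  expect_equal(fold_change_percent(3.599), 1211)
  expect_equal(fold_change_percent(0), 100)
  expect_equal(fold_decline(-2.51), 5.69)
  expect_error(fold_change_percent(Inf), "finite")
})

test_that("pca_scores separates groups and reports sane variance", {
  s <- small_study()
  de <- nb_wald_test(s$counts, factor(s$meta$age_group, c("6m", "28m")))
  norm <- normalized_log2(s$counts, attr(de, "size_factors"))
  p <- pca_scores(norm, n_components = 2, n_top = 200)
  expect_lte(sum(p$percent_variance), 100)
  grp <- s$meta$age_group
  # centroids separate on PC1 with no overlap direction ambiguity
  d <- abs(mean(p$scores[grp == "6m", 1]) - mean(p$scores[grp == "28m", 1]))
  pooled_sd <- sd(p$scores[, 1])
  expect_gt(d, pooled_sd)
  # identical samples: zero variance, zero percent
  two <- cbind(a = norm[, 1], b = norm[, 1])
  p2 <- pca_scores(two, n_components = 2, n_top = 50)
  expect_equal(p2$scores[1, ], p2$scores[2, ])
  expect_equal(sum(p2$percent_variance), 0)
  expect_error(pca_scores(norm, n_components = 99), "components")
})

test_that("heatmap z-scores are standardized and clipped to [-3, 3]", {
  s <- small_study()
  de <- nb_wald_test(s$counts, factor(s$meta$age_group, c("6m", "28m")))
  norm <- normalized_log2(s$counts, attr(de, "size_factors"))
  z <- top_z_heatmap_data(norm, de, k = 10)
  expect_equal(nrow(z), 10)
  expect_true(all(z >= -3 & z <= 3))
  # unclipped rows have mean 0, sd 1 by construction
  raw_ok <- apply(z, 1, function(r) all(abs(r) < 3))
  if (any(raw_ok)) {
    expect_equal(unname(rowMeans(z[raw_ok, , drop = FALSE])),
                 rep(0, sum(raw_ok)), tolerance = 1e-8)
    expect_equal(unname(apply(z[raw_ok, , drop = FALSE], 1, sd)),
                 rep(1, sum(raw_ok)), tolerance = 1e-8)
  }
  expect_warning(top_z_heatmap_data(norm, de, k = 1e5), "returning all")
})
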