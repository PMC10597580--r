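test_that("determinant_score standardizes against the reference", {
  # worked rotarod example: 160 s vs reference 123.9 +/- 28.9
  expect_equal(round(determinant_score(160, 123.9, 28.9), 3), 1.249)
  expect_equal(determinant_score(50, 50, 7), 0)
  expect_equal(determinant_score(57, 50, 7), 1)
  expect_equal(determinant_score(c(50, 57, 43), 50, 7), c(0, 1, -1))
  expect_error(determinant_score(1, 0, 0), "ref_sd")
  expect_error(determinant_score(1, 0, -2), "ref_sd")
})

test_that("inverted cling is scored on the log10 scale", {
  expect_equal(transform_inverted_cling(100), 2)
  expect_equal(transform_inverted_cling(1), 0)
  # composition: with reference (1.8, 0.2) on the log scale, a cling
  # time of 10^1.8 s has z-score 0
  expect_equal(determinant_score(transform_inverted_cling(10^1.8), 1.8, 0.2), 0)
  expect_error(transform_inverted_cling(0), "cling")
  expect_error(transform_inverted_cling(-3), "cling")
})

test_that("reference_stats uses sample SD and the log10 cling scale", {
  rec <- make_records(rotarod = c(100, 140))
  expect_error(reference_stats(rec), "zero variance")
  rec <- make_records(rotarod = c(100, 140), grip = c(90, 110),
                      cling = c(10, 1000), treadmill = c(20, 30),
                      vwr = c(4, 6))
  rs <- reference_stats(rec)
  expect_equal(rs$mean[["rotarod_s"]], 120)
  expect_equal(rs$sd[["rotarod_s"]], sqrt((20^2 + 20^2) / 1))
  # cling summarized after log10: mean of (1, 3)
  expect_equal(rs$mean[["inverted_cling_s"]], 2)
  expect_error(reference_stats(rec[1, ]), "at least 2")
  expect_error(reference_stats(rec[, -3]), "missing determinant")
})

test_that("reference group scored against itself centers at zero", {
  set.seed(42)
  rec <- make_records(rotarod = rnorm(8, 124, 25), grip = rnorm(8, 100, 12),
                      cling = 10^rnorm(8, 1.8, 0.3),
                      treadmill = rnorm(8, 25, 4), vwr = rnorm(8, 5, 1))
  rs <- reference_stats(rec)
  sc <- cfab_table(rec, rs)
  for (d in paste0(CFAB_DETERMINANTS, "_z"))
    expect_equal(mean(sc[[d]]), 0)
  expect_equal(mean(sc$cfab), 0)
})

test_that("cfab is the exact sum of the five determinant scores", {
  set.seed(7)
  rec <- make_records(rotarod = rnorm(5, 124, 25), grip = rnorm(5, 100, 12),
                      cling = 10^rnorm(5, 1.8, 0.3),
                      treadmill = rnorm(5, 25, 4), vwr = rnorm(5, 5, 1))
  rs <- reference_stats(rec)
  sc <- cfab_table(rec, rs)
  expect_equal(sc$cfab,
               rowSums(sc[paste0(CFAB_DETERMINANTS, "_z")]))
  # arithmetic example: z-scores (1.249, 0.5, -0.5, 0, 0.2) sum to 1.449
  expect_equal(sum(c(1.249, 0.5, -0.5, 0, 0.2)), 1.449)
  # a record one SD below the reference on every determinant scores -5
  one_low <- rec[1, ]
  one_low$rotarod_s <- rs$mean[["rotarod_s"]] - rs$sd[["rotarod_s"]]
  one_low$grip_force <- rs$mean[["grip_force"]] - rs$sd[["grip_force"]]
  one_low$inverted_cling_s <-
    10^(rs$mean[["inverted_cling_s"]] - rs$sd[["inverted_cling_s"]])
  one_low$treadmill_speed <-
    rs$mean[["treadmill_speed"]] - rs$sd[["treadmill_speed"]]
  one_low$vwr <- rs$mean[["vwr"]] - rs$sd[["vwr"]]
  expect_equal(cfab_score(one_low, rs)$cfab, -5)
  # a record exactly at the reference means scores 0
  at_mean <- one_low
  at_mean$rotarod_s <- rs$mean[["rotarod_s"]]
  at_mean$grip_force <- rs$mean[["grip_force"]]
  at_mean$inverted_cling_s <- 10^rs$mean[["inverted_cling_s"]]
  at_mean$treadmill_speed <- rs$mean[["treadmill_speed"]]
  at_mean$vwr <- rs$mean[["vwr"]]
  expect_equal(cfab_score(at_mean, rs)$cfab, 0)
  # missing measurement is an error, not imputed
  na_rec <- rec
  na_rec$grip_force[2] <- NA
  expect_error(cfab_table(na_rec, rs), "non-finite")
})

test_that("z-scores are invariant to determinant-wide affine shifts", {
  set.seed(11)
  rec <- make_records(rotarod = rnorm(10, 124, 25),
                      grip = rnorm(10, 100, 12),
                      cling = 10^rnorm(10, 1.8, 0.3),
                      treadmill = rnorm(10, 25, 4), vwr = rnorm(10, 5, 1))
  sc0 <- cfab_table(rec, reference_stats(rec))
  shifted <- rec
  shifted$rotarod_s <- shifted$rotarod_s + 500
  shifted$grip_force <- shifted$grip_force + 42
  sc1 <- cfab_table(shifted, reference_stats(shifted))
  expect_equal(sc1$rotarod_s_z, sc0$rotarod_s_z)
  expect_equal(sc1$grip_force_z, sc0$grip_force_z)
  # cling is log-transformed, so the invariance there is multiplicative
  scaled <- rec
  scaled$inverted_cling_s <- scaled$inverted_cling_s * 10
  sc2 <- cfab_table(scaled, reference_stats(scaled))
  expect_equal(sc2$inverted_cling_s_z, sc0$inverted_cling_s_z)
})

test_that("one-way ANOVA and LSD match textbook arithmetic", {
  # SSB = 26 on 2 df, SSW = 6 on 6 df -> F = 13
  an <- group_anova_lsd(c(1, 2, 3, 2, 3, 4, 5, 6, 7),
                        rep(c("a", "b", "c"), each = 3))
  expect_equal(an$F, 13)
  expect_equal(unname(an$df), c(2, 6))
  expect_equal(an$p, pf(13, 2, 6, lower.tail = FALSE))
  expect_equal(nrow(an$lsd), 3)
  # LSD pair a-b: diff -1, se sqrt(MSE * 2/3), 6 df
  ab <- an$lsd[an$lsd$group1 == "a" & an$lsd$group2 == "b", ]
  expect_equal(ab$t, -1 / sqrt(1 * 2 / 3))
  # identical groups: F = 0, p = 1
  an0 <- group_anova_lsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(an0$F, 0)
  expect_equal(an0$p, 1)
  expect_error(group_anova_lsd(1:3, c("a", "a", "b")), ">= 2")
})

test_that("two-group ANOVA equals the pooled-variance t-test (t^2 = F)", {
  set.seed(3)
  x <- rnorm(7, 0, 1); y <- rnorm(8, 1, 1)
  an <- group_anova_lsd(c(x, y), rep(c("a", "b"), c(7, 8)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2)
  expect_equal(an$p, tt$p.value)
  expect_equal(an$lsd$p, tt$p.value)
})
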