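# Complete-block ANOVA, paired patch comparisons, BH step-up.

test_that("block ANOVA returns the fixed-effect F tests with correct df", {
  set.seed(51)
  d <- sim_purity_table()
  a <- purity_block_anova(d)
  expect_equal(a$term, c("block", "structure", "position",
                         "structure:position", "residuals"))
  expect_equal(a$df, c(29, 2, 1, 2, 145))
  expect_true(all(a$F[2:4] >= 0))
  expect_true(all(a$p[2:4] >= 0 & a$p[2:4] <= 1))
})

test_that("block ANOVA F equals the random-intercept model F under balance", {
  skip_if_not_installed("lme4")
  set.seed(52)
  d <- sim_purity_table(shift_sd = 1)
  a <- purity_block_anova(d)
  f <- lme4::lmer(purity ~ structure * position + (1 | plant_id), data = d)
  expect_equal(a$F[2:4], anova(f)$`F value`, tolerance = 1e-8)
})

test_that("block ANOVA refuses incomplete designs", {
  set.seed(53)
  d <- sim_purity_table()
  expect_error(purity_block_anova(d[-1, ]), "complete block")
})

test_that("interaction p-values are uniform under the null and detect a +3 SD shift", {
  set.seed(54)
  p_null <- replicate(200, purity_block_anova(sim_purity_table())$p[4])
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
  p_shift <- replicate(200, purity_block_anova(sim_purity_table(shift_sd = 3))$p[4])
  expect_gte(mean(p_shift < 0.01), 0.95)
})

test_that("pairwise patch tests compare all 15 pairs with BH control", {
  tbl <- test_patch_table()
  pw <- pairwise_patch_tests(tbl)
  expect_equal(nrow(pw$comparisons), 15)
  expect_true(all(pw$comparisons$p_adj >= pw$comparisons$p, na.rm = TRUE))
  expect_true(all(nchar(pw$letters) >= 1))
  # two identical patches: t = 0, p = 1
  dup <- tbl
  dup[dup$patch == "sepal_base", "purity"] <-
    dup[dup$patch == "sepal_tip", "purity"]
  pw2 <- pairwise_patch_tests(dup)
  row <- pw2$comparisons[pw2$comparisons$patch_a == "sepal_tip" &
                           pw2$comparisons$patch_b == "sepal_base", ]
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
  # constant nonzero difference cannot be tested and is flagged
  dup[dup$patch == "sepal_base", "purity"] <-
    dup[dup$patch == "sepal_tip", "purity"] + 0.1
  pw3 <- pairwise_patch_tests(dup)
  row3 <- pw3$comparisons[pw3$comparisons$patch_a == "sepal_tip" &
                            pw3$comparisons$patch_b == "sepal_base", ]
  expect_true(row3$skipped)
})

test_that("BH step-up matches the hand rule and brackets Bonferroni", {
  r <- bh_fdr(c(0.005, 0.01, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  r2 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(r2$reject))  # p(5) = 0.05 <= 5 * 0.05 / 5
  expect_equal(bh_fdr(0.04, 0.05)$adjusted, 0.04)
  expect_true(bh_fdr(0.04, 0.05)$reject)
  expect_false(any(bh_fdr(rep(1, 6), 0.05)$reject))
  expect_length(bh_fdr(numeric(0))$adjusted, 0)
  # BH rejections contain the Bonferroni rejections at the same q
  set.seed(55)
  for (i in 1:20) {
    p <- runif(12)^2
    bh <- bh_fdr(p, 0.05)$reject
    bonf <- p <= 0.05 / length(p)
    expect_true(all(bh[bonf]))
  }
})

test_that("sqrt-distance ANOVA blocks on plant pair and back-transforms means", {
  tbl <- test_patch_table()
  d <- pairwise_distances(tbl)
  res <- sqrt_distance_anova(d)
  expect_equal(res$anova$df[1], choose(30, 2) - 1)
  expect_equal(res$anova$df[2:4], c(2, 1, 2))
  expect_named(res$patch_means, c("sepal_tip", "sepal_base", "petal_tip",
                                  "petal_base", "labellum_tip", "labellum_base"))
  expect_true(all(res$patch_means > 0))
  # all-equal distances give F = 0 for every treatment term
  d0 <- d
  d0$euclidean <- 0.05
  res0 <- sqrt_distance_anova(d0)
  expect_equal(res0$anova$F[2:4], rep(0, 3))
})
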