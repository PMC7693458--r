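# Covariance-ratio statistic, permutation test, bootstrap CI.

test_that("normalize_excitations builds a z-scored plants x 18 matrix", {
  tbl <- test_patch_table()
  M <- normalize_excitations(tbl)
  expect_equal(dim(M), c(30, 18))
  expect_equal(unname(colMeans(M)), rep(0, 18), tolerance = 1e-12)
  expect_equal(unname(apply(M, 2, stats::var)), rep(1, 18), tolerance = 1e-12)
  expect_true(all(names(default_module_assignment()) %in% colnames(M)))
  # constant column refused by name
  bad <- tbl
  bad$e_uv[bad$patch == "sepal_tip"] <- 0.4
  expect_error(normalize_excitations(bad), "sepal_tip.uv")
  expect_error(normalize_excitations(tbl[-1, ]), "complete")
})

test_that("CR closed form: two modules of perfectly correlated copies give sqrt(2)", {
  set.seed(71)
  z <- rnorm(40)
  M <- cbind(z, 2 * z, -0.5 * z, 3 * z)
  M <- scale(M)
  expect_equal(cr_statistic(M, c(1, 1, 2, 2)), sqrt(2), tolerance = 1e-10)
})

test_that("CR equals the brute-force covariance-summation oracle", {
  set.seed(72)
  for (i in 1:50) {
    n <- sample(6:12, 1)
    p <- sample(4:8, 1)
    M <- matrix(rnorm(n * p), n, p)
    k <- if (p >= 6) sample(2:3, 1) else 2L
    asg <- sample(rep_len(seq_len(k), p))  # every module gets >= 2 variables
    expect_equal(cr_statistic(M, asg), cr_oracle(M, asg), tolerance = 1e-10)
  }
})

test_that("CR is symmetric in module labels and invariant to variable scale", {
  set.seed(73)
  M <- matrix(rnorm(30 * 18), 30, 18,
              dimnames = list(NULL, names(default_module_assignment())))
  asg <- default_module_assignment()
  relabeled <- stats::setNames(c(3L, 1L, 2L)[asg], names(asg))
  expect_equal(cr_statistic(M, asg), cr_statistic(M, relabeled))
  # column reordering within the named assignment changes nothing
  perm <- sample(ncol(M))
  expect_equal(cr_statistic(M[, perm], asg[colnames(M)[perm]]),
               cr_statistic(M, asg))
  # scaling a variable is absorbed when inputs are z-scored
  M2 <- M
  M2[, 5] <- M2[, 5] * 7
  expect_equal(cr_statistic(scale(M2), asg), cr_statistic(scale(M), asg),
               tolerance = 1e-12)
})

test_that("CR degenerate inputs are refused", {
  set.seed(74)
  M <- matrix(rnorm(20), 10, 2)
  expect_error(cr_statistic(M, c(1, 2)), "degenerate within-module")
  expect_error(cr_statistic(M[1:2, ], c(1, 2)), "at least 3 observations")
  expect_error(cr_statistic(cbind(M, M), rep(1, 4)), "at least 2 modules")
})

test_that("permutation test honours the add-one convention and the seed", {
  tbl <- test_patch_table()
  M <- normalize_excitations(tbl)
  asg <- default_module_assignment()
  r1 <- cr_permutation_test(M, asg, n_perm = 999, seed = 5)
  r2 <- cr_permutation_test(M, asg, n_perm = 999, seed = 5)
  expect_identical(r1$perm, r2$perm)
  expect_equal(r1$p, (sum(r1$perm <= r1$observed) + 1) / 1000)
  # strongly modular data: observed below every permuted value -> p = 1/1000
  expect_equal(r1$p, 1 / 1000)
  expect_warning(cr_permutation_test(M, asg, n_perm = 50, seed = 1), "coarse")
})

test_that("patch-level permutation preserves whole patches", {
  tbl <- test_patch_table()
  M <- normalize_excitations(tbl)
  asg <- default_module_assignment()
  r <- cr_permutation_test(M, asg, n_perm = 299, seed = 6, unit = "patch")
  expect_true(r$p > 0 && r$p <= 1)
  # patch-level p cannot resolve below ~1/30: sampled assignments repeat
  expect_gte(r$p, 1 / 60)
  # mixed within-patch assignment is invalid at patch level
  bad <- asg
  bad["sepal_tip.uv"] <- 2L
  expect_error(cr_permutation_test(M, bad, n_perm = 299, unit = "patch"),
               "whole patches")
})

test_that("bootstrap CI brackets the estimate and is seed-reproducible", {
  tbl <- test_patch_table()
  M <- normalize_excitations(tbl)
  asg <- default_module_assignment()
  obs <- cr_statistic(M, asg)
  ci <- cr_bootstrap_ci(M, asg, n_boot = 300, seed = 7)
  expect_lte(ci[["low"]], ci[["high"]])
  ci2 <- cr_bootstrap_ci(M, asg, n_boot = 300, seed = 7)
  expect_identical(as.numeric(ci), as.numeric(ci2))
  one <- cr_bootstrap_ci(M, asg, n_boot = 1, seed = 8)
  expect_equal(one[["low"]], one[["high"]])
  expect_error(cr_bootstrap_ci(M[1:5, ], asg), "at least 10")
})

test_that("percentile bootstrap brackets its own distribution and shows the known upward bias", {
  # Resampling plants with replacement duplicates rows, which inflates the
  # apparent among-module covariance, so the bootstrap CR distribution sits
  # above the point estimate: the interval reliably covers the bootstrap
  # median while the point estimate hugs (or falls below) its lower bound.
  ctx <- test_ctx()
  set.seed(75)
  seeds <- sample.int(1e6, 10)
  stats <- vapply(seeds, function(sd) {
    d <- generate_dataset(generator_config(seed = sd))
    M <- normalize_excitations(patch_colors(d$spectra, d$manifest, ctx,
                                            locus = test_locus()))
    obs <- cr_statistic(M, default_module_assignment())
    ci <- cr_bootstrap_ci(M, default_module_assignment(), n_boot = 200,
                          seed = sd + 1)
    med <- stats::median(attr(ci, "boot"))
    c(obs = obs, low = ci[["low"]], med = med, high = ci[["high"]])
  }, numeric(4))
  expect_true(all(stats["low", ] <= stats["med", ]))
  expect_true(all(stats["med", ] <= stats["high", ]))
  expect_true(all(stats["obs", ] <= stats["high", ]))
  expect_gt(mean(stats["med", ] > stats["obs", ]), 0.8)
})
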