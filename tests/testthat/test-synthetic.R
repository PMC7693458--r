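# Synthetic reflectance generator and its null counterpart.

test_that("generator config validates its fields", {
  expect_error(generator_config(n_plants = 1), "at least 2")
  expect_error(generator_config(module_factor_sd = -0.1), "nonnegative")
  expect_error(generator_config(hue_jitter_sd = c(sepal_tip = 8)), "named by")
})

test_that("templates match the colour syndrome they emulate", {
  tmpl <- cattleya_templates()
  expect_named(tmpl, c("sepal_tip", "sepal_base", "petal_tip", "petal_base",
                       "labellum_tip", "labellum_base"))
  for (s in tmpl) expect_true(all(s$values >= 0 & s$values <= 1))
  # labellum base is yellow UV-absorbing: under 0.10 below 400 nm
  lb <- tmpl$labellum_base
  expect_true(all(lb$values[lb$wavelengths < 400] < 0.10))
  # and reflects in green-red, unlike the blue-reflecting pink patches
  expect_gt(lb$values[lb$wavelengths == 600], 0.5)
  st <- tmpl$sepal_tip
  expect_gt(st$values[st$wavelengths == 440],
            st$values[st$wavelengths == 540])
})

test_that("a default run yields 180 spectra and is byte-deterministic", {
  ds <- test_dataset()
  expect_length(ds$spectra, 180)
  expect_equal(nrow(ds$manifest), 180)
  expect_equal(sum(ds$manifest$structure == "labellum"), 60)
  ds2 <- generate_dataset(generator_config(seed = 7))
  expect_identical(ds$spectra, ds2$spectra)
  expect_identical(ds$truth$module_factors, ds2$truth$module_factors)
  # null generator: same determinism, no shared module factors
  n1 <- generate_null_dataset(generator_config(seed = 8))
  n2 <- generate_null_dataset(generator_config(seed = 8))
  expect_identical(n1$spectra, n2$spectra)
  expect_false(n1$truth$modular)
})

test_that("degenerate SDs collapse all plants onto the template", {
  cfg <- generator_config(n_plants = 3, seed = 9, module_factor_sd = 0,
                          patch_noise_sd = 0, measurement_noise_sd = 0,
                          hue_jitter_sd = c(sepal_tip = 0, sepal_base = 0,
                                            petal_tip = 0, petal_base = 0,
                                            labellum_tip = 0,
                                            labellum_base = 0))
  ds <- generate_dataset(cfg)
  tbl <- patch_colors(ds$spectra, ds$manifest, test_ctx(), locus = test_locus())
  d <- pairwise_distances(tbl)
  expect_equal(d$euclidean, rep(0, 6 * 3))
  expect_equal(d$angular, rep(0, 6 * 3))
})

test_that("two plants give 12 spectra and one pair per patch", {
  ds <- generate_dataset(generator_config(n_plants = 2, seed = 10))
  expect_length(ds$spectra, 12)
  tbl <- patch_colors(ds$spectra, ds$manifest, test_ctx(), locus = test_locus())
  expect_equal(nrow(pairwise_distances(tbl)), 6)
})

test_that("generated spectra satisfy the spectrum invariants and round-trip to disk", {
  ds <- generate_dataset(generator_config(n_plants = 2, seed = 11))
  for (s in ds$spectra) {
    expect_true(all(diff(s$wavelengths) > 0))
    expect_true(all(s$values >= 0 & s$values <= 1))
  }
  dir <- withr::local_tempdir()
  mpath <- write_dataset(ds, dir)
  back <- load_dataset(mpath)
  expect_equal(length(back$spectra), 12)
  expect_equal(back$manifest$plant_id, ds$manifest$plant_id)
  expect_equal(back$spectra[[1]]$values, ds$spectra[[1]]$values,
               tolerance = 1e-6)
})

test_that("modular generator plants within-module excitation covariance", {
  tbl <- test_patch_table()
  M <- normalize_excitations(tbl)
  C <- stats::cov(M)
  asg <- default_module_assignment()[colnames(M)]
  patch <- sub("\\.[^.]*$", "", colnames(M))
  same_mod <- outer(asg, asg, "==") & !outer(patch, patch, "==")
  diff_mod <- !outer(asg, asg, "==")
  off <- !diag(ncol(M))
  # among-patch correlation inside module 1 exceeds between-module correlation
  expect_gt(mean(abs(C[same_mod & off])), mean(abs(C[diff_mod & off])))
})
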