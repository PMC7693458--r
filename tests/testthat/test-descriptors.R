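# Spectrum locus, hue, contrast and spectral purity.

test_that("spectrum locus is a closed polygon of the right size around the origin", {
  locus <- test_locus()
  expect_equal(length(locus$wavelength), (700 - 300) / 1 + 1)
  r <- sqrt(locus$x^2 + locus$y^2)
  expect_true(all(r <= 1))
  expect_true(all(r > 0.1))
  # step selection must divide the grid
  locus5 <- build_spectrum_locus(test_ctx(), step = 5)
  expect_equal(length(locus5$wavelength), 81)
  expect_error(build_spectrum_locus(test_ctx(), step = 2.3), "step")
})

test_that("swapping UV and green receptors mirrors the locus across the y-axis", {
  ctx <- test_ctx()
  swapped <- viewing_context(receptors = list(uv = ctx$receptors$green,
                                              blue = ctx$receptors$blue,
                                              green = ctx$receptors$uv))
  loc <- build_spectrum_locus(ctx, step = 20)
  loc_sw <- build_spectrum_locus(swapped, step = 20)
  expect_equal(loc_sw$x, -loc$x, tolerance = 1e-6)
  expect_equal(loc_sw$y, loc$y, tolerance = 1e-6)
})

test_that("hue angle follows atan2 quadrants and flags near-origin loci", {
  expect_equal(hue_angle(1, 0), 0)
  expect_equal(hue_angle(0, 1), 90)
  expect_equal(hue_angle(-0.5, -0.5), 225)
  expect_true(is.na(hue_angle(1e-12, 0)))
})

test_that("chromatic contrast is the Euclidean norm", {
  expect_equal(chromatic_contrast(0, 0), 0)
  expect_equal(chromatic_contrast(0.3, 0.4), 0.5)
  expect_equal(chromatic_contrast(sqrt(3) / 2, -0.5), 1)
})

test_that("purity is the radius ratio along the hue ray", {
  locus <- test_locus()
  # locus vertices themselves are maximally pure
  i <- seq(1, length(locus$x), by = 25)
  expect_equal(as.numeric(spectral_purity(locus$x[i], locus$y[i], locus)),
               rep(1, length(i)), tolerance = 1e-9)
  # half-radius points have purity 1/2 wherever the boundary is
  # single-valued in hue; near both spectral ends the vertices bunch at
  # nearly constant hue and overhang the purple line, so the exact ratio
  # property is checked on the monotone 380-540 nm stretch
  j <- i[locus$wavelength[i] >= 380 & locus$wavelength[i] <= 540]
  expect_equal(as.numeric(spectral_purity(locus$x[j] / 2, locus$y[j] / 2, locus)),
               rep(0.5, length(j)), tolerance = 1e-9)
  expect_equal(as.numeric(spectral_purity(0, 0, locus)), 0)
})

test_that("axis rotation shifts hue by the rotation angle and leaves purity alone", {
  ctx <- test_ctx()
  ds <- test_dataset()
  ids <- ds$manifest$id[1:6]
  rot <- 30
  t0 <- patch_colors(ds$spectra[ids], ds$manifest[1:6, ], ctx,
                     locus = test_locus())
  t1 <- patch_colors(ds$spectra[ids], ds$manifest[1:6, ], ctx,
                     locus = build_spectrum_locus(ctx, rotation_deg = rot),
                     rotation_deg = rot)
  expect_equal(t1$purity, t0$purity, tolerance = 1e-6)
  expect_equal(t1$contrast, t0$contrast, tolerance = 1e-12)
  expect_equal((t1$hue_deg - t0$hue_deg) %% 360, rep(rot, 6), tolerance = 1e-9)
})

test_that("patch_colors assembles the tidy table with labels intact", {
  tbl <- test_patch_table()
  expect_s3_class(tbl, "patch_color_table")
  expect_equal(nrow(tbl), 180)
  expect_setequal(unique(tbl$patch),
                  c("sepal_tip", "sepal_base", "petal_tip", "petal_base",
                    "labellum_tip", "labellum_base"))
  expect_true(all(tbl$purity >= 0 & tbl$purity <= 1))
  expect_true(all(tbl$contrast >= 0))
  expect_equal(attr(tbl, "hue_undefined"), 0L)
  expect_error(patch_colors(test_dataset()$spectra,
                            test_dataset()$manifest[-1, c("plant_id", "structure",
                                                          "position")],
                            test_ctx()),
               "manifest must have columns")
})
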