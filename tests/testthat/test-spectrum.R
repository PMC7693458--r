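# Spectrum construction, file IO and resampling.

test_that("spectrum enforces its invariants", {
  s <- spectrum(400:500, seq(0.1, 0.3, length.out = 101))
  expect_s3_class(s, "spectrum")
  expect_error(spectrum(c(400, 400, 401), c(1, 1, 1)), "strictly increasing")
  expect_error(spectrum(c(401, 400), c(1, 1)), "strictly increasing")
  expect_error(spectrum(400:402, c(0.1, -0.1, 0.2)), "nonnegative")
  expect_error(spectrum(400:402, c(0.1, NA, 0.2)), "missing")
})

test_that("read_spectrum parses both dialects and both delimiters", {
  path <- withr::local_tempfile(fileext = ".csv")
  wl <- seq(300, 700, by = 10)
  writeLines(c("wavelength,reflectance",
               sprintf("%d,%.3f", wl, seq(0.10, 0.50, length.out = length(wl)))),
             path)
  s <- read_spectrum(path, dialect = "fraction")
  expect_equal(s$values[1], 0.10)
  expect_equal(length(s$wavelengths), length(wl))

  # percent dialect, tab-delimited, no header
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(sprintf("%d\t%.1f", wl, seq(10, 50, length.out = length(wl))), path2)
  s2 <- read_spectrum(path2, dialect = "percent")
  expect_equal(s2$values, s$values, tolerance = 1e-9)
})

test_that("read_spectrum drops out-of-range rows and validates order and size", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(sprintf("%d,0.2", c(180, 200, seq(300, 700, by = 10), 800))),
             path)
  expect_message(s <- read_spectrum(path, dialect = "fraction"),
                 "dropped 3 row")
  expect_equal(range(s$wavelengths), c(300, 700))

  path_dec <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("401,0.1", "400,0.2", sprintf("%d,0.2", seq(410, 500, 10))),
             path_dec)
  expect_error(read_spectrum(path_dec, dialect = "fraction"),
               "non-monotone|duplicated")

  path_small <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("400,0.10", "401,0.12"), path_small)
  expect_error(read_spectrum(path_small, dialect = "fraction"),
               "fewer than 10")
})

test_that("reflectance above 1 is flagged up to 1.2 and refused beyond", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%d,%.2f", seq(400, 500, 10), c(rep(0.5, 10), 1.1)), path)
  s <- read_spectrum(path, dialect = "fraction")
  expect_equal(attr(s, "over_unity"), 1L)
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%d,%.2f", seq(400, 500, 10), c(rep(0.5, 10), 1.5)), path2)
  expect_error(read_spectrum(path2, dialect = "fraction"), "exceeds 1.2")
})

test_that("write/read round trip reproduces values to 6 decimals", {
  set.seed(5)
  s <- rand_reflectance()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  s2 <- read_spectrum(path, dialect = "fraction")
  expect_equal(s2$values, s$values, tolerance = 1e-6)
  expect_equal(s2$wavelengths, s$wavelengths)
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  s <- spectrum(c(400, 500), c(0.0, 1.0))
  expect_equal(resample_spectrum(s, 450)$values, 0.5)
  expect_error(resample_spectrum(s, 300), "outside spectrum hull")
  expect_equal(resample_spectrum(s, c(300, 450), extrapolate = TRUE)$values,
               c(0.0, 0.5))
  # identity on own grid and idempotence
  set.seed(6)
  r <- rand_reflectance()
  expect_equal(resample_spectrum(r, r$wavelengths)$values, r$values)
  g <- seq(320, 680, by = 2.5)
  once <- resample_spectrum(r, g)
  twice <- resample_spectrum(once, g)
  expect_equal(twice$values, once$values)
  expect_true(all(once$values >= 0))
})
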