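# Spectrum container, validation, file IO and resampling.

#' Construct a spectrum
#'
#' A spectrum is a wavelength-indexed nonnegative curve: a reflectance (as a
#' fraction), a receptor spectral sensitivity (peak-normalised to 1), or a
#' relative irradiance. Wavelengths must be strictly increasing and values
#' nonnegative with no missing entries.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param values Numeric vector of the same length, nonnegative.
#' @param kind One of `"reflectance"`, `"sensitivity"`, `"irradiance"`; purely
#'   descriptive metadata.
#' @return An object of class `spectrum`: a list with elements `wavelengths`,
#'   `values` and `kind`.
#' @examples
#' s <- spectrum(400:500, seq(0.1, 0.3, length.out = 101))
#' s
#' @export
spectrum <- function(wavelengths, values,
                     kind = c("reflectance", "sensitivity", "irradiance")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values must have the same length")
  if (anyNA(wavelengths) || anyNA(values))
    stop("spectrum must not contain missing values")
  bad <- which(diff(wavelengths) <= 0)
  if (length(bad))
    stop(sprintf("wavelengths must be strictly increasing (violated at row %d: %g nm after %g nm)",
                 bad[1L] + 1L, wavelengths[bad[1L] + 1L], wavelengths[bad[1L]]))
  if (any(values < 0))
    stop(sprintf("spectrum values must be nonnegative (row %d is %g)",
                 which(values < 0)[1L], min(values)))
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm, values %.4g-%.4g>\n",
              x$kind, length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength = x$wavelengths, value = x$values)
}

#' Read a reflectance spectrum from a delimited text file
#'
#' Reads a two-column (wavelength nm, reflectance) plain-text export of a
#' field spectrophotometer. The delimiter (comma or tab) and presence of a
#' header row are auto-detected; the reflectance dialect is never guessed and
#' must be stated. Rows outside 250-750 nm are dropped (they fall far outside
#' the bee-visible range and instrument output there is unreliable).
#'
#' @param path Path to a text file (or a connection).
#' @param dialect `"fraction"` if reflectance is in `[0, 1]`, `"percent"` if
#'   in `[0, 100]` (divided by 100 on read).
#' @param wavelength_col,value_col Column indices holding wavelength and
#'   reflectance (defaults 1 and 2).
#' @return A [spectrum()] of kind `"reflectance"`. Values in `(1, 1.2]`
#'   (small instrument artifacts) are tolerated and flagged in the
#'   `"over_unity"` attribute; values above 1.2 are an error. The number of
#'   out-of-range rows dropped is recorded in the `"dropped_rows"` attribute.
#' @export
read_spectrum <- function(path, dialect = c("fraction", "percent"),
                          wavelength_col = 1L, value_col = 2L) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  sep <- if (lengths(regmatches(lines[1L], gregexpr("\t", lines[1L]))) >=
             lengths(regmatches(lines[1L], gregexpr(",", lines[1L])))) "\t" else ","
  first <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- utils::read.table(text = lines, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("spectrum file must have at least 2 numeric columns: ", path)
  wl <- suppressWarnings(as.numeric(df[[wavelength_col]]))
  val <- suppressWarnings(as.numeric(df[[value_col]]))
  if (anyNA(wl) || anyNA(val))
    stop(sprintf("non-numeric entry at row %d of %s",
                 which(is.na(wl) | is.na(val))[1L] + has_header, path))
  keep <- wl >= 250 & wl <= 750
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("read_spectrum: dropped %d row(s) outside 250-750 nm", dropped))
  wl <- wl[keep]; val <- val[keep]
  if (length(wl) < 10L)
    stop(sprintf("fewer than 10 usable rows (%d) in %s", length(wl), path))
  bad <- which(diff(wl) <= 0)
  if (length(bad))
    stop(sprintf("non-monotone or duplicated wavelengths at row %d of %s (%g nm after %g nm)",
                 bad[1L] + 1L + has_header, path, wl[bad[1L] + 1L], wl[bad[1L]]))
  if (dialect == "percent") val <- val / 100
  if (any(val > 1.2))
    stop(sprintf("reflectance value %.3f exceeds 1.2 at row %d; wrong dialect?",
                 max(val), which.max(val) + has_header))
  s <- spectrum(wl, val, kind = "reflectance")
  attr(s, "over_unity") <- sum(val > 1)
  attr(s, "dropped_rows") <- dropped
  s
}

#' Write a spectrum to a two-column CSV
#'
#' @param s A [spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly. Values are written with enough digits that a
#'   read/write round trip reproduces them to at least 6 decimals.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  df <- data.frame(wavelength = sprintf("%.6f", s$wavelengths),
                   reflectance = sprintf("%.8f", s$values))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = c("wavelength", "reflectance"))
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; extrapolation beyond the hull of the source grid is
#' refused unless explicitly enabled, in which case the end values are held
#' constant.
#'
#' @param s A [spectrum()].
#' @param grid Target wavelengths (strictly increasing).
#' @param extrapolate Allow constant-end extrapolation outside the hull.
#' @return A [spectrum()] on `grid`.
#' @export
resample_spectrum <- function(s, grid, extrapolate = FALSE) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  outside <- min(grid) < min(s$wavelengths) || max(grid) > max(s$wavelengths)
  if (outside && !extrapolate)
    stop(sprintf("target grid [%g, %g] outside spectrum hull [%g, %g]; set extrapolate = TRUE for constant-end extrapolation",
                 min(grid), max(grid), min(s$wavelengths), max(s$wavelengths)))
  v <- stats::approx(s$wavelengths, s$values, xout = grid, rule = 2)$y
  spectrum(grid, v, kind = s$kind)
}
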