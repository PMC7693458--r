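# Colour descriptors: hue angle, chromatic contrast, and spectral purity
# against the monochromatic spectrum locus.

#' Build the spectrum locus (maximal-purity boundary)
#'
#' The spectrum locus is the polyline traced in the hexagon by monochromatic
#' stimuli, closed between its short- and long-wavelength endpoints by the
#' purple line. Because receptor excitation is a saturating function of
#' intensity, the hexagon position of a monochromatic light depends on its
#' intensity; each vertex here is taken at the intensity that maximises the
#' distance from the background origin, i.e. the locus is the envelope of
#' monochromatic stimuli over all intensities — the maximal spectral purity
#' attainable at each hue. The resulting closed polygon strictly contains
#' the origin, so every hue ray meets the boundary exactly once.
#'
#' @param ctx A [viewing_context()].
#' @param step Wavelength step in nm between locus vertices; must divide the
#'   context grid spacing evenly (default 1).
#' @param rotation_deg Axis rotation, as in [hexagon_coords()].
#' @return An object of class `spectrum_locus`: a list with `wavelength`,
#'   `x`, `y` (polygon vertices in wavelength order), `step` and
#'   `rotation_deg`.
#' @export
build_spectrum_locus <- function(ctx, step = 1, rotation_deg = 0) {
  stopifnot(inherits(ctx, "viewing_context"))
  wl <- seq(min(ctx$grid), max(ctx$grid), by = step)
  if (!all(wl %in% ctx$grid))
    stop("step must select wavelengths present in the context grid")
  sens <- vapply(ctx$receptors, function(r) r$values, numeric(length(ctx$grid)))
  idx <- match(wl, ctx$grid)
  xy <- t(vapply(idx, function(i) {
    cvec <- sens[i, ] * ctx$illuminant$values[i] / ctx$bg_catch
    .mono_locus_point(cvec)
  }, numeric(2)))
  if (rotation_deg != 0) {
    th <- rotation_deg * pi / 180
    xy <- cbind(cos(th) * xy[, 1] - sin(th) * xy[, 2],
                sin(th) * xy[, 1] + cos(th) * xy[, 2])
  }
  if (!.point_in_polygon(0, 0, xy[, 1], xy[, 2]))
    stop("origin not strictly inside the spectrum locus polygon (degenerate viewing context)")
  structure(list(wavelength = wl, x = xy[, 1], y = xy[, 2], step = step,
                 rotation_deg = rotation_deg),
            class = "spectrum_locus")
}

#' Radius-maximising hexagon point of a monochromatic stimulus with
#' per-receptor catch coefficients cvec (catch = intensity * cvec)
#' @noRd
.mono_locus_point <- function(cvec) {
  f <- function(u) {
    p <- exp(u) * cvec
    e <- p / (p + 1)
    x <- sqrt(3) / 2 * (e[3L] - e[1L])
    y <- e[2L] - (e[1L] + e[3L]) / 2
    x * x + y * y
  }
  u0 <- -log(max(cvec))   # intensity at which the largest catch equals 1
  opt <- stats::optimize(f, interval = u0 + c(-10, 14), maximum = TRUE,
                         tol = 1e-8)
  p <- exp(opt$maximum) * cvec
  e <- p / (p + 1)
  c(sqrt(3) / 2 * (e[3L] - e[1L]), e[2L] - (e[1L] + e[3L]) / 2)
}

#' Crossing-number point-in-polygon test
#' @noRd
.point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  crosses <- ((vy > py) != (vy[j] > py)) &
    (px < (vx[j] - vx) * (py - vy) / (vy[j] - vy) + vx)
  sum(crosses) %% 2L == 1L
}

#' @export
print.spectrum_locus <- function(x, ...) {
  cat(sprintf("<spectrum_locus: %d vertices, %g-%g nm, step %g nm, radii %.3f-%.3f>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$step, min(sqrt(x$x^2 + x$y^2)), max(sqrt(x$x^2 + x$y^2))))
  invisible(x)
}

#' Hue angle of a colour locus
#'
#' Angle of the locus measured counterclockwise from the positive x-axis
#' through the hexagon centre, in degrees within `[0, 360)`. Loci closer to
#' the origin than `1e-9` hexagon units have no defined hue and return `NA`.
#'
#' @param x,y Hexagon coordinates (vectorised).
#' @return Numeric vector of degrees, `NA` where hue is undefined.
#' @export
hue_angle <- function(x, y) {
  r <- sqrt(x^2 + y^2)
  out <- (atan2(y, x) * 180 / pi) %% 360
  out[out >= 360 - 1e-9] <- 0   # keep the range right-open at 360
  out[r < 1e-9] <- NA_real_
  out
}

#' Chromatic contrast of a colour locus
#'
#' Euclidean distance from the hexagon centre (the locus of the adapting
#' green background), in hexagon units — the model's proxy for detectability
#' against the background.
#'
#' @param x,y Hexagon coordinates (vectorised).
#' @return Nonnegative numeric vector.
#' @export
chromatic_contrast <- function(x, y) sqrt(x^2 + y^2)

#' Spectral purity of a colour locus
#'
#' The radius of the locus divided by the radius of the spectrum-locus
#' boundary along the same hue ray (found by ray/segment intersection with
#' linear interpolation along the polygon edge). Purity is 0 for the
#' background origin by convention, 1 for points on the boundary, and is
#' clamped to `[0, 1]`; the number of clamped points is recorded in the
#' `"clamped"` attribute.
#'
#' @param x,y Hexagon coordinates (vectorised).
#' @param locus A [build_spectrum_locus()] result.
#' @return Numeric vector in `[0, 1]`.
#' @export
spectral_purity <- function(x, y, locus) {
  stopifnot(inherits(locus, "spectrum_locus"))
  r <- sqrt(x^2 + y^2)
  out <- numeric(length(r))
  clamped <- 0L
  nz <- which(r >= 1e-9)
  for (i in nz) {
    rb <- .boundary_radius(x[i] / r[i], y[i] / r[i], locus$x, locus$y)
    p <- r[i] / rb
    if (p > 1) clamped <- clamped + 1L
    out[i] <- min(p, 1)
  }
  attr(out, "clamped") <- clamped
  out
}

#' Distance from origin to a closed polygon along the unit ray (dx, dy)
#' @noRd
.boundary_radius <- function(dx, dy, vx, vy) {
  n <- length(vx)
  ax <- vx; ay <- vy
  bx <- c(vx[-1L], vx[1L]); by <- c(vy[-1L], vy[1L])
  ex <- bx - ax; ey <- by - ay
  denom <- dx * ey - dy * ex          # cross(d, e)
  ok <- abs(denom) > 1e-14
  t <- (ax * ey - ay * ex) / denom    # cross(A, e) / cross(d, e)
  s <- (ax * dy - ay * dx) / denom    # solves A + s e = t d
  hit <- ok & s >= -1e-12 & s <= 1 + 1e-12 & t > 1e-12
  if (!any(hit))
    stop("internal error: hue ray does not intersect the spectrum locus")
  min(t[hit])
}

#' Patch colour table: excitations and colour descriptors per floral patch
#'
#' Runs every spectrum of a dataset through the vision model and the colour
#' descriptors, producing the tidy table that all downstream statistics
#' consume: one row per plant x patch with excitations, hexagon coordinates,
#' hue, spectral purity and chromatic contrast.
#'
#' @param spectra Named list of [spectrum()] objects (names matched against
#'   `manifest$id`).
#' @param manifest Data frame with columns `id`, `plant_id`, `structure`
#'   (sepal/petal/labellum) and `position` (tip/base).
#' @param ctx A [viewing_context()].
#' @param locus Optional precomputed [build_spectrum_locus()]; built at 1 nm
#'   from `ctx` when `NULL`.
#' @param rotation_deg Axis rotation applied consistently to coordinates and
#'   the locus.
#' @return A data frame of class `patch_color_table` with columns `plant_id`,
#'   `structure`, `position`, `patch`, `e_uv`, `e_blue`, `e_green`, `x`, `y`,
#'   `hue_deg`, `purity`, `contrast`. The count of hue-undefined rows is in
#'   the `"hue_undefined"` attribute.
#' @export
patch_colors <- function(spectra, manifest, ctx, locus = NULL,
                         rotation_deg = 0) {
  stopifnot(inherits(ctx, "viewing_context"), is.data.frame(manifest))
  need <- c("id", "plant_id", "structure", "position")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(manifest$id, names(spectra))
  if (length(miss))
    stop("manifest rows without spectra: ", paste(utils::head(miss, 3), collapse = ", "))
  if (is.null(locus)) locus <- build_spectrum_locus(ctx, rotation_deg = rotation_deg)
  M <- vapply(manifest$id, function(id) {
    s <- spectra[[id]]
    if (!.same_grid(s$wavelengths, ctx$grid)) s <- resample_spectrum(s, ctx$grid)
    s$values
  }, numeric(length(ctx$grid)))
  e <- .excitation_matrix(ctx, M)
  xy <- hexagon_coords(e, rotation_deg = rotation_deg)
  hue <- hue_angle(xy[, 1], xy[, 2])
  pur <- spectral_purity(xy[, 1], xy[, 2], locus)
  out <- data.frame(plant_id = as.character(manifest$plant_id),
                    structure = as.character(manifest$structure),
                    position = as.character(manifest$position),
                    patch = .patch_name(manifest$structure, manifest$position),
                    e_uv = e[, 1], e_blue = e[, 2], e_green = e[, 3],
                    x = xy[, 1], y = xy[, 2],
                    hue_deg = hue, purity = as.numeric(pur),
                    contrast = chromatic_contrast(xy[, 1], xy[, 2]),
                    row.names = NULL)
  class(out) <- c("patch_color_table", "data.frame")
  attr(out, "hue_undefined") <- sum(is.na(hue))
  attr(out, "purity_clamped") <- attr(pur, "clamped")
  out
}
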