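# Bee colour-vision model: quantum catch, von Kries adaptation, receptor
# excitation, and hexagon chromaticity coordinates.
#
# The model is the noise-free hexagon colour space for trichromatic bees.
# For receptor i with sensitivity S_i(lambda), stimulus reflectance
# I_S(lambda), background reflectance I_B(lambda) and illuminant D(lambda):
#
#   raw catch   Q_i = integral I_S(l) S_i(l) D(l) dl        (trapezoid rule)
#   adaptation  P_i = Q_i / integral I_B(l) S_i(l) D(l) dl  (von Kries)
#   excitation  E_i = P_i / (P_i + 1)                       (bounded in [0,1))
#
# so the adapting background yields P_i = 1 and E_i = 0.5 in every receptor.
# Hexagon coordinates place the background at the origin:
#
#   x = (sqrt(3)/2) (E_green - E_uv)
#   y = E_blue - (E_uv + E_green)/2

#' Raw quantum catch of one receptor
#'
#' Trapezoid integral of stimulus x sensitivity x illuminant over the common
#' wavelength grid. All three spectra must be defined on identical grids.
#'
#' @param stimulus,sensitivity,illuminant [spectrum()] objects on one grid.
#' @return Nonnegative scalar catch.
#' @export
raw_catch <- function(stimulus, sensitivity, illuminant) {
  stopifnot(inherits(stimulus, "spectrum"), inherits(sensitivity, "spectrum"),
            inherits(illuminant, "spectrum"))
  if (!.same_grid(stimulus$wavelengths, sensitivity$wavelengths) ||
      !.same_grid(stimulus$wavelengths, illuminant$wavelengths))
    stop("stimulus, sensitivity and illuminant must share one wavelength grid")
  w <- .trapezoid_weights(stimulus$wavelengths)
  sum(w * stimulus$values * sensitivity$values * illuminant$values)
}

#' Photoreceptor excitations of a stimulus
#'
#' Maps a reflectance spectrum to the UV/blue/green excitation triple
#' `E_i = P_i / (P_i + 1)` with the von Kries adapted catch
#' `P_i = Q_i(stimulus) / Q_i(background)`. A stimulus identical to the
#' background excites all receptors at exactly 0.5.
#'
#' @param stimulus A [spectrum()] on the context grid.
#' @param ctx A [viewing_context()].
#' @return Named numeric vector `c(uv=, blue=, green=)`, each in `[0, 1)`.
#' @export
excitation_triple <- function(stimulus, ctx) {
  stopifnot(inherits(ctx, "viewing_context"))
  if (!.same_grid(stimulus$wavelengths, ctx$grid))
    stop("stimulus is not on the context grid; resample_spectrum() it first")
  drop(.excitation_matrix(ctx, matrix(stimulus$values, ncol = 1L)))
}

#' Vectorised excitation computation; M is length(grid) x n stimuli
#' @noRd
.excitation_matrix <- function(ctx, M) {
  ws <- vapply(ctx$receptors, function(r)
    ctx$weights * r$values * ctx$illuminant$values,
    numeric(length(ctx$grid)))          # grid x 3
  q <- t(M) %*% ws                      # n x 3 raw catches
  p <- sweep(q, 2L, ctx$bg_catch, "/")  # adapted catches
  e <- p / (p + 1)
  colnames(e) <- .RECEPTORS
  e
}

#' Hexagon chromaticity coordinates
#'
#' Projects an excitation triple into the 2-D hexagon colour space. The
#' adapting background (all excitations 0.5) maps to the origin; pure single
#' receptor excitation maps to a hexagon vertex at radius 1. The x-axis runs
#' from the UV vertex toward the green vertex; an optional rotation of the
#' axes is exposed because hue *angles* (though no angular or Euclidean
#' *distances*) depend on the axis convention.
#'
#' @param e Excitation triple `c(uv, blue, green)` or an n x 3 matrix.
#' @param rotation_deg Counterclockwise rotation of the coordinate axes.
#' @return Numeric `c(x, y)`, or an n x 2 matrix for matrix input.
#' @examples
#' hexagon_coords(c(0.5, 0.5, 0.5))  # origin
#' hexagon_coords(c(0, 1, 0))        # blue vertex (0, 1)
#' @export
hexagon_coords <- function(e, rotation_deg = 0) {
  m <- if (is.matrix(e)) e else matrix(e, ncol = 3L)
  if (ncol(m) != 3L) stop("excitations must have three components (uv, blue, green)")
  if (any(m < 0 | m >= 1 + 1e-12))
    stop("excitations must lie in [0, 1)")
  x <- sqrt(3) / 2 * (m[, 3L] - m[, 1L])
  y <- m[, 2L] - (m[, 1L] + m[, 3L]) / 2
  if (rotation_deg != 0) {
    th <- rotation_deg * pi / 180
    xr <- cos(th) * x - sin(th) * y
    y <- sin(th) * x + cos(th) * y
    x <- xr
  }
  out <- cbind(x = x, y = y)
  if (is.matrix(e)) out else drop(out)
}
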