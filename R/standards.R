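# Packaged standard curves: D65 daylight, a parametric green-leaf background,
# and the A1 visual-pigment nomogram used for bee receptor sensitivities.

# CIE standard illuminant D65, relative spectral power distribution at 10 nm
# steps over 300-700 nm (relative units, 100 at 560 nm by convention).
.D65_WL <- seq(300, 700, by = 10)
.D65_SPD <- c(
    0.0341,   3.2945,  20.2360,  37.0535,  39.9488,
   44.9117,  46.6383,  52.0891,  49.9755,  54.6482,
   82.7549,  91.4860,  93.4318,  86.6823, 104.8650,
  117.0080, 117.8120, 114.8610, 115.9230, 108.8110,
  109.3540, 107.8020, 104.7900, 107.6890, 104.4050,
  104.0460, 100.0000,  96.3342,  95.7880,  88.6856,
   90.0062,  89.5991,  87.6987,  83.2886,  83.6992,
   80.0268,  80.2146,  82.2778,  78.2842,  69.7213,
   71.6091)

#' Packaged standard curves
#'
#' Returns one of the standard curves packaged with hexflora, resampled onto
#' the requested grid:
#'
#' * `"D65"` — the CIE standard daylight illuminant, linearly interpolated
#'   from the packaged 10 nm table and normalised to 100 at 560 nm.
#' * `"green_leaf"` — a parametric green-foliage reflectance standard used as
#'   the chromatic adaptation background:
#'   `R(lambda) = 0.04 + 0.10 exp(-((lambda - 550)/40)^2) +
#'    0.05 / (1 + exp(-(lambda - 680)/12))`,
#'   i.e. low UV/blue reflectance, a green peak near 550 nm and a moderate
#'   far-red rise. It is a documented stand-in, not a measurement of any
#'   particular leaf; users can supply their own background spectrum to
#'   [viewing_context()].
#'
#' @param name `"D65"` or `"green_leaf"`.
#' @param grid Wavelengths (nm) to evaluate on; must lie within 300-700 nm.
#' @return A [spectrum()].
#' @export
standard_curves <- function(name, grid = 300:700) {
  available <- c("D65", "green_leaf")
  if (length(name) != 1L || !name %in% available)
    stop("unknown curve '", paste(name, collapse = ","),
         "'; available: ", paste(available, collapse = ", "))
  grid <- as.numeric(grid)
  if (min(grid) < 300 || max(grid) > 700)
    stop("grid must lie within 300-700 nm for packaged curves")
  if (name == "D65") {
    v <- stats::approx(.D65_WL, .D65_SPD, xout = grid, rule = 2)$y
    at560 <- stats::approx(.D65_WL, .D65_SPD, xout = 560)$y
    spectrum(grid, v / at560 * 100, kind = "irradiance")
  } else {
    v <- 0.04 + 0.10 * exp(-((grid - 550) / 40)^2) +
      0.05 / (1 + exp(-(grid - 680) / 12))
    spectrum(grid, v, kind = "reflectance")
  }
}

#' Visual-pigment sensitivity template
#'
#' Builds a photoreceptor spectral sensitivity from the A1 visual-pigment
#' alpha-band template of Govardovskii et al. (2000), parameterised only by
#' the wavelength of peak absorbance. An optional beta-band can be added;
#' it is off by default. The curve is normalised to a maximum of 1, attained
#' at the grid point nearest `lambda_max`.
#'
#' @param lambda_max Peak wavelength in nm, within 300-700.
#' @param grid Wavelengths (nm) to evaluate on.
#' @param beta Include the beta-band term.
#' @return A [spectrum()] of kind `"sensitivity"`.
#' @export
receptor_template <- function(lambda_max, grid = 300:700, beta = FALSE) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L ||
      lambda_max < 300 || lambda_max > 700)
    stop("lambda_max must be a single wavelength within 300-700 nm")
  grid <- as.numeric(grid)
  alpha_band <- function(wl) {
    x <- lambda_max / wl
    a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
    1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
         exp(-14.9 * (1.104 - x)) + 0.674)
  }
  # the alpha-band maximum sits within ~1 nm of lambda_max; shift the curve
  # so the peak lies exactly at lambda_max, as documented
  fine <- seq(lambda_max - 15, lambda_max + 15, by = 0.01)
  offset <- fine[which.max(alpha_band(fine))] - lambda_max
  s <- alpha_band(pmax(grid + offset, 1))
  if (beta) {
    lam_b <- 189 + 0.315 * lambda_max
    bw <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((grid + offset - lam_b) / bw)^2)
  }
  spectrum(grid, s / max(s), kind = "sensitivity")
}

#' Bee photoreceptor sensitivity triple
#'
#' The UV, blue and green receptor sensitivities of a trichromatic bee,
#' built from [receptor_template()]. The default peak wavelengths
#' (328, 428, 536 nm) follow measured *Bombus terrestris* sensitivities.
#'
#' @param grid Wavelengths (nm).
#' @param lambda_max Numeric length-3 vector of peak wavelengths, ordered
#'   UV, blue, green (strictly increasing).
#' @param beta Passed to [receptor_template()].
#' @return Named list of three [spectrum()] objects: `uv`, `blue`, `green`.
#' @export
bee_receptors <- function(grid = 300:700, lambda_max = c(328, 428, 536),
                          beta = FALSE) {
  if (length(lambda_max) != 3L || any(diff(lambda_max) <= 0))
    stop("lambda_max must be three increasing peaks ordered UV, blue, green")
  out <- lapply(lambda_max, receptor_template, grid = grid, beta = beta)
  names(out) <- .RECEPTORS
  out
}

#' Assemble a viewing context
#'
#' A viewing context bundles everything needed to map a reflectance spectrum
#' to a colour locus: the illuminant, the adaptation background, the three
#' receptor sensitivities, and the common wavelength grid. All curves are
#' resampled onto the grid at construction, and the background quantum catch
#' of each receptor (the von Kries denominator) is precomputed.
#'
#' @param grid Common wavelength grid in nm (default 300-700 at 1 nm, the
#'   bee-visible range).
#' @param illuminant A [spectrum()], or `NULL` for the packaged D65.
#' @param background A [spectrum()], or `NULL` for the packaged green leaf.
#' @param lambda_max Receptor peak wavelengths, passed to [bee_receptors()]
#'   when `receptors` is `NULL`.
#' @param receptors Optional named list (`uv`, `blue`, `green`) of
#'   [spectrum()] sensitivities overriding the nomogram.
#' @param beta Passed to [bee_receptors()].
#' @return An object of class `viewing_context`.
#' @examples
#' ctx <- viewing_context()
#' ctx
#' @export
viewing_context <- function(grid = 300:700, illuminant = NULL,
                            background = NULL,
                            lambda_max = c(328, 428, 536),
                            receptors = NULL, beta = FALSE) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (min(grid) > 300 || max(grid) < 700)
    stop("grid must span at least 300-700 nm")
  illuminant <- if (is.null(illuminant)) standard_curves("D65", grid)
                else resample_spectrum(illuminant, grid)
  background <- if (is.null(background)) standard_curves("green_leaf", grid)
                else resample_spectrum(background, grid)
  if (is.null(receptors)) {
    receptors <- bee_receptors(grid, lambda_max = lambda_max, beta = beta)
  } else {
    if (!identical(names(receptors), .RECEPTORS))
      stop("receptors must be a named list: uv, blue, green (in that order)")
    receptors <- lapply(receptors, resample_spectrum, grid = grid)
  }
  w <- .trapezoid_weights(grid)
  bg_catch <- vapply(receptors, function(r)
    sum(w * background$values * r$values * illuminant$values), numeric(1))
  if (any(bg_catch <= 0))
    stop("background quantum catch is zero for receptor(s): ",
         paste(names(bg_catch)[bg_catch <= 0], collapse = ", "),
         " (degenerate adaptation)")
  structure(list(grid = grid, illuminant = illuminant,
                 background = background, receptors = receptors,
                 weights = w, bg_catch = bg_catch,
                 lambda_max = vapply(receptors, function(r)
                   r$wavelengths[which.max(r$values)], numeric(1))),
            class = "viewing_context")
}

#' @export
print.viewing_context <- function(x, ...) {
  cat(sprintf("<viewing_context: grid %g-%g nm (%d pts), receptor peaks %s nm>\n",
              min(x$grid), max(x$grid), length(x$grid),
              paste(vapply(x$receptors, function(r)
                r$wavelengths[which.max(r$values)], numeric(1)),
                collapse = "/")))
  invisible(x)
}
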