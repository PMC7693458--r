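# Seeded generator of synthetic orchid-like floral reflectance datasets with
# planted modular covariance, plus a matched non-modular null generator.
#
# Each of the six floral patches has a parametric reflectance template
# (baseline + pigment absorption bands). Among-plant variation enters
# through (i) a latent pigment-amplitude factor shared by all patches of an
# intrafloral module — the mechanistic stand-in for module-specific pigment
# regulation — (ii) an independent patch-specific amplitude perturbation,
# (iii) a patch-specific shift of the band centres (hue jitter), and (iv)
# iid measurement noise per wavelength. The null generator replaces the
# shared module factors with independent per-patch factors of identical
# total variance, equalising the marginal structure while removing the
# planted among-patch covariance.

#' Generator configuration
#'
#' Frozen defaults emulate the study conditions of a Cattleya-like orchid:
#' 30 plants x 6 patches, pink sepals/petals reflecting in blue and red, a
#' more saturated UV-blue-shifted labellum tip, a yellow UV-absorbing
#' labellum base, lowest hue jitter in the labellum base, and a module
#' factor SD twice the patch noise SD (so within-module covariation
#' dominates among-module covariation).
#'
#' @param n_plants Number of plants (>= 2; default 30).
#' @param seed Integer seed; every draw of the generator descends from it.
#' @param module_factor_sd SD of the shared per-module amplitude factor.
#' @param patch_noise_sd SD of the independent per-patch amplitude noise.
#' @param measurement_noise_sd SD of iid per-wavelength reflectance noise.
#' @param hue_jitter_sd Named numeric vector (nm), band-centre jitter SD per
#'   patch; the labellum base default is the smallest.
#' @param grid Working wavelength grid (nm).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_plants = 30L, seed = 1L,
                             module_factor_sd = 0.10,
                             patch_noise_sd = 0.05,
                             measurement_noise_sd = 0.004,
                             hue_jitter_sd = c(sepal_tip = 8, sepal_base = 8,
                                               petal_tip = 8, petal_base = 8,
                                               labellum_tip = 2,
                                               labellum_base = 1.5),
                             grid = 300:700) {
  if (n_plants < 2L) stop("n_plants must be at least 2")
  if (any(c(module_factor_sd, patch_noise_sd, measurement_noise_sd) < 0))
    stop("all SDs must be nonnegative")
  if (!setequal(names(hue_jitter_sd), .PATCHES))
    stop("hue_jitter_sd must be named by the six patches")
  if (any(hue_jitter_sd < 0)) stop("all SDs must be nonnegative")
  structure(list(n_plants = as.integer(n_plants), seed = seed,
                 module_factor_sd = module_factor_sd,
                 patch_noise_sd = patch_noise_sd,
                 measurement_noise_sd = measurement_noise_sd,
                 hue_jitter_sd = hue_jitter_sd[.PATCHES],
                 grid = as.numeric(grid)),
            class = "generator_config")
}

# Template parameters per patch: baseline + chromatic components. Pink
# patches carry a Gaussian blue band plus a sigmoidal red rise; the
# labellum tip has larger amplitudes (higher purity) shifted toward
# UV-blue; the labellum base is a yellow UV-absorber with a green-edge
# sigmoid only.
.cattleya_params <- function() {
  gauss <- function(center, width, amp) list(type = "gauss", center = center,
                                             width = width, amp = amp)
  sigm <- function(center, scale, amp) list(type = "sigmoid", center = center,
                                            scale = scale, amp = amp)
  list(
    sepal_tip     = list(base = 0.06, bands = list(gauss(440, 35, 0.13),
                                                   sigm(620, 12, 0.22))),
    sepal_base    = list(base = 0.06, bands = list(gauss(440, 35, 0.11),
                                                   sigm(620, 12, 0.20))),
    petal_tip     = list(base = 0.06, bands = list(gauss(440, 35, 0.15),
                                                   sigm(620, 12, 0.24))),
    petal_base    = list(base = 0.06, bands = list(gauss(440, 35, 0.09),
                                                   sigm(620, 12, 0.18))),
    labellum_tip  = list(base = 0.04, bands = list(gauss(425, 40, 0.40),
                                                   sigm(615, 12, 0.42))),
    labellum_base = list(base = 0.03, bands = list(sigm(520, 18, 0.60)))
  )
}

#' Evaluate a template with amplitude multiplier and band-centre shift
#' @noRd
.template_eval <- function(par, grid, amp_mult = 1, shift = 0) {
  v <- rep(par$base, length(grid))
  for (b in par$bands) {
    shape <- if (b$type == "gauss")
      exp(-((grid - (b$center + shift)) / b$width)^2)
    else
      1 / (1 + exp(-(grid - (b$center + shift)) / b$scale))
    v <- v + amp_mult * b$amp * shape
  }
  v
}

#' Reflectance templates of the six floral patches
#'
#' The noiseless patch templates used by the generator, evaluated on a grid.
#'
#' @param grid Wavelength grid spanning 300-700 nm.
#' @return Named list of six [spectrum()] objects (canonical patch order).
#' @export
cattleya_templates <- function(grid = 300:700) {
  grid <- as.numeric(grid)
  if (min(grid) > 300 || max(grid) < 700) stop("grid must span 300-700 nm")
  pars <- .cattleya_params()
  out <- lapply(pars, function(p) spectrum(grid, pmin(.template_eval(p, grid), 1)))
  out[.PATCHES]
}

#' Generate a synthetic floral reflectance dataset
#'
#' Draws, for every plant, one latent amplitude factor per intrafloral
#' module and builds each patch spectrum from its template deformed by the
#' module factor, patch-level amplitude noise, patch-level hue jitter and
#' measurement noise. The planted module assignment is
#' sepals+petals / labellum tip / labellum base.
#'
#' @param config A [generator_config()].
#' @return List of class `floral_dataset`: `spectra` (named list of
#'   [spectrum()]), `manifest` (data frame `id`, `plant_id`, `structure`,
#'   `position`), `truth` (module factors, patch multipliers, modular flag)
#'   and `config`. Negative reflectances produced by noise are clipped to 0
#'   and counted in `truth$n_clipped`.
#' @export
generate_dataset <- function(config = generator_config()) {
  .generate(config, modular = TRUE)
}

#' Generate a matched non-modular (null) dataset
#'
#' Identical marginal structure to [generate_dataset()], but every patch
#' receives its own independent amplitude factor with total SD
#' `sqrt(module_factor_sd^2 + patch_noise_sd^2)`, so no among-patch
#' covariance is planted.
#'
#' @param config A [generator_config()].
#' @return As [generate_dataset()].
#' @export
generate_null_dataset <- function(config = generator_config()) {
  .generate(config, modular = FALSE)
}

#' @noRd
.generate <- function(config, modular) {
  stopifnot(inherits(config, "generator_config"))
  grid <- config$grid
  pars <- .cattleya_params()
  patch_module <- c(sepal_tip = 1L, sepal_base = 1L, petal_tip = 1L,
                    petal_base = 1L, labellum_tip = 2L, labellum_base = 3L)
  .with_seed(config$seed, {
    n <- config$n_plants
    plant_ids <- sprintf("p%02d", seq_len(n))
    factors <- matrix(stats::rnorm(n * 3L), n, 3L,
                      dimnames = list(plant_ids, paste0("module", 1:3)))
    spectra <- vector("list", n * 6L)
    ids <- character(n * 6L)
    n_clipped <- 0L
    mult <- matrix(NA_real_, n, 6L, dimnames = list(plant_ids, .PATCHES))
    k <- 0L
    for (i in seq_len(n)) {
      for (pt in .PATCHES) {
        k <- k + 1L
        amp <- if (modular)
          1 + config$module_factor_sd * factors[i, patch_module[[pt]]] +
            config$patch_noise_sd * stats::rnorm(1)
        else
          1 + sqrt(config$module_factor_sd^2 + config$patch_noise_sd^2) *
            stats::rnorm(1)
        shift <- config$hue_jitter_sd[[pt]] * stats::rnorm(1)
        v <- .template_eval(pars[[pt]], grid, amp_mult = amp, shift = shift) +
          config$measurement_noise_sd * stats::rnorm(length(grid))
        n_clipped <- n_clipped + sum(v < 0)
        v <- pmin(pmax(v, 0), 1)
        ids[k] <- paste(plant_ids[i], pt, sep = "_")
        spectra[[k]] <- spectrum(grid, v)
        mult[i, pt] <- amp
      }
    }
    names(spectra) <- ids
    manifest <- data.frame(id = ids,
                           plant_id = rep(plant_ids, each = 6L),
                           structure = rep(.patch_structure(.PATCHES), n),
                           position = rep(.patch_position(.PATCHES), n),
                           row.names = NULL)
    structure(list(spectra = spectra, manifest = manifest,
                   truth = list(modular = modular, module_factors = factors,
                                amplitude_multipliers = mult,
                                patch_module = patch_module,
                                n_clipped = n_clipped),
                   config = config),
              class = "floral_dataset")
  })
}

#' @export
print.floral_dataset <- function(x, ...) {
  cat(sprintf("<floral_dataset: %d plants x 6 patches = %d spectra (%s), seed %s>\n",
              x$config$n_plants, length(x$spectra),
              if (x$truth$modular) "modular" else "null", x$config$seed))
  invisible(x)
}

#' Write a dataset as spectra CSVs plus a manifest
#'
#' Writes one two-column CSV per spectrum and a `manifest.csv` mapping file
#' to plant/structure/position — the same format [read_spectrum()] and
#' [load_dataset()] read back.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "floral_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, paste0(ds$manifest$id, ".csv"))
  for (i in seq_along(files)) write_spectrum(ds$spectra[[i]], files[i])
  manifest <- cbind(file = basename(files), ds$manifest)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Load a dataset from a manifest CSV
#'
#' @param manifest_path Path to a manifest CSV with columns `file`, `id`
#'   (optional; defaults to the file stem), `plant_id`, `structure`,
#'   `position`; `file` is resolved relative to the manifest directory.
#' @param dialect Reflectance dialect passed to [read_spectrum()].
#' @return List with `spectra` and `manifest`, as in [generate_dataset()].
#' @export
load_dataset <- function(manifest_path, dialect = "fraction") {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("file", "plant_id", "structure", "position")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (is.null(manifest$id))
    manifest$id <- sub("\\.[^.]*$", "", basename(manifest$file))
  dir <- dirname(manifest_path)
  spectra <- lapply(file.path(dir, manifest$file), read_spectrum,
                    dialect = dialect)
  names(spectra) <- manifest$id
  list(spectra = spectra, manifest = manifest[c("id", "plant_id",
                                                "structure", "position")])
}
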