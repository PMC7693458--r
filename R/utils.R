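# Internal helpers shared across modules.

#' Trapezoid quadrature weights for an arbitrary strictly increasing grid
#' @noRd
.trapezoid_weights <- function(grid) {
  n <- length(grid)
  if (n < 2L) stop("grid must have at least two points")
  d <- diff(grid)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-1L] + d[-(n - 1L)]) / 2
  w
}

#' Evaluate code under a temporary RNG seed, restoring global RNG state
#' @noRd
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number or NULL")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive k reproducible child seeds from one root seed (all < 2^31)
#' @noRd
.child_seeds <- function(seed, k) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Canonical patch bookkeeping used throughout the package ---------------------

.STRUCTURES <- c("sepal", "petal", "labellum")
.POSITIONS <- c("tip", "base")
.PATCHES <- c("sepal_tip", "sepal_base", "petal_tip", "petal_base",
              "labellum_tip", "labellum_base")
.RECEPTORS <- c("uv", "blue", "green")

.patch_name <- function(structure, position) paste(structure, position, sep = "_")

.patch_structure <- function(patch) sub("_(tip|base)$", "", patch)

.patch_position <- function(patch) sub("^.*_", "", patch)

#' Check two numeric vectors are the same grid
#' @noRd
.same_grid <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= tol)
}
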