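# Shared fixtures, built once per test run. Everything is generated in code;
# no data files.

.fixtures <- new.env()

test_ctx <- function() {
  if (is.null(.fixtures$ctx)) .fixtures$ctx <- viewing_context()
  .fixtures$ctx
}

test_locus <- function() {
  if (is.null(.fixtures$locus))
    .fixtures$locus <- build_spectrum_locus(test_ctx())
  .fixtures$locus
}

test_dataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- generate_dataset(generator_config(seed = 7))
  .fixtures$ds
}

test_patch_table <- function() {
  if (is.null(.fixtures$tbl)) {
    ds <- test_dataset()
    .fixtures$tbl <- patch_colors(ds$spectra, ds$manifest, test_ctx(),
                                  locus = test_locus())
  }
  .fixtures$tbl
}

# Smooth random reflectance: mixture of a few broad Gaussian bumps
rand_reflectance <- function(grid = 300:700) {
  v <- rep(stats::runif(1, 0.02, 0.1), length(grid))
  for (k in seq_len(sample(1:3, 1)))
    v <- v + stats::runif(1, 0.05, 0.3) *
      exp(-((grid - stats::runif(1, 320, 680)) / stats::runif(1, 25, 80))^2)
  spectrum(grid, pmin(v, 1))
}

# Independent brute-force covariance-ratio: builds the full covariance
# matrix element by element and sums products in explicit loops.
cr_oracle <- function(M, assignment) {
  n <- nrow(M); p <- ncol(M)
  mu <- colMeans(M)
  S <- matrix(0, p, p)
  for (a in 1:p) for (b in 1:p)
    S[a, b] <- sum((M[, a] - mu[a]) * (M[, b] - mu[b])) / (n - 1)
  mods <- sort(unique(as.integer(factor(assignment))))
  asg <- as.integer(factor(assignment))
  prs <- utils::combn(mods, 2)
  crs <- numeric(0)
  for (k in seq_len(ncol(prs))) {
    ia <- which(asg == prs[1, k]); ib <- which(asg == prs[2, k])
    num <- 0
    for (a in ia) for (b in ib) num <- num + S[a, b]^2
    d1 <- 0
    for (a in ia) for (b in ia) if (a != b) d1 <- d1 + S[a, b]^2
    d2 <- 0
    for (a in ib) for (b in ib) if (a != b) d2 <- d2 + S[a, b]^2
    crs <- c(crs, sqrt(num / sqrt(d1 * d2)))
  }
  mean(crs)
}

# Balanced patch-level table with a plant random effect, optional shift of
# the labellum tip in units of the within-plant SD (0.03).
sim_purity_table <- function(n_plants = 30, shift_sd = 0) {
  plants <- sprintf("p%02d", seq_len(n_plants))
  d <- expand.grid(plant_id = plants,
                   structure = c("sepal", "petal", "labellum"),
                   position = c("tip", "base"),
                   stringsAsFactors = FALSE)
  blk <- stats::rnorm(n_plants, 0, 0.05)
  d$purity <- 0.3 + blk[match(d$plant_id, plants)] +
    stats::rnorm(nrow(d), 0, 0.03) +
    ifelse(d$structure == "labellum" & d$position == "tip",
           shift_sd * 0.03, 0)
  d
}
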