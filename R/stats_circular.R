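# Circular statistics for hue angles: directional summaries, a von Mises
# sampler, the Watson-Williams one-way test, and Watson's two-sample U2
# test with a permutation null. Interfaces use degrees; radians internally.

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

#' Circular summary of a sample of angles
#'
#' Mean direction, mean resultant length and circular standard deviation of
#' a sample of angles in degrees. `NA` angles (undefined hues) are dropped.
#'
#' @param deg Numeric vector of angles in degrees.
#' @return List with `n`, `mean_deg`, `rbar` (mean resultant length in
#'   `[0, 1]`) and `sd_deg` (circular SD, `sqrt(-2 log rbar)` in degrees).
#' @export
circular_summary <- function(deg) {
  deg <- deg[!is.na(deg)]
  th <- .deg2rad(deg)
  n <- length(th)
  if (!n) return(list(n = 0L, mean_deg = NA_real_, rbar = NA_real_,
                      sd_deg = NA_real_))
  C <- sum(cos(th)); S <- sum(sin(th))
  rbar <- sqrt(C^2 + S^2) / n
  mean_deg <- (.rad2deg(atan2(S, C))) %% 360
  if (mean_deg >= 360 - 1e-9) mean_deg <- 0
  list(n = n, mean_deg = mean_deg, rbar = rbar,
       sd_deg = if (rbar > 0) .rad2deg(sqrt(-2 * log(rbar))) else Inf)
}

#' Maximum-likelihood concentration from a mean resultant length
#' (Fisher 1993 approximation to the inverse of A(kappa))
#' @noRd
.est_kappa <- function(rbar) {
  if (rbar < 0.53) 2 * rbar + rbar^3 + 5 * rbar^5 / 6
  else if (rbar < 0.85) -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  else 1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used by the simulation suites for circular
#' type-I-error and power studies.
#'
#' @param n Number of draws.
#' @param mu_deg Mean direction in degrees.
#' @param kappa Concentration (>= 0; 0 is the circular uniform).
#' @return Angles in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (kappa < 1e-10) return(stats::runif(n, 0, 360))
  mu <- .deg2rad(mu_deg)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1); u2 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
        u3 <- stats::runif(1)
        out[i] <- mu + sign(u3 - 0.5) * acos(f)
        break
      }
    }
  }
  .rad2deg(out) %% 360
}

#' Watson-Williams one-way test for equal mean directions
#'
#' High-concentration F test comparing mean hue directions among k groups,
#' with the standard concentration-dependent multiplicative correction
#' `1 + 3/(8 kappa)`. Assumes von Mises-like samples with common
#' concentration; a warning is issued when the estimated concentration falls
#' below 1, where the approximation degrades.
#'
#' @param hue_deg Angles in degrees (NA dropped with a count).
#' @param group Grouping vector, same length.
#' @return List of class `circular_test` with `method`, `statistic` (F),
#'   `df`, `p`, `kappa`, and per-group circular summaries.
#' @export
circular_anova <- function(hue_deg, group) {
  keep <- !is.na(hue_deg)
  dropped <- sum(!keep)
  if (dropped) message(sprintf("circular_anova: excluding %d undefined hue(s)", dropped))
  hue_deg <- hue_deg[keep]; group <- factor(group[keep])
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 defined hues")
  th <- .deg2rad(hue_deg)
  Ri <- tapply(seq_along(th), group, function(i)
    sqrt(sum(cos(th[i]))^2 + sum(sin(th[i]))^2))
  if (any(Ri / table(group) < 1e-8))
    stop("a group has mean resultant length ~0; mean direction undefined")
  N <- length(th); k <- nlevels(group)
  Rsum <- sum(Ri)
  R <- sqrt(sum(cos(th))^2 + sum(sin(th))^2)
  kappa <- .est_kappa(Rsum / N)
  if (kappa < 1)
    warning("estimated concentration below 1; Watson-Williams F is unreliable")
  g <- 1 + 3 / (8 * kappa)
  denom <- N - Rsum
  Fstat <- if (denom < 1e-12) {
    if (Rsum - R < 1e-12) 0 else Inf
  } else g * ((N - k) * (Rsum - R)) / ((k - 1) * denom)
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  summaries <- lapply(split(hue_deg, group), circular_summary)
  structure(list(method = "Watson-Williams one-way test",
                 statistic = c(F = unname(Fstat)), df = c(k - 1, N - k),
                 p = p, kappa = kappa, groups = summaries,
                 n_excluded = dropped),
            class = "circular_test")
}

#' Watson's two-sample U2 test of homogeneity
#'
#' Nonparametric comparison of two samples of angles based on the squared
#' difference of their empirical CDFs around the circle (origin-invariant).
#' The p-value is obtained from a seeded random-permutation null rather than
#' critical-value tables, so significance can be assessed at levels finer
#' than the tables print (e.g. the conservative 0.001 used for post hoc hue
#' comparisons).
#'
#' @param a_deg,b_deg Samples of angles in degrees (each n >= 8).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Seed for the permutation null (local to this call).
#' @param level Significance level for the rejection flag (default 0.001).
#' @return List of class `circular_test` with `statistic` (U2), `p`,
#'   `reject`, `n_perm` and `seed`.
#' @export
watson_u2 <- function(a_deg, b_deg, n_perm = 10000, seed = NULL,
                      level = 0.001) {
  a_deg <- a_deg[!is.na(a_deg)]; b_deg <- b_deg[!is.na(b_deg)]
  n <- length(a_deg); m <- length(b_deg)
  if (n < 8L || m < 8L)
    stop("watson_u2 requires at least 8 defined angles per sample")
  obs <- .watson_u2_stat(a_deg, b_deg)
  pooled <- c(a_deg, b_deg)
  perm <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n + m, n)
    .watson_u2_stat(pooled[idx], pooled[-idx])
  }, numeric(1)))
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  structure(list(method = "Watson two-sample U2 (permutation)",
                 statistic = c(U2 = obs), p = p, reject = p <= level,
                 level = level, n_perm = n_perm, seed = seed,
                 n = c(n, m)),
            class = "circular_test")
}

#' U2 statistic via tie-aware pooled empirical CDF differences
#' @noRd
.watson_u2_stat <- function(a, b) {
  n <- length(a); m <- length(b); N <- n + m
  v <- sort(unique(c(a, b)))
  ca <- cumsum(tabulate(match(a, v), length(v))) / n
  cb <- cumsum(tabulate(match(b, v), length(v))) / m
  tj <- tabulate(match(c(a, b), v), length(v))
  d <- ca - cb
  dbar <- sum(tj * d) / N
  n * m / N^2 * sum(tj * (d - dbar)^2)
}

#' @export
print.circular_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g", x$method, names(x$statistic), x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = (%s)", paste(x$df, collapse = ", ")))
  cat(sprintf(", p = %.4g\n", x$p))
  invisible(x)
}
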