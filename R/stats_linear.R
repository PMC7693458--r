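# Linear inferential statistics: complete-block ANOVAs, paired patch
# comparisons with FDR control, and the Benjamini-Hochberg step-up rule.
#
# The among-plant designs here are balanced complete blocks (every plant, or
# every plant pair, contributes exactly one value per patch). For such
# designs the F tests of the randomized-complete-block ANOVA coincide
# exactly with those of the corresponding random-intercept mixed model, so
# the block ANOVA is used and imbalance is refused rather than silently
# approximated.

#' Complete-block ANOVA of a patch-level response
#'
#' Two-way (structure x position) ANOVA with plant as block, for a balanced
#' complete-block patch colour table: F tests for floral structure (df 2),
#' measurement position (df 1) and their interaction (df 2) against the
#' within-block residual. Under balance this is exactly the F test of the
#' model with a random plant intercept.
#'
#' @param tbl A [patch_colors()] table (or any data frame with `plant_id`,
#'   `structure`, `position` and the response column).
#' @param response Name of the response column (default `"purity"`).
#' @param block Name of the blocking column (default `"plant_id"`).
#' @return Data frame of class `anova_result` with columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p` (block and residual rows included; the
#'   block row carries no test).
#' @export
purity_block_anova <- function(tbl, response = "purity", block = "plant_id") {
  stopifnot(is.data.frame(tbl), response %in% names(tbl), block %in% names(tbl))
  cell <- table(tbl[[block]], paste(tbl$structure, tbl$position))
  if (any(cell != 1L))
    stop("design is not a balanced complete block (every plant must have each ",
         "structure x position exactly once); drop incomplete plants first")
  d <- data.frame(y = tbl[[response]],
                  blk = factor(tbl[[block]]),
                  structure = factor(tbl$structure, levels = .STRUCTURES),
                  position = factor(tbl$position, levels = .POSITIONS))
  fit <- stats::lm(y ~ blk + structure * position, data = d)
  # a perfect fit (all-equal responses) is handled explicitly below
  an <- withCallingHandlers(stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  out <- data.frame(term = c("block", "structure", "position",
                             "structure:position", "residuals"),
                    df = an$Df, sum_sq = an$`Sum Sq`, mean_sq = an$`Mean Sq`,
                    F = an$`F value`, p = an$`Pr(>F)`, row.names = NULL)
  out$F[c(1L, 5L)] <- NA_real_
  out$p[c(1L, 5L)] <- NA_real_
  # degenerate data with zero treatment sum of squares: F is 0, not 0/0
  zero <- which(out$sum_sq < 1e-20 & out$term %in%
                  c("structure", "position", "structure:position"))
  out$F[zero] <- 0
  out$p[zero] <- 1
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Paired post hoc comparisons between all floral patches
#'
#' Paired t tests (within plant) of a response between all 15 unordered
#' patch pairs, with Benjamini-Hochberg adjustment of the p-values and a
#' compact-letter display of the resulting groups. A pair whose within-plant
#' differences are all zero yields t = 0, p = 1; a pair with zero variance
#' around a nonzero mean difference cannot be tested and is flagged skipped.
#'
#' @param tbl A [patch_colors()] table with complete blocks.
#' @param response Response column name (default `"purity"`).
#' @param alpha FDR level for the rejection flags (default 0.05).
#' @return List of class `pairwise_result`: `comparisons` (data frame with
#'   `patch_a`, `patch_b`, `mean_diff`, `t`, `df`, `p`, `p_adj`, `reject`,
#'   `skipped`), `letters` (compact-letter display per patch) and `alpha`.
#' @export
pairwise_patch_tests <- function(tbl, response = "purity", alpha = 0.05) {
  stopifnot(is.data.frame(tbl), response %in% names(tbl))
  tbl$patch <- .patch_name(tbl$structure, tbl$position)
  cell <- table(tbl$plant_id, tbl$patch)
  if (any(cell != 1L))
    stop("design is not a balanced complete block; drop incomplete plants first")
  plants <- sort(unique(tbl$plant_id))
  wide <- vapply(.PATCHES, function(pt) {
    sub <- tbl[tbl$patch == pt, ]
    sub[[response]][match(plants, sub$plant_id)]
  }, numeric(length(plants)))
  pairs <- utils::combn(.PATCHES, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    d <- wide[, pairs[1L, k]] - wide[, pairs[2L, k]]
    if (stats::sd(d) < 1e-12) {
      if (abs(mean(d)) < 1e-12)
        data.frame(patch_a = pairs[1L, k], patch_b = pairs[2L, k],
                   mean_diff = 0, t = 0, df = length(d) - 1L, p = 1,
                   skipped = FALSE)
      else
        data.frame(patch_a = pairs[1L, k], patch_b = pairs[2L, k],
                   mean_diff = mean(d), t = NA_real_, df = length(d) - 1L,
                   p = NA_real_, skipped = TRUE)
    } else {
      tt <- stats::t.test(d)
      data.frame(patch_a = pairs[1L, k], patch_b = pairs[2L, k],
                 mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value, skipped = FALSE)
    }
  })
  cmp <- do.call(rbind, rows)
  adj <- bh_fdr(cmp$p[!cmp$skipped], q = alpha)
  cmp$p_adj <- NA_real_
  cmp$reject <- NA
  cmp$p_adj[!cmp$skipped] <- adj$adjusted
  cmp$reject[!cmp$skipped] <- adj$reject
  means <- colMeans(wide)
  letters <- .compact_letters(.PATCHES, cmp, means)
  structure(list(comparisons = cmp, letters = letters, means = means,
                 alpha = alpha, response = response),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("Paired patch comparisons of %s (BH-FDR at %.3g):\n",
              x$response, x$alpha))
  print(x$comparisons, digits = 4)
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-adjusted p-values with rejection flags at level `q`.
#' Thin, explicit wrapper around `stats::p.adjust(..., "BH")` so that the
#' rejection rule (adjusted p <= q) is applied in one documented place.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return List with `adjusted` (same length as `pvals`) and `reject`
#'   (logical). Empty input gives empty output.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}

#' Insert-and-absorb compact letter display from pairwise rejections
#' @noRd
.compact_letters <- function(levels, cmp, means) {
  sig <- cmp[!is.na(cmp$reject) & cmp$reject, c("patch_a", "patch_b")]
  groups <- list(levels)
  for (k in seq_len(nrow(sig))) {
    a <- sig$patch_a[k]; b <- sig$patch_b[k]
    new_groups <- list()
    for (g in groups) {
      if (a %in% g && b %in% g)
        new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
      else new_groups <- c(new_groups, list(g))
    }
    keep <- rep(TRUE, length(new_groups))
    for (i in seq_along(new_groups)) for (j in seq_along(new_groups))
      if (i != j && keep[i] && all(new_groups[[i]] %in% new_groups[[j]]) &&
          !identical(new_groups[[i]], new_groups[[j]])) keep[i] <- FALSE
    groups <- unique(new_groups[keep])
  }
  ord <- order(-means)
  out <- stats::setNames(rep("", length(levels)), levels)
  for (gi in seq_along(groups))
    for (lv in groups[[gi]]) out[lv] <- paste0(out[lv], letters[gi])
  out[ord][out[ord] == ""] <- "?"
  out
}

#' Complete-block ANOVA of square-root Euclidean distances
#'
#' Fits the among-pair colour-distance model: response is the square root of
#' the Euclidean distance between the loci of the same patch in two plants,
#' explanatory terms are floral structure, measurement position and their
#' interaction, and the plant pair is the block. Back-transformed
#' (squared) patch means are reported for plotting on the original
#' hexagon-unit scale.
#'
#' @param records A [pairwise_distances()] data frame.
#' @return List of class `distance_anova`: `anova` (an `anova_result`),
#'   `patch_means` (back-transformed means per patch).
#' @export
sqrt_distance_anova <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("patch", "plant_a", "plant_b", "euclidean") %in% names(records)))
  records$pair <- paste(records$plant_a, records$plant_b, sep = ":")
  cell <- table(records$pair, records$patch)
  if (any(cell != 1L))
    stop("every plant pair must have exactly one distance per patch")
  d <- data.frame(y = sqrt(records$euclidean),
                  plant_id = records$pair,
                  structure = records$structure,
                  position = records$position)
  an <- purity_block_anova(d, response = "y", block = "plant_id")
  an$term[an$term == "block"] <- "pair"
  sqrt_means <- tapply(sqrt(records$euclidean), records$patch, mean)
  structure(list(anova = an, patch_means = sqrt_means[.PATCHES]^2),
            class = "distance_anova")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Complete-block ANOVA:\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
print.distance_anova <- function(x, ...) {
  print(x$anova)
  cat("Back-transformed patch mean distances (hexagon units):\n")
  print(round(x$patch_means, 4))
  invisible(x)
}
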