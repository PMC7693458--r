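# Pipeline orchestration: config validation and the end-to-end analysis
# (spectra -> excitations -> descriptors -> distances -> statistics ->
# modularity), with CSV/JSON reports and a run log.

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a list, checks every invariant, fills
#' defaults, and returns a normalised `run_config`. Exactly one input
#' source must be given: `manifest` (path to a manifest CSV of measured
#' spectra) or `generator` (arguments for [generator_config()], possibly an
#' empty list for all defaults; add `null: true` for the non-modular
#' generator).
#'
#' Defaults mirror the package's standard analysis: FDR level 0.05,
#' circular post hoc level 0.001, 10000 permutations, 1000 bootstrap
#' resamples, receptor peaks 328/428/536 nm, grid 300-700 nm at 1 nm,
#' 1 nm locus step, no axis rotation, seed 1.
#'
#' @param config Path to a YAML file, or a list.
#' @return List of class `run_config`. All violated invariants are reported
#'   together in the error message, each naming its field.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(alpha = 0.05, circular_alpha = 0.001, n_perm = 10000L,
                   n_boot = 1000L, seed = 1L,
                   lambda_max = c(328, 428, 536),
                   grid = list(from = 300, to = 700, step = 1),
                   locus_step = 1, rotation_deg = 0, out_dir = NULL,
                   cr_unit = "variable")
  unknown <- setdiff(names(config), c(names(defaults), "manifest", "generator"))
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  has_manifest <- !is.null(cfg$manifest)
  has_generator <- !is.null(cfg$generator)
  if (has_manifest + has_generator != 1L)
    errs <- c(errs, "exactly one input source required: 'manifest' or 'generator'")
  for (f in c("alpha", "circular_alpha")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      errs <- c(errs, sprintf("%s must be a single number in (0, 1), got %s",
                              f, paste(v, collapse = ",")))
  }
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 100)
    errs <- c(errs, "n_perm must be at least 100")
  if (!is.numeric(cfg$n_boot) || cfg$n_boot < 1)
    errs <- c(errs, "n_boot must be at least 1")
  if (length(cfg$lambda_max) != 3L || any(diff(as.numeric(cfg$lambda_max)) <= 0))
    errs <- c(errs, "lambda_max must be three increasing peaks (uv, blue, green)")
  g <- cfg$grid
  if (!all(c("from", "to", "step") %in% names(g)) || g$from > 300 ||
      g$to < 700 || g$step <= 0)
    errs <- c(errs, "grid must span at least 300-700 nm with positive step")
  if (!cfg$cr_unit %in% c("variable", "patch"))
    errs <- c(errs, "cr_unit must be 'variable' or 'patch'")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$grid <- seq(g$from, g$to, by = g$step)
  if (has_generator) {
    gen <- cfg$generator
    is_null_gen <- isTRUE(gen$null)
    gen$null <- NULL
    gen$grid <- cfg$grid
    if (is.null(gen$seed)) gen$seed <- cfg$seed
    cfg$generator <- do.call(generator_config, gen)
    attr(cfg$generator, "null") <- is_null_gen
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full intrafloral colour analysis
#'
#' Executes, in order: viewing-context construction, data input (generator
#' or manifest), spectrum-locus construction, patch colour table, pairwise
#' colour distances, the purity complete-block ANOVA with FDR pairwise
#' comparisons, the hue circular one-way test with Watson U2 post hocs, the
#' square-root Euclidean distance ANOVA, the angular-distance circular
#' test, the purity-contrast correlation, and the covariance-ratio
#' modularity test with permutation p-value and bootstrap CI. Any stage
#' error is re-signalled with the stage name; partial outputs already
#' written are preserved.
#'
#' All randomness (generator, permutations, bootstrap, post hocs) descends
#' from `config$seed`, so a run is reproducible end to end.
#'
#' @param config A `run_config`, a list, or a YAML path (passed through
#'   [validate_config()]).
#' @param out_dir Optional output directory overriding `config$out_dir`;
#'   when set, tidy CSV tables, a JSON summary and a run log are written.
#' @return List of class `hexflora_run` with elements `patch_table`,
#'   `distances`, `purity_anova`, `purity_pairwise`, `hue_anova`,
#'   `hue_posthoc`, `distance_anova`, `angular_anova`, `cr`, `cr_ci`,
#'   `purity_contrast_r`, `config`, `seeds`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    note("stage %s", name)
    tryCatch(expr, error = function(e) {
      note("ERROR in stage %s: %s", name, conditionMessage(e))
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(log_lines, file.path(out_dir, "run_log.txt"))
      }
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seeds <- .child_seeds(config$seed, 5L)
  names(seeds) <- c("generator", "cr_perm", "cr_boot", "posthoc", "spare")
  note("hexflora %s, R %s, root seed %s",
       as.character(utils::packageVersion("hexflora")),
       getRversion(), config$seed)

  ctx <- stage("viewing_context", viewing_context(
    grid = config$grid, lambda_max = as.numeric(config$lambda_max)))
  data <- stage("input", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      if (isTRUE(attr(gen, "null"))) generate_null_dataset(gen)
      else generate_dataset(gen)
    } else load_dataset(config$manifest)
  })
  locus <- stage("spectrum_locus", build_spectrum_locus(
    ctx, step = config$locus_step, rotation_deg = config$rotation_deg))
  tbl <- stage("patch_colors", patch_colors(
    data$spectra, data$manifest, ctx, locus = locus,
    rotation_deg = config$rotation_deg))
  dists <- stage("distances", pairwise_distances(tbl))
  purity_anova <- stage("purity_anova", purity_block_anova(tbl))
  purity_pairwise <- stage("purity_pairwise",
                           pairwise_patch_tests(tbl, alpha = config$alpha))
  hue_anova <- stage("hue_circular_anova",
                     circular_anova(tbl$hue_deg, tbl$patch))
  hue_posthoc <- stage("hue_posthoc", .watson_posthoc(
    tbl$hue_deg, tbl$patch, n_perm = config$n_perm,
    seed = seeds[["posthoc"]], level = config$circular_alpha))
  distance_anova <- stage("distance_anova", sqrt_distance_anova(dists))
  angular_anova <- stage("angular_circular_anova",
                         circular_anova(dists$angular, dists$patch))
  pc_r <- stage("purity_contrast_correlation",
                stats::cor(tbl$purity, tbl$contrast))
  cr <- stage("cr_test", {
    M <- normalize_excitations(tbl)
    cr_permutation_test(M, default_module_assignment(),
                        n_perm = config$n_perm, seed = seeds[["cr_perm"]],
                        unit = config$cr_unit)
  })
  cr_ci <- stage("cr_bootstrap", cr_bootstrap_ci(
    normalize_excitations(tbl), default_module_assignment(),
    n_boot = config$n_boot, seed = seeds[["cr_boot"]]))
  note("done: %d patch records, %d distance records, CR = %.4f (p = %.4g)",
       nrow(tbl), nrow(dists), cr$observed, cr$p)

  res <- structure(list(patch_table = tbl, distances = dists,
                        purity_anova = purity_anova,
                        purity_pairwise = purity_pairwise,
                        hue_anova = hue_anova, hue_posthoc = hue_posthoc,
                        distance_anova = distance_anova,
                        angular_anova = angular_anova,
                        cr = cr, cr_ci = cr_ci,
                        purity_contrast_r = pc_r,
                        config = config, seeds = seeds, log = log_lines),
                   class = "hexflora_run")
  if (!is.null(out_dir)) .write_report(res, out_dir)
  invisible(res)
}

#' Watson U2 post hoc comparisons between all patch pairs
#' @noRd
.watson_posthoc <- function(hue_deg, patch, n_perm, seed, level) {
  pairs <- utils::combn(.PATCHES, 2L)
  sub_seeds <- .child_seeds(seed, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- hue_deg[patch == pairs[1L, k]]
    b <- hue_deg[patch == pairs[2L, k]]
    w <- watson_u2(a, b, n_perm = n_perm, seed = sub_seeds[k], level = level)
    data.frame(patch_a = pairs[1L, k], patch_b = pairs[2L, k],
               u2 = unname(w$statistic), p = w$p, reject = w$reject)
  })
  do.call(rbind, rows)
}

#' @noRd
.write_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(as.data.frame(res$patch_table), "patch_colors.csv")
  wcsv(res$distances, "distances.csv")
  wcsv(as.data.frame(res$purity_anova), "purity_anova.csv")
  pw <- res$purity_pairwise$comparisons
  pw$letters_a <- res$purity_pairwise$letters[pw$patch_a]
  pw$letters_b <- res$purity_pairwise$letters[pw$patch_b]
  wcsv(pw, "purity_pairwise.csv")
  wcsv(data.frame(term = "patch", F = res$hue_anova$statistic,
                  df1 = res$hue_anova$df[1], df2 = res$hue_anova$df[2],
                  p = res$hue_anova$p), "hue_circular_anova.csv")
  wcsv(res$hue_posthoc, "hue_watson_pairs.csv")
  wcsv(as.data.frame(res$distance_anova$anova), "distance_anova.csv")
  wcsv(data.frame(patch = names(res$distance_anova$patch_means),
                  mean_euclidean = as.numeric(res$distance_anova$patch_means)),
       "distance_patch_means.csv")
  summary <- list(
    n_patch_records = nrow(res$patch_table),
    n_distance_records = nrow(res$distances),
    purity_contrast_r = res$purity_contrast_r,
    purity_interaction_F = res$purity_anova$F[res$purity_anova$term == "structure:position"],
    purity_interaction_p = res$purity_anova$p[res$purity_anova$term == "structure:position"],
    hue_anova_F = unname(res$hue_anova$statistic),
    hue_anova_p = res$hue_anova$p,
    cr_observed = res$cr$observed,
    cr_p = res$cr$p,
    cr_unit = res$cr$unit,
    cr_ci = as.numeric(res$cr_ci),
    n_perm = res$cr$n_perm,
    seed = res$config$seed,
    seeds = as.list(res$seeds),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("hexflora")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.hexflora_run <- function(x, ...) {
  cat("hexflora pipeline run\n")
  cat(sprintf("  %d patch records, %d distance records\n",
              nrow(x$patch_table), nrow(x$distances)))
  cat(sprintf("  purity-contrast r = %.3f\n", x$purity_contrast_r))
  ia <- x$purity_anova[x$purity_anova$term == "structure:position", ]
  cat(sprintf("  purity structure:position F = %.3f (df %d), p = %.3g\n",
              ia$F, ia$df, ia$p))
  cat(sprintf("  CR = %.3f (95%% CI %.3f-%.3f), p = %.4g [%s-level, %d perms]\n",
              x$cr$observed, x$cr_ci[["low"]], x$cr_ci[["high"]], x$cr$p,
              x$cr$unit, x$cr$n_perm))
  invisible(x)
}
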