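## End-to-end orchestration: load -> prep -> fit -> predict -> report -----

default_config <- function() {
  list(input = NULL, schema = NULL,
       endpoints = phenotype_registry()$endpoint,
       effects = rix_effects(),
       kappa = 1,
       flag_quantile = 0.10,
       interval_level = 0.95,
       n_starts = 5L,
       seed = 1L,
       out_dir = NULL)
}

#' Validate a pipeline configuration
#'
#' @param config Named list (or path to a JSON file) with any of: `input`
#'   (CSV path), `schema` (column-name map), `endpoints`, `effects`,
#'   `kappa`, `flag_quantile`, `interval_level`, `n_starts`, `seed`,
#'   `out_dir`.  Unspecified fields take their defaults.
#' @return The merged, validated configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_config(), config)
  unknown <- setdiff(cfg$endpoints, phenotype_registry()$endpoint)
  if (length(unknown) > 0L) {
    rix_abort(sprintf("config names unknown endpoint(s): %s",
                      paste(unknown, collapse = ", ")), "rixmm_schema_error")
  }
  unknown_eff <- setdiff(cfg$effects, rix_effects())
  if (length(unknown_eff) > 0L) {
    rix_abort(sprintf("config names unknown effect(s): %s",
                      paste(unknown_eff, collapse = ", ")), "rixmm_schema_error")
  }
  if (cfg$flag_quantile <= 0 || cfg$flag_quantile > 0.5) {
    rix_abort("flag_quantile must lie in (0, 0.5]", "rixmm_range_error")
  }
  if (cfg$interval_level <= 0 || cfg$interval_level >= 1) {
    rix_abort("interval_level must lie in (0, 1)", "rixmm_range_error")
  }
  cfg
}

write_manifest <- function(out_dir, manifest) {
  files <- setdiff(list.files(out_dir, full.names = TRUE, recursive = TRUE),
                   file.path(out_dir, "manifest.json"))
  manifest$files <- lapply(files, function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)),
         bytes = file.info(f)$size)
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Run the full analysis pipeline
#'
#' Executes load -> phenotype preparation -> REML fits and hypothesis tests
#' -> BLUPs -> heritability -> extreme-strain flags -> cross-phenotype
#' correlations, and writes a report bundle: the hypothesis-test report
#' (CSV + JSON), per-endpoint BLUP tables, correlation matrices, the flag
#' summary, and a run manifest with the configuration echo, seeds, package
#' version, per-endpoint row accounting, the heritability definition used,
#' and a checksum for every output file.  Re-running with an identical
#' configuration reproduces the outputs byte for byte.
#'
#' Flag directions are taken from the sign of each endpoint's estimated
#' fixed treatment effect, restricted to endpoints where that effect is
#' significant at 0.05.
#'
#' @param config See [pipeline_config()].  `table` may be supplied directly
#'   instead of `config$input`.
#' @param table Optional [as_animal_table()] object (overrides
#'   `config$input`).
#' @return Invisibly, a list with the analysis, report, blups,
#'   correlations, flags, and manifest.  If any endpoint failed, the
#'   manifest records it and the returned list has `status = "partial"`.
#' @export
run_pipeline <- function(config = list(), table = NULL) {
  cfg <- pipeline_config(config)
  if (is.null(table)) {
    if (is.null(cfg$input)) {
      rix_abort("either config$input or a table must be supplied",
                "rixmm_schema_error")
    }
    table <- load_animal_table(cfg$input, schema = cfg$schema)
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  analysis <- fit_all_phenotypes(table, endpoints = cfg$endpoints,
                                 effects = cfg$effects, kappa = cfg$kappa,
                                 n_starts = cfg$n_starts, seed = cfg$seed)
  failed <- names(analysis)[vapply(analysis, function(a) !is.null(a$error),
                                   logical(1L))]
  okay <- setdiff(names(analysis), failed)

  report <- table2_report(analysis)
  blup_map <- lapply(analysis[okay], function(a)
    prediction_intervals(a$blups, cfg$interval_level))

  directions <- c()
  for (ep in okay) {
    t <- analysis[[ep]]$fixed_tests$tmt
    if (!is.null(t) && t$p_value < 0.05) {
      directions[ep] <- sign(analysis[[ep]]$fit$beta[["tmt"]])
    }
  }
  flags <- if (length(directions) > 0L) {
    flag_extreme_strains(blup_map, quantile = cfg$flag_quantile,
                         directions = directions)
  } else NULL

  corr <- list()
  for (eff in c("strain", "strain_x_tmt")) {
    corr[[eff]] <- tryCatch(strain_effect_correlations(blup_map, eff),
                            error = function(e) NULL)
  }

  row_accounting <- lapply(analysis[okay], function(a) a$frame$counts[
    c("n_input", "n_used", "n_dropped")])

  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (ep in okay) {
      utils::write.csv(as.data.frame(blup_map[[ep]]),
                       file.path(out_dir, sprintf("blups_%s.csv", ep)),
                       row.names = FALSE)
    }
    for (eff in names(corr)) {
      if (is.null(corr[[eff]])) next
      utils::write.csv(corr[[eff]]$correlation,
                       file.path(out_dir, sprintf("correlations_%s.csv", eff)))
    }
    if (!is.null(flags)) {
      utils::write.csv(flags$summary, file.path(out_dir, "flagged_strains.csv"),
                       row.names = FALSE)
      jsonlite::write_json(flags[c("per_endpoint", "any", "multiple")],
                           file.path(out_dir, "flagged_strains.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
  }

  manifest <- list(
    tool = "rixmm", version = as.character(utils::packageVersion("rixmm")),
    status = if (length(failed) > 0L) "partial" else "complete",
    config = cfg[setdiff(names(cfg), "out_dir")],
    heritability_definition = if (length(okay) > 0L)
      analysis[[okay[1L]]]$heritability$definition else NULL,
    flag_directions = as.list(directions),
    row_accounting = row_accounting,
    failed_endpoints = as.list(failed))
  if (!is.null(out_dir)) manifest <- write_manifest(out_dir, manifest)

  invisible(list(analysis = analysis, report = report, blups = blup_map,
                 correlations = corr, flags = flags, manifest = manifest,
                 status = manifest$status))
}

#' Run a simulation study with progress logging and a manifest
#'
#' Wraps [parameter_recovery_study()]: writes a manifest marked
#' `"running"` before computation starts (so an interrupted run leaves
#' evidence of incompleteness), then the recovery report as CSV + JSON and
#' the completed manifest.
#'
#' @param truth A [simulation_truth()] object.
#' @param reps Number of replicates (>= 1).
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param ... Passed to [parameter_recovery_study()].
#' @return Invisibly, the `recovery_report`.
#' @export
run_simulation_suite <- function(truth, reps, seed = 1L, out_dir = NULL, ...) {
  stopifnot(reps >= 1L)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(
      list(tool = "rixmm", status = "running", reps = reps, seed = seed),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  message(sprintf("simulation suite: %d replicates, seed %d", reps, seed))
  report <- parameter_recovery_study(truth, reps, seed = seed, ...)
  if (!is.null(out_dir)) {
    utils::write.csv(report$parameters,
                     file.path(out_dir, "recovery_parameters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(parameters = report$parameters, coverage = report$coverage,
           lrt = report$lrt[c("component", "truth", "alpha",
                              "rejection_rate", "n")],
           design = report$design, reps = report$reps,
           n_fail = report$n_fail, seed = report$seed),
      file.path(out_dir, "recovery_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_manifest(out_dir, list(
      tool = "rixmm", version = as.character(utils::packageVersion("rixmm")),
      status = "complete", reps = reps, seed = seed,
      n_fail = report$n_fail))
  }
  invisible(report)
}
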