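# End-to-end pipeline: preprocess -> interactions/significance ->
# module detection -> prioritisation, with deterministic file outputs.

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline with its default: trimming
#' threshold 0.1, minimum smCOG membership 3, threshold-ladder cap 0.1,
#' minimum module size 3, minimum supporting-cluster count 2, and the
#' default [mib_weights()].
#'
#' @param input Path to a cluster table, or a `bgc_dataset`.
#' @param format Input format for file paths, see [read_cluster_table()];
#'   `"genbank"` routes through [read_genbank_clusters()].
#' @param out_dir Output directory.
#' @param trim_threshold,min_members,cap,min_size,min_support,max_steps
#'   Stage parameters; see the stage functions.
#' @param weights A [mib_weights()] vector.
#' @param smcog_map Sidecar gene-to-smCOG mapping for GenBank input.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, out_dir = "bgcmodules_out",
                       format = c("tsv", "json", "genbank"),
                       trim_threshold = 0.1, min_members = 3, cap = 0.1,
                       min_size = 3, min_support = 2, max_steps = Inf,
                       weights = mib_weights(), smcog_map = NULL) {
  structure(
    list(
      input = input, out_dir = out_dir, format = match.arg(format),
      trim_threshold = trim_threshold, min_members = min_members,
      cap = cap, min_size = min_size, min_support = min_support,
      max_steps = max_steps, weights = weights, smcog_map = smcog_map
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) file whose keys mirror the arguments of [run_config()];
#' a `weights` mapping overrides individual [mib_weights()] entries.
#' Values supplied in the file override the defaults; callers can still
#' override file values via `...`.
#'
#' @param path YAML/JSON config path.
#' @param ... Overrides applied after the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  if (!is.null(cfg$weights)) {
    cfg$weights <- do.call(mib_weights, as.list(cfg$weights))
  }
  do.call(run_config, cfg)
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort_bgc(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)),
              "bgc_pipeline_error")
  })
}

#' Run the full module-detection pipeline
#'
#' Executes preprocessing, pairwise significance testing, module
#' detection, and prioritisation, writing to the configured output
#' directory: `interactions.tsv` (per-pair test results), per-threshold
#' edge lists under `edges/`, `modules.tsv` + `modules.json` (the ranked
#' module table with supporting clusters), and `run_log.json` (parameter
#' echo plus the preprocessing report). Reruns on identical input produce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `dataset` (preprocessed), `results`,
#'   `modules` (with metrics and MIB scores), `report`, and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dataset <- stage("read", {
    if (inherits(config$input, "bgc_dataset")) {
      config$input
    } else if (config$format == "genbank") {
      read_genbank_clusters(config$input, smcog_map = config$smcog_map)
    } else {
      read_cluster_table(config$input, format = config$format)
    }
  })
  pre <- stage("preprocess", preprocess_dataset(
    dataset, trim_threshold = config$trim_threshold,
    min_members = config$min_members
  ))
  results <- stage("significance", test_all_pairs(pre$dataset))
  modules <- stage("module_detect", detect_modules(
    results, pre$dataset, cap = config$cap, min_size = config$min_size,
    min_support = config$min_support, max_steps = config$max_steps
  ))
  modules <- stage("prioritize", {
    if (nrow(modules) > 0) {
      m <- compute_module_metrics(modules, pre$dataset)
      m$mib_score <- mib_score(m, config$weights)
      m[order(-m$mib_score, m$module_id), ]
    } else {
      modules
    }
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    interactions = file.path(config$out_dir, "interactions.tsv"),
    modules = file.path(config$out_dir, "modules.tsv"),
    log = file.path(config$out_dir, "run_log.json")
  )
  stage("write", {
    readr::write_tsv(results, paths$interactions, progress = FALSE)
    write_edge_lists(results, file.path(config$out_dir, "edges"),
                     cap = config$cap, max_steps = config$max_steps)
    write_modules(modules, paths$modules)
    jsonlite::write_json(
      list(
        parameters = list(
          trim_threshold = config$trim_threshold,
          min_members = config$min_members, cap = config$cap,
          min_size = config$min_size, min_support = config$min_support,
          max_steps = if (is.finite(config$max_steps)) config$max_steps,
          weights = as.list(unclass(config$weights))
        ),
        preprocess_report = unclass(pre$report),
        n_tests = nrow(results),
        n_modules = nrow(modules)
      ),
      paths$log, auto_unbox = TRUE, digits = NA, null = "null"
    )
  })
  invisible(list(dataset = pre$dataset, results = results, modules = modules,
                 report = pre$report, paths = paths))
}
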