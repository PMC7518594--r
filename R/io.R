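#' Write the per-sample solution table
#'
#' TSV with columns `sample_id` and `module_id` (integer, or `"lonely"`).
#'
#' @param fit A `modulomics_fit` (or `module_solution`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_solution <- function(fit, path) {
  sol <- if (inherits(fit, "modulomics_fit")) fit$solution else fit
  asg <- module_assignment(sol)
  tb <- tibble::tibble(sample_id = sol$sample_ids,
                       module_id = ifelse(is.na(asg), "lonely",
                                          as.character(asg)))
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Write the module table
#'
#' TSV with `module_id`, `size`, semicolon-joined covered `omics`, `weight`.
#'
#' @inheritParams write_solution
#' @export
write_module_table <- function(fit, path) {
  tb <- tidy(fit, "modules") |>
    dplyr::rename(module_id = "module")
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Write run diagnostics as JSON
#'
#' Per-restart objectives, applied-action counts and the significance-filter
#' report.
#'
#' @inheritParams write_solution
#' @export
write_diagnostics <- function(fit, path) {
  d <- fit$diagnostics
  out <- list(
    objective = fit$objective,
    restart_objectives = d$restart_objectives$objective,
    action_counts = as.list(d$action_counts),
    epochs = d$epochs,
    filter_report = if (!is.null(d$filter_report)) d$filter_report else NULL
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write simulated omics as delimited matrices plus ground truth
#'
#' One TSV per omic (features x samples, first column = feature id), plus
#' `truth_labels.tsv` (sample_id, label) and `truth_coverage.tsv`.
#'
#' @param dataset Result of [simulate_omics()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (o in dataset$omics) {
    tb <- tibble::as_tibble(o$values, .name_repair = "minimal")
    tb <- dplyr::bind_cols(tibble::tibble(feature_id = o$feature_ids), tb)
    readr::write_tsv(tb, file.path(dir, paste0(o$omic_id, ".tsv")))
  }
  readr::write_tsv(tibble::tibble(sample_id = names(dataset$labels),
                                  label = unname(dataset$labels)),
                   file.path(dir, "truth_labels.tsv"))
  cov <- tibble::as_tibble(dataset$coverage, rownames = "module")
  readr::write_tsv(cov, file.path(dir, "truth_coverage.tsv"))
  invisible(dir)
}

#' Run the full pipeline from a configuration file
#'
#' The configuration is a flat-key YAML file. Recognised keys:
#' `omics` (named map of omic id to matrix path) or `preset`
#' (`"sim1"` / `"sim2"` / `"sim2_two_omics"`), `transpose`, `scheme`
#' (`consensus`/`gmm`), `C`, `R`, `global_shift`, `S`, `k`, `eta`,
#' `batch_cap`, `restarts`, `n_null`, `keep_quantile`, `seed`, `out_dir`.
#' Writes the solution and module tables, the coverage table, the graph edge
#' list, a diagnostics JSON and the resolved configuration next to the
#' outputs.
#'
#' @param config Path to the YAML configuration, or an equivalent named list.
#' @return The `modulomics_fit`, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  need <- function(key, default = NULL) {
    v <- cfg[[key]] %||% default
    if (is.null(v)) stop("config is missing required key '", key, "'",
                         call. = FALSE)
    v
  }
  out_dir <- need("out_dir")
  seed <- as.integer(need("seed", 1L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- if (!is.null(cfg$omics)) {
    paths <- unlist(cfg$omics)
    load_omics(paths, transpose = isTRUE(cfg$transpose))
  } else {
    preset <- need("preset")
    spec <- switch(preset,
                   sim1 = sim1_preset(rng_seed = seed),
                   sim2 = sim2_preset(TRUE, rng_seed = seed),
                   sim2_two_omics = sim2_preset(FALSE, rng_seed = seed),
                   stop("config key 'preset' must be sim1, sim2 or ",
                        "sim2_two_omics", call. = FALSE))
    simulate_omics(spec)
  }
  n <- length(dataset$registry$sample_ids)
  weighting <- weighting_config(
    scheme = cfg$scheme %||% "consensus",
    C = cfg$C %||% 0.2, R = cfg$R %||% 100L,
    global_shift = cfg$global_shift %||% 0,
    rng_seed = seed)
  search <- search_params(
    n, S = cfg$S %||% 15L, k = cfg$k, eta = cfg$eta,
    batch_cap = cfg$batch_cap, restarts = cfg$restarts %||% 15L,
    rng_seed = seed)
  significance <- null_test_config(
    n_null = cfg$n_null %||% 500L,
    keep_quantile = cfg$keep_quantile %||% 0.99,
    rng_seed = seed)
  message("fitting ", n, " samples across ", length(dataset$omics),
          " omic(s) [scheme=", weighting$scheme, ", restarts=",
          search$restarts, "]")
  fit <- detect_modules(dataset$omics, dataset$registry, weighting, search,
                        significance)
  write_solution(fit, file.path(out_dir, "solution.tsv"))
  write_module_table(fit, file.path(out_dir, "modules.tsv"))
  readr::write_tsv(tidy(fit, "coverage"), file.path(out_dir, "coverage.tsv"))
  readr::write_tsv(graph_edge_list(fit$graphs),
                   file.path(out_dir, "graph_edges.tsv"))
  write_diagnostics(fit, file.path(out_dir, "diagnostics.json"))
  resolved <- list(seed = seed, scheme = weighting$scheme, C = weighting$C,
                   R = weighting$R, global_shift = weighting$global_shift,
                   S = search$S, k = search$k, eta = search$eta,
                   batch_cap = search$batch_cap, restarts = search$restarts,
                   n_null = significance$n_null,
                   keep_quantile = significance$keep_quantile,
                   out_dir = out_dir)
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  message("objective ", round(fit$objective, 3), "; ",
          length(fit$solution$modules), " module(s), ",
          length(fit$solution$lonely), " lonely sample(s)")
  invisible(fit)
}
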