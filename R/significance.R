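#' Configuration for the empirical module-significance filter
#'
#' @param n_null Number of random null modules per tested module
#'   (default 500).
#' @param keep_quantile A module is kept only if its weight strictly exceeds
#'   this empirical quantile of the null weights (default 0.99, i.e. the
#'   weight must be in the highest 1 percent).
#' @param test_scope `"all_modules"` (default) tests every module;
#'   `"minimal_size_only"` tests only modules at the minimum size `eta`
#'   (larger modules are always retained — the practical setting, since
#'   larger modules essentially never fail the test).
#' @param eta Minimum module size used by `"minimal_size_only"`; filled in
#'   from the search parameters by [detect_modules()].
#' @param rng_seed Integer seed for the null draws.
#' @return A `null_test_config` list.
#' @export
null_test_config <- function(n_null = 500L, keep_quantile = 0.99,
                             test_scope = c("all_modules",
                                            "minimal_size_only"),
                             eta = NULL, rng_seed = 1L) {
  test_scope <- match.arg(test_scope)
  stopifnot(keep_quantile > 0, keep_quantile < 1, n_null >= 100L)
  structure(list(n_null = as.integer(n_null), keep_quantile = keep_quantile,
                 test_scope = test_scope, eta = eta,
                 rng_seed = as.integer(rng_seed)),
            class = "null_test_config")
}

#' Filter modules by empirical significance
#'
#' For each tested module, draws `n_null` uniformly random sample subsets of
#' the same size from all samples, scores each with the module's own omic
#' set, and keeps the module only if its weight strictly exceeds the
#' `keep_quantile` empirical quantile of the null weights (the
#' `ceiling(keep_quantile * n_null)`-th order statistic; 495th of 500 under
#' the defaults). Samples of removed modules become lonely. Retained modules
#' are never altered.
#'
#' @param solution A converged `module_solution`.
#' @param graphs Named list of `omic_graph` objects.
#' @param cfg A [null_test_config()].
#' @return The filtered `module_solution`, with a tibble report (module,
#'   size, observed weight, null quantile, kept flag) in attribute
#'   `"filter_report"`.
#' @export
filter_modules <- function(solution, graphs, cfg = null_test_config()) {
  n <- length(solution$sample_ids)
  mods <- solution$modules
  if (length(mods) == 0L) {
    out <- solution
    attr(out, "filter_report") <- tibble::tibble(
      module = integer(0), size = integer(0), observed = numeric(0),
      null_quantile = numeric(0), tested = logical(0), kept = logical(0))
    return(out)
  }
  ord_stat <- ceiling(cfg$keep_quantile * cfg$n_null)
  report <- purrr::map_dfr(seq_along(mods), function(i) {
    m <- mods[[i]]
    size <- length(m$samples)
    obs <- module_weight(m, graphs)
    tested <- cfg$test_scope == "all_modules" ||
      (is.null(cfg$eta) || size <= cfg$eta)
    if (!tested) {
      return(tibble::tibble(module = i, size = size, observed = obs,
                            null_quantile = NA_real_, tested = FALSE,
                            kept = TRUE))
    }
    nulls <- withr::with_seed(cfg$rng_seed + i, {
      vapply(seq_len(cfg$n_null), function(r) {
        idx <- sample.int(n, size)
        pair_sum(m$omics, idx, graphs)
      }, numeric(1))
    })
    thr <- sort(nulls, method = "quick")[ord_stat]
    tibble::tibble(module = i, size = size, observed = obs,
                   null_quantile = thr, tested = TRUE, kept = obs > thr)
  })
  keep <- report$kept
  lonely <- sort(c(solution$lonely,
                   unlist(lapply(mods[!keep], `[[`, "samples"))))
  out <- module_solution(mods[keep], lonely, solution$sample_ids)
  attr(out, "filter_report") <- report
  out
}
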