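#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a module-discovery fit
#'
#' @param x A `modulomics_fit`.
#' @param what `"samples"` (default): one row per sample with its module
#'   assignment; `"modules"`: one row per module with size, covered omics and
#'   weight; `"coverage"`: one row per (module, omic) cell; `"restarts"`:
#'   per-restart objectives.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.modulomics_fit <- function(x, what = c("samples", "modules", "coverage",
                                            "restarts"), ...) {
  what <- match.arg(what)
  sol <- x$solution
  switch(what,
    samples = {
      asg <- module_assignment(sol)
      tibble::tibble(sample_id = sol$sample_ids,
                     module = ifelse(is.na(asg), "lonely",
                                     paste0("M", asg)),
                     lonely = is.na(asg))
    },
    modules = purrr::map_dfr(seq_along(sol$modules), function(i) {
      m <- sol$modules[[i]]
      tibble::tibble(module = paste0("M", i), size = length(m$samples),
                     omics = paste(m$omics, collapse = ";"),
                     weight = module_weight(m, x$graphs))
    }),
    coverage = {
      omic_ids <- names(x$graphs)
      purrr::map_dfr(seq_along(sol$modules), function(i) {
        tibble::tibble(module = paste0("M", i), omic = omic_ids,
                       covered = omic_ids %in% sol$modules[[i]]$omics)
      })
    },
    restarts = x$diagnostics$restart_objectives
  )
}

#' One-row summary of a module-discovery fit
#'
#' @param x A `modulomics_fit`.
#' @param ... Unused.
#' @return A tibble with sample/module counts, the objective, and the number
#'   of modules removed by the significance filter.
#' @export
glance.modulomics_fit <- function(x, ...) {
  sol <- x$solution
  rep <- x$diagnostics$filter_report
  tibble::tibble(
    n_samples = length(sol$sample_ids),
    n_modules = length(sol$modules),
    n_lonely = length(sol$lonely),
    objective = x$objective,
    restarts = x$search$restarts,
    n_filtered = if (is.null(rep)) 0L else sum(!rep$kept),
    epochs = x$diagnostics$epochs %||% NA_integer_
  )
}

#' Plot a module-discovery fit
#'
#' @param object A `modulomics_fit`.
#' @param type `"coverage"` (default): module-by-omic coverage tiles;
#'   `"objective"`: per-restart objectives; `"weights"`: the omic-summed
#'   weight matrix with samples ordered by module.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.modulomics_fit <- function(object, type = c("coverage", "objective",
                                                     "weights"), ...) {
  type <- match.arg(type)
  if (type == "coverage") {
    cov <- tidy(object, "coverage") |>
      dplyr::left_join(tidy(object, "modules"), by = "module")
    ggplot2::ggplot(cov, ggplot2::aes(x = .data$omic, y = .data$module,
                                      fill = .data$covered)) +
      ggplot2::geom_tile(colour = "grey30") +
      ggplot2::geom_text(ggplot2::aes(label = .data$size), size = 3) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "grey90")) +
      ggplot2::labs(x = NULL, y = NULL, fill = "covered",
                    title = "Module omic coverage (tile label = size)") +
      ggplot2::theme_minimal()
  } else if (type == "objective") {
    ggplot2::ggplot(tidy(object, "restarts"),
                    ggplot2::aes(x = .data$restart, y = .data$objective)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = object$objective,
                          linetype = "dashed") +
      ggplot2::labs(title = "Objective per restart",
                    x = "restart", y = "objective") +
      ggplot2::theme_minimal()
  } else {
    asg <- module_assignment(object$solution)
    ord <- order(asg, na.last = TRUE)
    w <- omic_weight_sum(object$graphs, names(object$graphs))[ord, ord]
    df <- tidyr::expand_grid(i = seq_len(nrow(w)), j = seq_len(ncol(w))) |>
      dplyr::mutate(weight = as.vector(t(w)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                     fill = .data$weight)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(low = "#313695", mid = "white",
                                    high = "#a50026") +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(title = "Omic-summed weights (samples ordered by module)",
                    x = NULL, y = NULL) +
      ggplot2::theme_minimal()
  }
}
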