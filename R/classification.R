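#' Association score between a sample and a module
#'
#' The gain in the module's weight from adding the sample: the sum of edge
#' weights between the sample and all the module's samples, across all omics
#' the module covers. For samples already in the dataset the precomputed
#' graphs are used; new samples require the gmm scheme's frozen models (pass
#' their per-omic feature vectors via `new_data`).
#'
#' @param u A sample id (or global index) for an in-dataset sample, or the id
#'   of a new sample present in `new_data`.
#' @param module A [module()].
#' @param graphs Named list of `omic_graph` objects.
#' @param new_data Optional named list (by omic id) of feature vectors for a
#'   new sample; omit for in-dataset samples.
#' @param per_omic Return the per-omic breakdown instead of the total
#'   (diagnostic view of which omics drive the association).
#' @return Numeric score (or named vector when `per_omic = TRUE`).
#' @export
sample_module_score <- function(u, module, graphs, new_data = NULL,
                                per_omic = FALSE) {
  ids <- rownames(graphs[[1L]]$weights)
  per <- if (is.null(new_data)) {
    ui <- if (is.character(u)) match(u, ids) else as.integer(u)
    if (is.na(ui)) stop("unknown sample '", u, "'", call. = FALSE)
    vapply(module$omics, function(l) {
      sum(graphs[[l]]$weights[ui, module$samples])
    }, numeric(1))
  } else {
    vapply(module$omics, function(l) {
      w <- new_sample_weights(graphs[[l]], new_data[[l]])
      mem <- ids[module$samples]
      sum(w[stats::na.omit(match(mem, names(w)))])
    }, numeric(1))
  }
  if (per_omic) per else sum(per)
}

classify_one <- function(scores) {
  if (length(scores) == 0L || max(scores) < 0) NA_integer_ else
    which.max(scores)  # ties resolve to the lowest module index
}

#' Classify new samples into existing modules
#'
#' Scores every (sample, module) pair with [sample_module_score()] and
#' assigns each sample to the module with maximal score; samples whose
#' scores are all negative stay unassigned ("lonely"). A score of exactly
#' zero still classifies. Requires a fit built with the gmm weighting scheme
#' when the samples are not part of the fitted dataset.
#'
#' @param fit A `modulomics_fit`.
#' @param new_omics Optional list of [omic_matrix()] objects holding the new
#'   samples (matching omic ids and feature order); when `NULL`, the fit's
#'   own samples are (re-)classified from the precomputed graphs.
#' @return A tibble with `sample_id`, `module` (integer, `NA` = lonely) and
#'   one `score_M<i>` column per module.
#' @export
classify_samples <- function(fit, new_omics = NULL) {
  sol <- fit$solution
  graphs <- fit$graphs
  if (is.null(new_omics)) {
    ids <- sol$sample_ids
    score_rows <- lapply(seq_along(ids), function(ui) {
      vapply(sol$modules, function(m) {
        sample_module_score(ui, m, graphs)
      }, numeric(1))
    })
  } else {
    if (is.list(new_omics) && !is.null(new_omics$omics)) {
      new_omics <- new_omics$omics
    }
    names(new_omics) <- vapply(new_omics, `[[`, character(1), "omic_id")
    ids <- unique(unlist(lapply(new_omics, `[[`, "sample_ids")))
    score_rows <- lapply(ids, function(sid) {
      nd <- purrr::imap(new_omics, function(o, l) {
        j <- match(sid, o$sample_ids)
        if (is.na(j)) return(NULL)
        feats <- graphs[[l]]$model$feature_ids
        idx <- match(feats, o$feature_ids)
        if (anyNA(idx)) {
          stop("omic '", l, "': new data lacks ", sum(is.na(idx)),
               " training feature(s)", call. = FALSE)
        }
        o$values[idx, j]
      })
      vapply(sol$modules, function(m) {
        sample_module_score(sid, m, graphs, new_data = nd)
      }, numeric(1))
    })
  }
  scores <- do.call(rbind, score_rows)
  if (is.null(scores)) scores <- matrix(numeric(0), 0L, length(sol$modules))
  colnames(scores) <- paste0("score_M", seq_along(sol$modules))
  tibble::tibble(
    sample_id = ids,
    module = vapply(score_rows, classify_one, integer(1))
  ) |>
    dplyr::bind_cols(tibble::as_tibble(scores))
}
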