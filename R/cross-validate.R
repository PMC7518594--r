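#' Unsupervised cross-validation of module discovery with classification
#'
#' Mirrors the standard classification experiment: fit the full dataset
#' (`Sol_all`), partition the samples into `folds` equal folds, and for every
#' fold refit on the remaining samples (`Sol_i`), then classify the held-out
#' samples into `Sol_i`'s modules using the frozen gmm models. Per fold it
#' reports: `stability` = ARI(`Sol_all`, `Sol_i`) over the samples present in
#' both; `rfc` (Rand index following classification) = ARI(`Sol_all`,
#' `Sol_i` + classified hold-outs) over all samples; and, when ground truth
#' is supplied, `pre_ca` = ARI(truth, `Sol_i`) over the fold's training
#' samples and `post_ca` = ARI(truth, `Sol_i` + hold-outs) over all samples,
#' plus `holdout_accuracy`, the fraction of held-out samples classified into
#' the module matched (by maximal overlap) to their true module.
#'
#' @param dataset A list with `omics` (e.g. from [simulate_omics()]).
#' @param weighting A [weighting_config()]; must use the gmm scheme, the only
#'   one able to score unseen samples.
#' @param search Optional [search_params()] template; its sizes are rescaled
#'   to each fold's training set.
#' @param significance A [null_test_config()] or `NULL`.
#' @param folds Number of folds (default 10).
#' @param truth Optional ground-truth labels (named by sample id; -1 =
#'   outlier).
#' @param lonely_mode Lonely-sample convention for all ARIs.
#' @param rng_seed Seed for the fold split.
#' @return A tibble with one row per fold; the full-data fit is attached as
#'   attribute `"fit_all"`.
#' @export
cross_validate <- function(dataset, weighting = weighting_config("gmm"),
                           search = NULL, significance = null_test_config(),
                           folds = 10L, truth = NULL,
                           lonely_mode = "own_cluster", rng_seed = 1L) {
  if (weighting$scheme != "gmm") {
    stop("cross_validate requires the gmm weighting scheme ",
         "(classification needs frozen per-omic models)", call. = FALSE)
  }
  omics <- dataset$omics
  all_ids <- sample_registry(omics)$sample_ids
  n <- length(all_ids)
  fit_all <- detect_modules(omics, weighting = weighting, search = search,
                            significance = significance)
  lab_all <- solution_labels(fit_all)
  fold_of <- withr::with_seed(rng_seed,
                              sample(rep_len(seq_len(folds), n)))
  names(fold_of) <- all_ids
  if (!is.null(truth)) truth <- align_labels(truth, all_ids)
  res <- purrr::map_dfr(seq_len(folds), function(i) {
    train_ids <- all_ids[fold_of != i]
    test_ids <- all_ids[fold_of == i]
    sub <- subset_omics(omics, train_ids)
    search_i <- if (is.null(search)) {
      search_params(length(train_ids), rng_seed = weighting$rng_seed + i)
    } else {
      s <- search
      s$rng_seed <- search$rng_seed + i
      s
    }
    fit_i <- detect_modules(sub$omics, sub$registry, weighting = weighting,
                            search = search_i, significance = significance)
    lab_i <- solution_labels(fit_i)
    stability <- adjusted_rand_index(lab_all[train_ids], lab_i[train_ids],
                                     lonely_mode)
    test_omics <- subset_omics(omics, test_ids)$omics
    cls <- classify_samples(fit_i, test_omics)
    lab_hat <- lab_i
    lab_hat[cls$sample_id] <- cls$module
    lab_hat <- lab_hat[all_ids]
    rfc <- adjusted_rand_index(lab_all, lab_hat, lonely_mode)
    pre_ca <- post_ca <- acc <- NA_real_
    if (!is.null(truth)) {
      pre_ca <- adjusted_rand_index(truth[train_ids], lab_i[train_ids],
                                    lonely_mode)
      post_ca <- adjusted_rand_index(truth, lab_hat, lonely_mode)
      acc <- holdout_accuracy(fit_i, cls, truth, train_ids)
    }
    tibble::tibble(fold = i, stability = stability, rfc = rfc,
                   pre_ca = pre_ca, post_ca = post_ca,
                   holdout_accuracy = acc,
                   n_classified = sum(!is.na(cls$module)))
  })
  attr(res, "fit_all") <- fit_all
  res
}

# fraction of held-out samples classified into the fold module matched to
# their true module (truth -1 is correct when left unclassified)
holdout_accuracy <- function(fit_i, cls, truth, train_ids) {
  sol <- fit_i$solution
  lab_i <- solution_labels(sol)
  k <- max(truth[truth > 0])
  overlap <- vapply(seq_len(k), function(j) {
    vapply(sol$modules, function(m) {
      sum(truth[sol$sample_ids[m$samples]] == j, na.rm = TRUE)
    }, numeric(1))
  }, numeric(length(sol$modules)))
  overlap <- matrix(overlap, nrow = length(sol$modules), ncol = k)
  assign <- match_modules(overlap)  # truth module per found module
  truth_of_module <- assign
  correct <- vapply(seq_len(nrow(cls)), function(r) {
    tr <- truth[cls$sample_id[r]]
    mod <- cls$module[r]
    if (is.na(mod)) return(tr == -1)
    !is.na(truth_of_module[mod]) && truth_of_module[mod] == tr
  }, logical(1))
  mean(correct)
}
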