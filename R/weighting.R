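#' Weighting-scheme configuration
#'
#' Controls how per-omic sample similarity is turned into signed edge weights.
#' Both schemes centre the similarities so that weights take positive values
#' within genuine clusters and negative values across them; the constant `C`
#' is then subtracted, trading modules that cover one omic (larger `C`)
#' against modules reinforced by several omics (smaller `C`).
#'
#' @param scheme `"consensus"` (co-clustering frequency over resampled runs of
#'   a single-omic clusterer) or `"gmm"` (soft co-membership under a Gaussian
#'   mixture fitted in PCA space; the only scheme that can score new, unseen
#'   samples, and hence the one used for classification).
#' @param C Module-balance constant subtracted from every centred similarity
#'   (default 0.2).
#' @param R Number of resampling runs for the consensus scheme (default 100).
#' @param subsample_fraction Fraction of measured samples drawn per run
#'   (default 0.8).
#' @param global_shift Constant added to every measured-pair weight; positive
#'   values encourage more, larger modules. Default 0.
#' @param base_clusterer Function `(x, seed) -> integer labels` clustering a
#'   samples-by-features matrix; default [spectral_cluster()] with the
#'   cluster number picked by the largest Laplacian eigengap in
#'   `cluster_range`.
#' @param cluster_range Candidate cluster numbers for the default clusterer.
#' @param gmm_dim Number of principal components for the gmm scheme
#'   (default 10).
#' @param gmm_components Candidate mixture sizes, selected by BIC.
#' @param standardize Standardize features (z-score) before clustering /
#'   projection.
#' @param rng_seed Integer seed; run `r` of the consensus scheme uses
#'   `rng_seed + r`, and omic `o` offsets the seed by `(o - 1) * 100000`, so
#'   a single integer makes the whole graph construction reproducible.
#'
#' @return A `weighting_config` list.
#' @export
weighting_config <- function(scheme = c("consensus", "gmm"),
                             C = 0.2, R = 100L,
                             subsample_fraction = 0.8,
                             global_shift = 0,
                             base_clusterer = NULL,
                             cluster_range = 2:15,
                             gmm_dim = 10L,
                             gmm_components = 2:10,
                             standardize = FALSE,
                             rng_seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(C >= 0, R >= 1, subsample_fraction > 0, subsample_fraction <= 1)
  structure(
    list(scheme = scheme, C = C, R = as.integer(R),
         subsample_fraction = subsample_fraction,
         global_shift = global_shift,
         base_clusterer = base_clusterer,
         cluster_range = cluster_range,
         gmm_dim = as.integer(gmm_dim),
         gmm_components = gmm_components,
         standardize = standardize,
         rng_seed = as.integer(rng_seed)),
    class = "weighting_config"
  )
}

#' Spectral clustering with eigengap model selection
#'
#' Default single-omic base clusterer for the consensus weighting scheme:
#' a Gaussian-kernel affinity with local (self-tuning) bandwidths, sparsified
#' to a symmetric k-nearest-neighbour graph, normalised-Laplacian embedding,
#' and k-means on the row-normalised eigenvectors. The number of clusters is
#' the value in `k_range` with the largest eigengap.
#'
#' @param x Samples-by-features numeric matrix.
#' @param k_range Candidate cluster numbers.
#' @param nn Neighbourhood size for the affinity graph.
#' @param seed Integer seed for the k-means initialisation.
#' @return Integer cluster labels, one per row of `x`.
#' @export
spectral_cluster <- function(x, k_range = 2:15, nn = 15L, seed = NULL) {
  n <- nrow(x)
  k_range <- k_range[k_range < n]
  if (length(k_range) == 0L) k_range <- 2L
  d2 <- as.matrix(stats::dist(x))^2
  nn <- min(nn, n - 1L)
  # local scaling: bandwidth = distance to the nn/2-th neighbour
  srt <- apply(d2, 1L, sort, method = "quick")
  sigma <- sqrt(srt[max(2L, ceiling(nn / 2)) + 1L, ])
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1e-8)
  aff <- exp(-d2 / (outer(sigma, sigma) + 1e-12))
  # keep each node's nn strongest edges (symmetric union)
  keep <- matrix(FALSE, n, n)
  ord <- apply(d2, 1L, order)
  for (i in seq_len(n)) keep[i, ord[2:(nn + 1L), i]] <- TRUE
  keep <- keep | t(keep)
  aff[!keep] <- 0
  diag(aff) <- 0
  deg <- rowSums(aff)
  deg[deg <= 0] <- 1e-12
  dhalf <- 1 / sqrt(deg)
  lsym <- diag(n) - (dhalf * aff) * rep(dhalf, each = n)
  ev <- eigen(lsym, symmetric = TRUE)
  lambda <- rev(ev$values)            # ascending
  vecs <- ev$vectors[, n:1, drop = FALSE]
  gaps <- lambda[k_range + 1L] - lambda[k_range]
  k <- k_range[which.max(gaps)]
  emb <- vecs[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(emb^2))
  emb <- emb / pmax(norms, 1e-12)
  if (!is.null(seed)) {
    withr::with_seed(seed, stats::kmeans(emb, centers = k, nstart = 5L,
                                         iter.max = 30L)$cluster)
  } else {
    stats::kmeans(emb, centers = k, nstart = 5L, iter.max = 30L)$cluster
  }
}

new_omic_graph <- function(omic_id, weights, measured, sample_ids,
                           model = NULL) {
  dimnames(weights) <- list(sample_ids, sample_ids)
  structure(list(omic_id = omic_id, weights = weights,
                 measured = measured, model = model),
            class = "omic_graph")
}

#' @export
print.omic_graph <- function(x, ...) {
  w <- x$weights[x$measured, x$measured]
  off <- w[upper.tri(w)]
  cat("<omic_graph> ", x$omic_id, ": ", nrow(x$weights), " samples (",
      sum(x$measured), " measured), weight range [",
      round(min(off), 3), ", ", round(max(off), 3), "]\n", sep = "")
  invisible(x)
}

check_signed <- function(w, measured, omic_id) {
  off <- w[upper.tri(w)]
  if (all(measured) && (!any(off > 0) || !any(off < 0))) {
    warning("omic '", omic_id, "': weights are not signed (no ",
            if (any(off > 0)) "negative" else "positive",
            " entries); module growth will not self-limit", call. = FALSE)
  }
}

#' Consensus co-clustering edge weights for one omic
#'
#' Runs the base single-omic clusterer `R` times, each time on a random
#' `subsample_fraction` of the measured samples. With `cl_r(u,v)` the
#' indicator that `u` and `v` co-clustered in run `r` and `avg(cl_r)` the mean
#' indicator over that run's sampled pairs, the weight of a measured pair is
#'
#'   `mean over runs containing both samples of (cl_r(u,v) - avg(cl_r)) - C`
#'
#' plus `global_shift`. Pairs never sampled together get weight 0, as do all
#' edges incident to samples not measured in this omic.
#'
#' @param matrix An [omic_matrix()].
#' @param registry The [sample_registry()] fixing the global sample order.
#' @param cfg A [weighting_config()].
#' @return An `omic_graph` over the registry's samples.
#' @export
consensus_edge_weights <- function(matrix, registry, cfg = weighting_config()) {
  measured <- registry$membership[[matrix$omic_id]]
  if (is.null(measured)) stop("omic not in registry", call. = FALSE)
  m <- sum(measured)
  if (m < 20L) {
    stop("omic '", matrix$omic_id, "': needs >= 20 measured samples, has ", m,
         call. = FALSE)
  }
  x <- t(matrix$values)
  if (cfg$standardize) x <- scale(x)
  # align rows to the registry order of measured samples
  meas_ids <- registry$sample_ids[measured]
  x <- x[match(meas_ids, matrix$sample_ids), , drop = FALSE]
  clusterer <- cfg$base_clusterer %||%
    function(x, seed) spectral_cluster(x, k_range = cfg$cluster_range,
                                       seed = seed)
  ns <- floor(cfg$subsample_fraction * m)
  if (ns < 3L) stop("subsample too small for clustering", call. = FALSE)
  sums <- base::matrix(0, m, m)
  cnts <- base::matrix(0, m, m)
  for (r in seq_len(cfg$R)) {
    run_seed <- cfg$rng_seed + r
    sub <- withr::with_seed(run_seed, sort(sample.int(m, ns)))
    labels <- clusterer(x[sub, , drop = FALSE], seed = run_seed)
    cl <- outer(labels, labels, `==`) * 1
    avg <- (sum(cl) - ns) / (ns * (ns - 1))
    sums[sub, sub] <- sums[sub, sub] + (cl - avg)
    cnts[sub, sub] <- cnts[sub, sub] + 1
  }
  w_meas <- base::matrix(0, m, m)
  seen <- cnts > 0
  w_meas[seen] <- sums[seen] / cnts[seen] - cfg$C + cfg$global_shift
  diag(w_meas) <- 0
  n <- length(registry$sample_ids)
  w <- base::matrix(0, n, n)
  w[measured, measured] <- w_meas
  check_signed(w, measured, matrix$omic_id)
  new_omic_graph(matrix$omic_id, w, measured, registry$sample_ids)
}

#' Gaussian-mixture edge weights for one omic
#'
#' Projects the measured samples to `gmm_dim` principal components, fits a
#' Gaussian mixture (components selected by BIC), and scores a pair by the
#' probability that the two samples share a mixture component: with
#' `gamma_u` the posterior component vector of `u` and `pi` the mixing
#' weights,
#'
#'   `weight(u, v) = sum_k gamma_uk gamma_vk - sum_k pi_k^2 - C + global_shift`.
#'
#' The subtracted `sum(pi^2)` is the expected co-membership of two random
#' samples, so weights are centred like the consensus scheme's. The fitted
#' projection and mixture are frozen in the returned graph's `model` field,
#' which is what allows weights to new, unseen samples (and hence
#' classification) — the consensus scheme cannot do this.
#'
#' @inheritParams consensus_edge_weights
#' @return An `omic_graph` whose `model` field holds the frozen model.
#' @export
gmm_edge_weights <- function(matrix, registry, cfg = weighting_config("gmm")) {
  measured <- registry$membership[[matrix$omic_id]]
  if (is.null(measured)) stop("omic not in registry", call. = FALSE)
  m <- sum(measured)
  if (m < 20L) {
    stop("omic '", matrix$omic_id, "': needs >= 20 measured samples, has ", m,
         call. = FALSE)
  }
  x <- t(matrix$values)
  meas_ids <- registry$sample_ids[measured]
  x <- x[match(meas_ids, matrix$sample_ids), , drop = FALSE]
  ctr <- colMeans(x)
  scl <- if (cfg$standardize) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  scl[scl <= 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, `/`)
  d <- min(cfg$gmm_dim, m - 1L, ncol(xs))
  pca <- stats::prcomp(xs, center = FALSE, rank. = d)
  scores <- pca$x
  comp <- cfg$gmm_components[cfg$gmm_components < m]
  fit <- withr::with_seed(cfg$rng_seed,
    mclust::Mclust(scores, G = comp, verbose = FALSE))
  if (is.null(fit)) {
    warning("omic '", matrix$omic_id,
            "': full-covariance mixture failed; falling back to diagonal",
            call. = FALSE)
    fit <- withr::with_seed(cfg$rng_seed,
      mclust::Mclust(scores, G = comp, verbose = FALSE,
                     modelNames = c("EII", "VII", "EEI", "VVI")))
  }
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  z <- fit$z
  pro <- fit$parameters$pro
  base <- sum(pro^2)
  w_meas <- tcrossprod(z) - base - cfg$C + cfg$global_shift
  diag(w_meas) <- 0
  n <- length(registry$sample_ids)
  w <- base::matrix(0, n, n)
  w[measured, measured] <- w_meas
  check_signed(w, measured, matrix$omic_id)
  model <- list(center = ctr, scale = scl, rotation = pca$rotation,
                fit = fit, z = z, pro = pro, C = cfg$C,
                shift = cfg$global_shift, sample_ids = meas_ids,
                feature_ids = matrix$feature_ids)
  new_omic_graph(matrix$omic_id, w, measured, registry$sample_ids,
                 model = model)
}

#' Weights from a frozen gmm model to a new sample
#'
#' @param graph An `omic_graph` produced by [gmm_edge_weights()].
#' @param x_new Numeric vector of the new sample's features in this omic (in
#'   the omic's feature order), or `NULL` if the sample was not measured.
#' @return Named numeric vector of weights to every measured sample of the
#'   graph (zeros when `x_new` is `NULL`).
#' @export
new_sample_weights <- function(graph, x_new) {
  model <- graph$model
  if (is.null(model)) {
    stop("graph carries no frozen model; use the gmm weighting scheme",
         call. = FALSE)
  }
  if (is.null(x_new)) {
    w <- rep(0, length(model$sample_ids))
    names(w) <- model$sample_ids
    return(w)
  }
  stopifnot(length(x_new) == length(model$center))
  sc <- ((x_new - model$center) / model$scale) %*% model$rotation
  pred <- stats::predict(model$fit, newdata = sc)
  z_u <- as.numeric(pred$z)
  w <- as.numeric(model$z %*% z_u) - sum(model$pro^2) - model$C + model$shift
  names(w) <- model$sample_ids
  w
}

#' Build one signed sample graph per omic
#'
#' @param omics List of [omic_matrix()] objects.
#' @param registry The [sample_registry()]; built from `omics` when `NULL`.
#' @param cfg A [weighting_config()].
#' @return Named list of `omic_graph` objects sharing the registry's sample
#'   order. Deterministic given `cfg$rng_seed`.
#' @export
build_graphs <- function(omics, registry = NULL, cfg = weighting_config()) {
  registry <- registry %||% sample_registry(omics)
  graphs <- purrr::imap(omics, function(o, i) {
    idx <- match(o$omic_id, names(registry$membership))
    ocfg <- cfg
    ocfg$rng_seed <- cfg$rng_seed + (idx - 1L) * 100000L
    switch(cfg$scheme,
           consensus = consensus_edge_weights(o, registry, ocfg),
           gmm = gmm_edge_weights(o, registry, ocfg))
  })
  names(graphs) <- vapply(omics, function(o) o$omic_id, character(1))
  graphs
}

#' Export graphs as a tidy edge list
#'
#' @param graphs List of `omic_graph` objects.
#' @param keep_zero Keep zero-weight (unmeasured / never co-sampled) edges.
#' @return A tibble with columns `sample_u`, `sample_v`, `omic`, `weight`,
#'   one row per unordered measured pair.
#' @export
graph_edge_list <- function(graphs, keep_zero = FALSE) {
  purrr::map_dfr(graphs, function(g) {
    ids <- rownames(g$weights)
    ut <- upper.tri(g$weights)
    idx <- which(ut, arr.ind = TRUE)
    tb <- tibble::tibble(sample_u = ids[idx[, 1L]],
                         sample_v = ids[idx[, 2L]],
                         omic = g$omic_id,
                         weight = g$weights[ut])
    if (!keep_zero) tb <- dplyr::filter(tb, .data$weight != 0)
    tb
  })
}
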