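# mock base clusterer producing two known partitions of 20 samples with the
# same pair-density (avg(cl_r) = 57/190 = 0.3 in every run): partition A for
# runs 1..40, partition B (samples 1 and 20 swapped) afterwards
mock_labels_a <- rep(1:4, c(9, 6, 4, 1))
mock_labels_b <- replace(mock_labels_a, c(1, 20), c(4, 1))
mock_clusterer <- function(x, seed) {
  if (seed <= 40) mock_labels_a[seq_len(nrow(x))] else
    mock_labels_b[seq_len(nrow(x))]
}

mock_omic <- function(n = 20L, id = "A") {
  omic_matrix(matrix(rnorm(5 * n), 5, n,
                     dimnames = list(NULL, sprintf("s%02d", seq_len(n)))),
              id, drop_constant = FALSE)
}

test_that("consensus weights follow the centred co-clustering formula", {
  o <- mock_omic()
  reg <- sample_registry(list(o))
  cfg <- weighting_config("consensus", C = 0.2, R = 50L,
                          subsample_fraction = 1,
                          base_clusterer = mock_clusterer, rng_seed = 0L)
  g <- consensus_edge_weights(o, reg, cfg)
  # sample 1 co-clusters with sample 2 in 40 of 50 runs, avg(cl_r) = 0.3,
  # C = 0.2: (40 * (1 - 0.3) + 10 * (0 - 0.3)) / 50 - 0.2 = 0.3
  expect_equal(g$weights[1, 2], 0.3)
  # co-clustered in every run: (1 - 0.3) - 0.2 = 0.5
  expect_equal(g$weights[2, 3], 0.5)
  # never co-clustered: (0 - 0.3) - 0.2 = -0.5
  expect_equal(g$weights[10, 16], -0.5)
  expect_equal(g$weights, t(g$weights))
  expect_true(all(diag(g$weights) == 0))
})

test_that("consensus weights match a naive recomputation under subsampling", {
  o <- mock_omic(24L)
  reg <- sample_registry(list(o))
  cfg <- weighting_config("consensus", C = 0.2, R = 12L,
                          subsample_fraction = 0.75,
                          base_clusterer = mock_clusterer, rng_seed = 0L)
  g <- consensus_edge_weights(o, reg, cfg)
  m <- 24L
  ns <- floor(0.75 * m)
  runs <- lapply(seq_len(12L), function(r) {
    sub <- withr::with_seed(r, sort(sample.int(m, ns)))
    list(sub = sub, labels = mock_clusterer(matrix(0, ns, 1), r))
  })
  expect_equal(unname(g$weights), naive_consensus(runs, m, C = 0.2),
               tolerance = 1e-12)
  # a pair never jointly sampled keeps weight exactly 0
  cnt <- matrix(0, m, m)
  for (r in runs) cnt[r$sub, r$sub] <- cnt[r$sub, r$sub] + 1
  if (any(cnt[upper.tri(cnt)] == 0)) {
    idx <- which(cnt == 0 & upper.tri(cnt), arr.ind = TRUE)[1L, ]
    expect_identical(g$weights[idx[1L], idx[2L]], 0)
  }
})

test_that("samples unmeasured in an omic have zero incident weight", {
  ids <- sprintf("s%02d", 1:21)
  oa <- omic_matrix(matrix(rnorm(5 * 21), 5, 21,
                           dimnames = list(NULL, ids)), "A",
                    drop_constant = FALSE)
  ob <- omic_matrix(matrix(rnorm(5 * 20), 5, 20,
                           dimnames = list(NULL, ids[-1L])), "B",
                    drop_constant = FALSE)
  reg <- sample_registry(list(oa, ob))
  cfg <- weighting_config("consensus", R = 5L,
                          base_clusterer = mock_clusterer, rng_seed = 0L)
  g <- consensus_edge_weights(ob, reg, cfg)
  expect_true(all(g$weights[1, ] == 0))
  expect_true(all(g$weights[, 1] == 0))
  expect_false(g$measured[1L])
})

test_that("well-separated blobs give higher within- than between weights", {
  ds <- blob_fixture()
  cfg <- weighting_config("consensus", R = 10L, rng_seed = 3L)
  g <- build_graphs(ds$omics, ds$registry, cfg)[[1L]]
  w <- g$weights
  a <- which(ds$labels == 1L)
  b <- which(ds$labels == 2L)
  within <- c(w[a, a][upper.tri(w[a, a])], w[b, b][upper.tri(w[b, b])])
  between <- as.vector(w[a, b])
  expect_gt(min(within), max(between))
  # consensus weights live in [-1 - C, 1 - C] (shift 0)
  expect_true(all(w >= -1.2 - 1e-12 & w <= 0.8 + 1e-12))
})

test_that("graph construction is deterministic and shift acts additively", {
  ds <- blob_fixture()
  cfg <- weighting_config("consensus", R = 5L, subsample_fraction = 1,
                          rng_seed = 9L)
  g1 <- build_graphs(ds$omics, ds$registry, cfg)
  g2 <- build_graphs(ds$omics, ds$registry, cfg)
  expect_identical(g1[[1L]]$weights, g2[[1L]]$weights)
  cfg_shift <- cfg
  cfg_shift$global_shift <- 0.1
  g3 <- build_graphs(ds$omics, ds$registry, cfg_shift)[[1L]]
  off <- upper.tri(g3$weights)
  expect_equal(g3$weights[off], g1[[1L]]$weights[off] + 0.1,
               tolerance = 1e-12)
  expect_true(all(diag(g3$weights) == 0))
})

test_that("gmm weights encode soft co-membership minus expected overlap", {
  ds <- blob_fixture()
  o <- ds$omics[[1L]]
  o$values[, 2L] <- o$values[, 1L]  # sample 2 duplicates sample 1
  reg <- sample_registry(list(o))
  g <- gmm_edge_weights(o, reg, weighting_config("gmm", rng_seed = 5L))
  pro <- g$model$pro
  base <- sum(pro^2)
  # duplicate points share a one-hot posterior: weight ~ 1 - sum(pi^2) - C
  expect_equal(g$weights[1, 2], 1 - base - 0.2, tolerance = 0.02)
  # samples from different blobs have orthogonal posteriors
  expect_equal(g$weights[1, 25], -base - 0.2, tolerance = 0.02)
  # mean pair similarity ~ sum(pi^2), so the mean weight is about -C
  off <- g$weights[upper.tri(g$weights)]
  expect_lt(abs(mean(off) + 0.2), 0.05)
})

test_that("frozen gmm models score new samples consistently", {
  ds <- blob_fixture()
  reg <- ds$registry
  g <- gmm_edge_weights(ds$omics[[1L]], reg,
                        weighting_config("gmm", rng_seed = 5L))
  # a copy of training sample 1 must get (almost) its weight vector
  w_new <- new_sample_weights(g, ds$omics[[1L]]$values[, 1L])
  expect_equal(unname(w_new[-1L]), unname(g$weights[1L, -1L]),
               tolerance = 1e-6)
  expect_error(new_sample_weights(
    structure(list(model = NULL), class = "omic_graph"), rnorm(5)),
    "frozen model")
})
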