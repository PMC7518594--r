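test_that("a dominant module is kept and filtering is deterministic", {
  set.seed(5)
  w <- random_signed_graph(40, sd = 0.1, shift = -0.2)
  w[1:10, 1:10] <- abs(w[1:10, 1:10]) + 1   # globally maximal edges
  diag(w) <- 0
  w <- (w + t(w)) / 2
  g <- graphs_from_matrices(list(o1 = w))
  ids <- rownames(g$o1$weights)
  sol <- module_solution(list(module(1:10, "o1")), 11:40, ids)
  cfg <- null_test_config(n_null = 100L, rng_seed = 1L)
  f1 <- filter_modules(sol, g, cfg)
  f2 <- filter_modules(sol, g, cfg)
  expect_length(f1$modules, 1L)
  expect_identical(f1$modules, sol$modules)  # retained modules unaltered
  expect_identical(attr(f1, "filter_report"), attr(f2, "filter_report"))
})

test_that("random modules on a structureless graph are usually removed", {
  set.seed(6)
  w <- random_signed_graph(50)
  g <- graphs_from_matrices(list(o1 = w))
  ids <- rownames(g$o1$weights)
  removed <- vapply(1:40, function(r) {
    s <- withr::with_seed(100 + r, sample.int(50, 10))
    sol <- module_solution(list(module(s, "o1")), setdiff(1:50, s), ids)
    f <- filter_modules(sol, g, null_test_config(n_null = 200L,
                                                 rng_seed = r))
    length(f$modules) == 0L
  }, logical(1))
  expect_gte(mean(removed), 0.85)
  # removed samples become lonely
  s <- withr::with_seed(101, sample.int(50, 10))
  sol <- module_solution(list(module(s, "o1")), setdiff(1:50, s), ids)
  f <- filter_modules(sol, g, null_test_config(n_null = 200L, rng_seed = 1L))
  if (length(f$modules) == 0L) expect_setequal(f$lonely, 1:50)
})

test_that("minimal-size-only scope always retains modules larger than eta", {
  set.seed(7)
  w <- random_signed_graph(50)
  g <- graphs_from_matrices(list(o1 = w))
  ids <- rownames(g$o1$weights)
  big <- withr::with_seed(42, sample.int(50, 20))
  sol <- module_solution(list(module(big, "o1")), setdiff(1:50, big), ids)
  cfg <- null_test_config(n_null = 200L, test_scope = "minimal_size_only",
                          eta = 10L, rng_seed = 1L)
  f <- filter_modules(sol, g, cfg)
  expect_length(f$modules, 1L)
  expect_false(attr(f, "filter_report")$tested[1L])
})

test_that("the keep threshold is the ceiling(q * n)th null order statistic", {
  # directly check the quantile arithmetic on the report
  set.seed(8)
  w <- random_signed_graph(30)
  g <- graphs_from_matrices(list(o1 = w))
  ids <- rownames(g$o1$weights)
  sol <- module_solution(list(module(1:8, "o1")), 9:30, ids)
  cfg <- null_test_config(n_null = 100L, keep_quantile = 0.99, rng_seed = 3L)
  f <- filter_modules(sol, g, cfg)
  rep <- attr(f, "filter_report")
  nulls <- withr::with_seed(cfg$rng_seed + 1L, {
    vapply(seq_len(100L), function(r) {
      idx <- sample.int(30, 8)
      sum(w[idx, idx]) / 2
    }, numeric(1))
  })
  expect_equal(rep$null_quantile, sort(nulls)[99L])
  expect_equal(rep$kept, rep$observed > rep$null_quantile)
})
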