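test_that("ARI matches hand evaluation and basic identities", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # label-permutation invariance
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), c(3, 3, 1, 1, 2)), 1)
  # symmetry
  a <- c(1, 1, 2, 3, 3, 2, 1)
  b <- c(2, 1, 2, 3, 1, 2, 1)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
})

test_that("ARI agrees with brute-force pair counting on all small partitions", {
  parts <- all_partitions(5L)
  expect_length(parts, 52L)  # Bell(5)
  for (i in seq_along(parts)) {
    for (j in seq(i, length(parts), by = 7L)) {
      expect_equal(adjusted_rand_index(parts[[i]], parts[[j]]),
                   brute_force_ari(parts[[i]], parts[[j]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("ARI agrees with independent references on random partitions", {
  set.seed(20)
  for (r in 1:25) {
    a <- sample.int(3, 8, replace = TRUE)
    b <- sample.int(4, 8, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), brute_force_ari(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("lonely-sample conventions behave as documented", {
  a <- c(1, 1, 2, 2, NA, NA)
  b <- c(1, 1, 2, 2, 1, 2)
  expect_equal(adjusted_rand_index(a, b, "exclude"), 1)
  # own_cluster pools lonely samples into one extra cluster
  expect_equal(adjusted_rand_index(a, b, "own_cluster"),
               brute_force_ari(c(1, 1, 2, 2, 9, 9), b))
  # singleton_cluster gives each lonely sample its own cluster
  expect_equal(adjusted_rand_index(a, b, "singleton_cluster"),
               brute_force_ari(c(1, 1, 2, 2, 8, 9), b))
  expect_equal(adjusted_rand_index(c(-1, 1, 1, 2, 2), c(-1, 1, 1, 2, 2),
                                   "exclude"), 1)
  expect_error(adjusted_rand_index(c(NA, 1), c(1, 1), "exclude"),
               "fewer than 2")
})

test_that("coverage accuracy counts matched module-omic cells", {
  ids <- sprintf("s%03d", 1:30)
  truth <- rep(1:3, each = 10)
  names(truth) <- ids
  cov <- rbind(c(TRUE, FALSE), c(TRUE, TRUE), c(FALSE, TRUE))
  colnames(cov) <- c("o1", "o2")
  perfect <- module_solution(list(module(1:10, "o1"),
                                  module(11:20, c("o1", "o2")),
                                  module(21:30, "o2")), integer(0), ids)
  expect_equal(coverage_accuracy(perfect, truth, cov), 1)
  one_wrong <- module_solution(list(module(1:10, "o1"),
                                    module(11:20, "o1"),
                                    module(21:30, "o2")), integer(0), ids)
  expect_equal(coverage_accuracy(one_wrong, truth, cov), 5 / 6)
  # an unmatched truth module counts all its cells wrong
  two_found <- module_solution(list(module(1:10, "o1"),
                                    module(11:20, c("o1", "o2"))),
                               21:30, ids)
  expect_equal(coverage_accuracy(two_found, truth, cov), 4 / 6)
})

test_that("module matching maximises total overlap", {
  ov <- rbind(c(9, 1, 0), c(8, 0, 0), c(0, 0, 5))
  # greedy would give row1 -> col1; the optimum assigns row2 -> col1
  got <- modulomics:::match_modules(ov)
  expect_equal(got[3L], 3L)
  score <- sum(ov[cbind(which(!is.na(got)), got[!is.na(got)])])
  expect_equal(score, 9 + 5)  # row1->1 (9), row3->3 (5), row2 unmatched adds 0
})
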