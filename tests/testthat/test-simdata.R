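test_that("generated datasets have the declared shapes and labels", {
  spec <- sim_spec(module_sizes = c(10L, 15L), n_outliers = 3L,
                   omic_names = c("a", "b"), features_per_omic = c(50L, 80L),
                   rng_seed = 1L)
  ds <- simulate_omics(spec)
  expect_length(ds$labels, 28L)
  expect_equal(sum(ds$labels == -1L), 3L)
  expect_equal(dim(ds$omics$a$values), c(50L, 28L))
  expect_equal(dim(ds$omics$b$values), c(80L, 28L))
  ds2 <- simulate_omics(sim_spec(module_sizes = c(10L, 15L), n_outliers = 3L,
                                 omic_names = c("a", "b"),
                                 features_per_omic = c(50L, 80L),
                                 rng_seed = 2L))
  expect_false(identical(ds$omics$a$values, ds2$omics$a$values))
  expect_identical(ds$labels, ds2$labels)
})

test_that("planted mean shifts are recoverable from sample means", {
  spec <- sim_spec(module_sizes = 200L, omic_names = "a", rng_seed = 3L)
  ds <- simulate_omics(spec)
  x <- ds$omics$a$values
  shift <- rowMeans(x[1:30, ])      # informative block, one module
  # displacement norm is effect * sqrt(n_informative) by construction
  expect_equal(sqrt(sum(shift^2)), 2.5 * sqrt(30), tolerance = 0.1)
  # non-informative features stay centred at zero
  expect_lt(max(abs(rowMeans(x[31:100, ]))), 4 / sqrt(200))
})

test_that("structure-free samples show no signal on informative features", {
  cov <- rbind(c(TRUE, FALSE), c(TRUE, TRUE))
  ds <- simulate_omics(sim_spec(module_sizes = c(40L, 40L), n_outliers = 5L,
                                omic_names = c("a", "b"), coverage = cov,
                                rng_seed = 4L))
  xb <- ds$omics$b$values
  m1 <- which(ds$labels == 1L)      # module 1 has no structure in omic b
  expect_lt(sqrt(sum(rowMeans(xb[1:30, m1])^2)), 1.5)
  m2 <- which(ds$labels == 2L)
  expect_gt(sqrt(sum(rowMeans(xb[1:30, m2])^2)), 10)
})

test_that("presets match the two simulation designs", {
  s1 <- sim1_preset()
  expect_equal(sum(s1$module_sizes) + s1$n_outliers, 305L)
  expect_equal(unname(s1$coverage),
               rbind(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE),
                     c(TRUE, TRUE), c(TRUE, TRUE)))
  s2 <- sim2_preset(TRUE)
  expect_length(s2$omic_names, 3L)
  expect_equal(sum(s2$module_sizes), 150L)
  # modules 2-5 share one mean group in omic 1
  expect_length(unique(s2$mean_groups[2:5, 1L]), 1L)
  expect_length(unique(s2$mean_groups[2:5, 3L]), 4L)
  expect_true(s2$weak_omics[2L])
  expect_length(sim2_preset(FALSE)$omic_names, 2L)
})

test_that("tcga-style masking removes equal groups from each omic", {
  ds <- simulate_omics(sim_spec(module_sizes = rep(100L, 3L),
                                omic_names = c("a", "b", "c"),
                                rng_seed = 5L))
  pd <- make_partial(ds, "tcga_style", 0.4, rng_seed = 9L)
  removed <- vapply(pd$registry$membership, function(m) sum(!m), integer(1))
  expect_equal(unname(removed), rep(40L, 3L))
  # each removed sample is missing from exactly one omic
  miss <- Reduce(`+`, lapply(pd$registry$membership, function(m) !m))
  expect_true(all(miss <= 1L))
  expect_length(pd$registry$sample_ids, 300L)
})

test_that("independent masking keeps every sample measured somewhere", {
  ds <- simulate_omics(sim_spec(module_sizes = rep(50L, 2L),
                                omic_names = c("a", "b"), rng_seed = 6L))
  pd <- make_partial(ds, "independent", 0.2, rng_seed = 3L)
  kept <- vapply(pd$registry$membership, sum, integer(1))
  expect_true(all(kept >= 78L & kept <= 100L))
  expect_length(pd$registry$sample_ids, 100L)
  pd0 <- make_partial(ds, "independent", 0, rng_seed = 3L)
  expect_true(all(vapply(pd0$registry$membership, all, logical(1))))
})
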