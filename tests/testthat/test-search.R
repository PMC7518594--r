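# planted two-module, two-omic graphs: module A = 1:10 heavy in o1 only,
# module B = 11:20 heavy in both; samples 21:24 background
planted_graphs <- function(noise = 0.05, seed = 1) {
  set.seed(seed)
  n <- 24
  base <- function() random_signed_graph(n, sd = noise, shift = -0.3)
  w1 <- base(); w1[1:10, 1:10] <- w1[1:10, 1:10] + 0.8
  w2 <- base()
  w1[11:20, 11:20] <- w1[11:20, 11:20] + 0.8
  w2[11:20, 11:20] <- w2[11:20, 11:20] + 0.8
  diag(w1) <- diag(w2) <- 0
  w1 <- (w1 + t(w1)) / 2; w2 <- (w2 + t(w2)) / 2
  graphs_from_matrices(list(o1 = w1, o2 = w2))
}

test_that("seeds are disjoint, cover all omics, and partition with lonely", {
  g <- planted_graphs()
  p <- search_params(24, S = 3L, k = 6L, eta = 3L, rng_seed = 2L)
  sol <- find_seeds(g, p)
  sizes <- lengths(lapply(sol$modules, `[[`, "samples"))
  expect_true(all(sizes <= 7L))
  all_s <- unlist(lapply(sol$modules, `[[`, "samples"))
  expect_false(anyDuplicated(all_s) > 0)
  expect_setequal(c(all_s, sol$lonely), 1:24)
  expect_true(all(vapply(sol$modules, function(m)
    setequal(m$omics, c("o1", "o2")), logical(1))))
  expect_identical(find_seeds(g, p), sol)  # deterministic
})

test_that("an anchor without positive neighbours forms a singleton seed", {
  w <- -abs(random_signed_graph(10))
  g <- graphs_from_matrices(list(o1 = w))
  p <- search_params(10, S = 10L, k = 3L, eta = 2L, rng_seed = 1L)
  sol <- find_seeds(g, p)
  expect_true(all(lengths(lapply(sol$modules, `[[`, "samples")) == 1L))
})

test_that("incremental action gains equal full objective recomputation", {
  set.seed(31)
  p <- search_params(20, eta = 3L, batch_cap = 4L, rng_seed = 1L)
  for (rep in 1:10) {
    g <- graphs_from_matrices(list(o1 = random_signed_graph(20),
                                   o2 = random_signed_graph(20)))
    sol <- random_solution(20, 2L, c("o1", "o2"))
    before <- solution_objective(sol, g)
    cands <- modulomics:::propose_actions(sol, 1L, g, p)
    for (act in cands) {
      gain <- action_gain(act, sol, g, p)
      expect_equal(gain, act$gain, tolerance = 1e-9)
      after <- solution_objective(apply_action(sol, act), g)
      expect_equal(after - before, gain, tolerance = 1e-9,
                   label = paste("kind", act$kind))
    }
  }
})

test_that("removing a just-added sample negates the addition gain", {
  g <- planted_graphs()
  ids <- rownames(g$o1$weights)
  sol <- module_solution(list(module(1:9, "o1")), c(10:24), ids)
  p <- search_params(24, eta = 3L, rng_seed = 1L)
  add <- action_record("add_samples", 1L, samples = 10L)
  gain <- action_gain(add, sol, g, p)
  sol2 <- apply_action(sol, add)
  rem <- action_record("remove_sample", 1L, sample = 10L)
  expect_equal(action_gain(rem, sol2, g, p), -gain, tolerance = 1e-12)
})

test_that("eta-violating actions report -Inf gain", {
  g <- planted_graphs()
  ids <- rownames(g$o1$weights)
  sol <- module_solution(list(module(1:5, "o1"), module(11:20, "o1")),
                         c(6:10, 21:24), ids)
  p <- search_params(24, eta = 5L, rng_seed = 1L)
  expect_identical(action_gain(action_record("remove_sample", 1L,
                                             sample = 1L), sol, g, p), -Inf)
  expect_identical(action_gain(
    action_record("split", 2L, part = 11:13), sol, g, p), -Inf)
  expect_identical(action_gain(
    action_record("new_module", NA_integer_, samples = 21:22, omic = "o1"),
    sol, g, p), -Inf)
})

test_that("optimisation strictly increases the objective and converges", {
  g <- planted_graphs()
  p <- search_params(24, S = 4L, k = 5L, eta = 3L, restarts = 1L,
                     rng_seed = 3L)
  sol <- optimize_solution(find_seeds(g, p), g, p)
  trace <- attr(sol, "objective_trace")
  expect_true(length(trace) <= 1L || all(diff(trace) > 0))
  expect_lt(attr(sol, "epochs"), p$max_epochs)
  expect_true(all(lengths(lapply(sol$modules, `[[`, "samples")) >= p$eta))
})

test_that("planted modules and their omic coverage are recovered", {
  g <- planted_graphs()
  p <- search_params(24, S = 4L, k = 5L, eta = 3L, rng_seed = 5L)
  best <- NULL
  for (i in 1:5) {
    pi <- p; pi$rng_seed <- p$rng_seed + i
    s <- optimize_solution(find_seeds(g, pi), g, pi)
    if (is.null(best) ||
        solution_objective(s, g) > solution_objective(best, g)) best <- s
  }
  found <- lapply(best$modules, `[[`, "samples")
  expect_true(any(vapply(found, setequal, logical(1), y = 1:10)))
  expect_true(any(vapply(found, setequal, logical(1), y = 11:20)))
  omics_a <- best$modules[[which(vapply(found, setequal, logical(1),
                                        y = 1:10))]]$omics
  expect_identical(omics_a, "o1")
})

test_that("a planted module split across two seeds gets merged", {
  set.seed(9)
  mk <- function() {
    w <- random_signed_graph(20, sd = 0.05, shift = -0.4)
    w[1:12, 1:12] <- w[1:12, 1:12] + 1
    diag(w) <- 0
    w
  }
  # the planted module is heavy in both omics, but the two seed halves each
  # cover only one of them: only a merge (with the union omic set) can claim
  # the full double-omic weight in a single action
  g <- graphs_from_matrices(list(o1 = mk(), o2 = mk()))
  ids <- rownames(g$o1$weights)
  start <- module_solution(list(module(1:6, "o1"), module(7:12, "o2")),
                           13:20, ids)
  p <- search_params(20, eta = 3L, rng_seed = 4L)
  sol <- optimize_solution(start, g, p)
  counts <- attr(sol, "action_counts")
  expect_gte(counts[["merge"]], 1L)
  big <- vapply(lapply(sol$modules, `[[`, "samples"),
                function(s) all(1:12 %in% s), logical(1))
  expect_true(any(big))
  expect_setequal(sol$modules[[which(big)]]$omics, c("o1", "o2"))
})

test_that("detection is deterministic and improves with restarts", {
  ds <- blob_fixture()
  w <- weighting_config("consensus", R = 8L, rng_seed = 13L)
  p1 <- search_params(40, restarts = 1L, eta = 5L, rng_seed = 13L)
  p5 <- search_params(40, restarts = 5L, eta = 5L, rng_seed = 13L)
  f1 <- detect_modules(ds, weighting = w, search = p1, significance = NULL)
  f5 <- detect_modules(ds, weighting = w, search = p5, significance = NULL)
  f5b <- detect_modules(ds, weighting = w, search = p5, significance = NULL)
  expect_gte(max(f5$diagnostics$restart_objectives$objective),
             f1$diagnostics$restart_objectives$objective[1L])
  expect_identical(f5$solution, f5b$solution)
})
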