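# Shared (memoised) fixtures. The simulation-study fits are expensive, and
# several properties are checked on the same runs (recovery, coverage,
# objective monotonicity, partial-data agreement), so they are computed once
# per session.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# two well-separated Gaussian blobs in one omic (weighting-scheme fixture)
blob_fixture <- function() {
  memo("blobs", {
    spec <- sim_spec(module_sizes = c(20L, 20L), omic_names = "o1",
                     rng_seed = 7L)
    simulate_omics(spec)
  })
}

# small three-module two-omic dataset and a converged fit (fast, gmm)
easy_gmm_fit <- function() {
  memo("easy_gmm", {
    ds <- simulate_omics(sim_spec(module_sizes = rep(30L, 3L),
                                  omic_names = c("o1", "o2"),
                                  rng_seed = 42L))
    fit <- detect_modules(ds, weighting = weighting_config("gmm",
                                                           rng_seed = 42L),
                          search = search_params(90L, restarts = 3L,
                                                 rng_seed = 42L))
    list(ds = ds, fit = fit)
  })
}

# full simulation-study runs (defaults; shared by several acceptance checks)
sim1_runs <- function() {
  memo("sim1_runs", {
    lapply(1:5, function(seed) {
      ds <- simulate_omics(sim1_preset(rng_seed = seed))
      fit <- detect_modules(
        ds, weighting = weighting_config("consensus", rng_seed = seed),
        search = search_params(305L, rng_seed = seed))
      list(seed = seed, ds = ds, fit = fit)
    })
  })
}

sim1_partial_runs <- function() {
  memo("sim1_partial", {
    lapply(sim1_runs(), function(run) {
      pd <- make_partial(run$ds, "independent", 0.2, rng_seed = run$seed)
      pfit <- detect_modules(
        pd$omics, pd$registry,
        weighting = weighting_config("consensus", rng_seed = run$seed),
        search = search_params(length(pd$registry$sample_ids),
                               rng_seed = run$seed))
      list(seed = run$seed, pd = pd, pfit = pfit, full = run$fit)
    })
  })
}

sim2_runs <- function(include_omic3) {
  key <- paste0("sim2_", include_omic3)
  memo(key, {
    lapply(1:5, function(seed) {
      ds <- simulate_omics(sim2_preset(include_omic3, rng_seed = seed))
      fit <- detect_modules(
        ds, weighting = weighting_config("consensus", rng_seed = seed),
        search = search_params(150L, rng_seed = seed))
      list(seed = seed, ds = ds, fit = fit)
    })
  })
}

easy_cv <- function() {
  memo("easy_cv", {
    ds <- easy_gmm_fit()$ds
    cross_validate(ds, weighting_config("gmm", rng_seed = 42L),
                   folds = 10L, truth = ds$labels, rng_seed = 42L)
  })
}
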