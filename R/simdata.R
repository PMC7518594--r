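#' Specify a synthetic multi-omic dataset with planted modules
#'
#' Generative description of a planted-module dataset. Each omic has
#' `features_per_omic` features of which `informative_features` carry signal.
#' For a module with structure in an omic, the informative features' means
#' are shifted along a fresh random (continuous) direction per mean group,
#' scaled so the per-feature root-mean-square shift is
#' `effect_size * noise_sd`; distinct groups therefore get distinct means
#' almost surely. Modules sharing a value in `mean_groups`
#' share their mean in that omic (used to make modules indistinguishable in
#' one omic); a value of 0 means no structure. Samples without structure in
#' an omic — modules not covering it, and outliers — keep pure background
#' noise on the informative features (so they carry no module-membership
#' signal there) and instead receive an independent per-sample random
#' displacement in the non-informative block, `diffuse_scale` times the
#' module-mean norm, which keeps them equidistant from every module and from
#' each other — neither clumping into a spurious null cluster nor acting as
#' de-facto members of a module.
#'
#' @param module_sizes Positive integers; samples per planted module.
#' @param n_outliers Samples belonging to no module (label -1).
#' @param omic_names Character vector of omic ids.
#' @param coverage Logical matrix (modules x omics): does the module have
#'   structure in the omic? Defaults to all-`TRUE`.
#' @param mean_groups Optional integer matrix (modules x omics); equal
#'   non-zero values share a mean, 0 = no structure. Defaults to one group
#'   per covered module.
#' @param features_per_omic Integer (recycled per omic), default 100.
#' @param informative_features Integer per omic, default 30 (5 for weak
#'   omics).
#' @param effect_size Mean separation in units of `noise_sd`, default 2.5.
#' @param weak_effect_size Effect used for omics flagged in `weak_omics`,
#'   default 1.0.
#' @param weak_omics Logical per omic; weak omics get few informative
#'   features and the smaller effect.
#' @param noise_sd Noise standard deviation, default 1.
#' @param diffuse_scale Norm of the structure-free samples' orthogonal
#'   displacement, relative to the module-mean norm (default 2).
#' @param rng_seed Integer seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(module_sizes, n_outliers = 0L,
                     omic_names = c("omic1", "omic2"),
                     coverage = NULL, mean_groups = NULL,
                     features_per_omic = 100L,
                     informative_features = NULL,
                     effect_size = 2.5, weak_effect_size = 1.0,
                     weak_omics = NULL, noise_sd = 1,
                     diffuse_scale = 2, rng_seed = 1L) {
  k <- length(module_sizes)
  L <- length(omic_names)
  stopifnot(k >= 1L, all(module_sizes > 0L), n_outliers >= 0L)
  coverage <- coverage %||% matrix(TRUE, k, L)
  stopifnot(nrow(coverage) == k, ncol(coverage) == L)
  if (any(rowSums(coverage) == 0L)) {
    stop("every module must cover at least one omic", call. = FALSE)
  }
  weak_omics <- weak_omics %||% rep(FALSE, L)
  features_per_omic <- rep_len(as.integer(features_per_omic), L)
  informative_features <- informative_features %||%
    ifelse(weak_omics, 5L, 30L)
  informative_features <- rep_len(as.integer(informative_features), L)
  if (any(informative_features > features_per_omic)) {
    stop("informative features exceed total features", call. = FALSE)
  }
  if (is.null(mean_groups)) {
    mean_groups <- matrix(0L, k, L)
    mean_groups[coverage] <- row(coverage)[coverage]
  }
  stopifnot(all((mean_groups > 0L) == coverage))
  dimnames(coverage) <- dimnames(mean_groups) <-
    list(paste0("module", seq_len(k)), omic_names)
  structure(
    list(module_sizes = as.integer(module_sizes),
         n_outliers = as.integer(n_outliers),
         omic_names = omic_names, coverage = coverage,
         mean_groups = mean_groups,
         features_per_omic = features_per_omic,
         informative_features = informative_features,
         effect_size = effect_size, weak_effect_size = weak_effect_size,
         weak_omics = weak_omics, noise_sd = noise_sd,
         diffuse_scale = diffuse_scale,
         rng_seed = as.integer(rng_seed)),
    class = "sim_spec"
  )
}

#' Generate a synthetic multi-omic dataset
#'
#' @param spec A [sim_spec()].
#' @return A list with `omics` (list of [omic_matrix()]), `registry`,
#'   `labels` (integer ground truth, outliers = -1, named by sample id),
#'   `coverage` (the ground-truth module x omic matrix) and `spec`.
#' @export
simulate_omics <- function(spec) {
  k <- length(spec$module_sizes)
  n <- sum(spec$module_sizes) + spec$n_outliers
  labels <- c(rep(seq_len(k), spec$module_sizes), rep(-1L, spec$n_outliers))
  ids <- sprintf("s%03d", seq_len(n))
  names(labels) <- ids
  sdn <- spec$noise_sd
  omics <- withr::with_seed(spec$rng_seed, {
    purrr::imap(stats::setNames(seq_along(spec$omic_names),
                                spec$omic_names), function(li, lname) {
      p <- spec$features_per_omic[li]
      m_inf <- spec$informative_features[li]
      eff <- if (spec$weak_omics[li]) spec$weak_effect_size else
        spec$effect_size
      x <- matrix(stats::rnorm(p * n, 0, sdn), p, n)
      groups <- spec$mean_groups[, li]
      # random continuous direction, per-feature RMS shift = eff * sdn
      rand_dir <- function(d, norm) {
        v <- stats::rnorm(d)
        norm * v / sqrt(sum(v^2))
      }
      mu_norm <- eff * sdn * sqrt(m_inf)
      for (g in unique(groups[groups > 0L])) {
        mu <- rand_dir(m_inf, mu_norm)
        cols <- which(labels %in% which(groups == g))
        x[seq_len(m_inf), cols] <- x[seq_len(m_inf), cols] + mu
      }
      # structure-free samples: informative features stay pure background
      # (no membership signal); a displacement orthogonal to the signal
      # space keeps them from clumping into a spurious null cluster
      diffuse <- which(labels == -1L | labels %in% which(groups == 0L))
      orth <- (m_inf + 1L):p
      if (length(orth) == 0L) orth <- seq_len(m_inf)
      for (u in diffuse) {
        x[orth, u] <- x[orth, u] +
          rand_dir(length(orth), spec$diffuse_scale * mu_norm)
      }
      omic_matrix(x, lname, feature_ids = paste0(lname, "_f", seq_len(p)),
                  sample_ids = ids, drop_constant = FALSE)
    })
  })
  list(omics = omics, registry = sample_registry(omics),
       labels = labels, coverage = spec$coverage, spec = spec)
}

#' Preset: five modules with heterogeneous omic coverage
#'
#' 300 samples in five equal-size modules over two omics — module 1 has
#' structure only in omic 1, module 2 only in omic 2, modules 3-5 in both —
#' plus five outlier samples belonging to no module.
#'
#' @param rng_seed Integer seed.
#' @return A [sim_spec()].
#' @export
sim1_preset <- function(rng_seed = 1L) {
  cov <- rbind(c(TRUE, FALSE), c(FALSE, TRUE),
               c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, TRUE))
  sim_spec(module_sizes = rep(60L, 5L), n_outliers = 5L,
           omic_names = c("omic1", "omic2"), coverage = cov,
           rng_seed = rng_seed)
}

#' Preset: five modules, one omic uninformative, one weak
#'
#' 150 samples in five modules over three omics. Module 1 is distinct
#' everywhere; modules 2-5 share a single mean in omic 1 (indistinguishable
#' there), are separated by only a few weakly shifted features in omic 2, and
#' are clearly separated in omic 3. With `include_omic3 = FALSE` the third
#' omic is dropped — the condition under which modules 2-5 are expected to
#' collapse into one module covering only omic 1.
#'
#' @param include_omic3 Keep the third (strong) omic.
#' @param rng_seed Integer seed.
#' @return A [sim_spec()].
#' @export
sim2_preset <- function(include_omic3 = TRUE, rng_seed = 1L) {
  groups <- cbind(omic1 = c(1L, 2L, 2L, 2L, 2L),
                  omic2 = 1:5,
                  omic3 = 1:5)
  weak <- c(FALSE, TRUE, FALSE)
  L <- if (include_omic3) 3L else 2L
  sim_spec(module_sizes = rep(30L, 5L), n_outliers = 0L,
           omic_names = colnames(groups)[seq_len(L)],
           coverage = groups[, seq_len(L), drop = FALSE] > 0L,
           mean_groups = groups[, seq_len(L), drop = FALSE],
           weak_omics = weak[seq_len(L)],
           rng_seed = rng_seed)
}

#' Mask samples from some omics (partial-dataset protocols)
#'
#' Two removal protocols: `"tcga_style"` samples `fraction` (default 40%) of
#' the samples, partitions them into as many equal groups as there are omics,
#' and removes each group from one omic; `"independent"` removes `fraction`
#' (default 20%) of the samples from each omic independently. Every sample is
#' guaranteed to stay measured in at least one omic: a sample drawn for
#' removal everywhere is restored in one random omic.
#'
#' @param dataset A list with `omics` (and optionally `registry`), e.g. from
#'   [simulate_omics()] or [load_omics()].
#' @param protocol `"tcga_style"` or `"independent"`.
#' @param fraction Fraction of samples removed (per the protocol's meaning).
#' @param rng_seed Integer seed.
#' @return A list with the masked `omics` and rebuilt `registry` (plus any
#'   other fields of `dataset`, carried through).
#' @export
make_partial <- function(dataset, protocol = c("tcga_style", "independent"),
                         fraction = NULL, rng_seed = 1L) {
  protocol <- match.arg(protocol)
  omics <- dataset$omics
  L <- length(omics)
  fraction <- fraction %||% if (protocol == "tcga_style") 0.4 else 0.2
  stopifnot(fraction >= 0, fraction < 1)
  all_ids <- unique(unlist(lapply(omics, `[[`, "sample_ids")))
  n <- length(all_ids)
  if (protocol == "tcga_style" && L != 3L) {
    stop("tcga_style protocol requires exactly 3 omics", call. = FALSE)
  }
  removed <- withr::with_seed(rng_seed, {
    if (protocol == "tcga_style") {
      picked <- sample(all_ids, floor(fraction * n))
      grp <- rep_len(seq_len(L), length(picked))
      lapply(seq_len(L), function(l) picked[grp == l])
    } else {
      rem <- lapply(omics, function(o) {
        sample(o$sample_ids, floor(fraction * length(o$sample_ids)))
      })
      # keep every sample measured somewhere
      gone <- Reduce(intersect, rem)
      for (sid in gone) {
        keep_in <- sample.int(L, 1L)
        rem[[keep_in]] <- setdiff(rem[[keep_in]], sid)
      }
      rem
    }
  })
  new_omics <- purrr::map2(omics, removed, function(o, rm) {
    keep <- !(o$sample_ids %in% rm)
    if (!any(keep)) stop("an omic would lose all samples", call. = FALSE)
    omic_matrix(o$values[, keep, drop = FALSE], o$omic_id,
                feature_ids = o$feature_ids,
                sample_ids = o$sample_ids[keep], drop_constant = FALSE)
  })
  names(new_omics) <- names(omics)
  reg <- sample_registry(new_omics)
  if (length(reg$sample_ids) < n) {
    stop("removal would leave ", n - length(reg$sample_ids),
         " sample(s) measured nowhere", call. = FALSE)
  }
  out <- dataset
  out$omics <- new_omics
  out$registry <- reg
  out
}
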