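is_lonely_label <- function(x) {
  if (is.numeric(x)) is.na(x) | x == -1 else is.na(x) | x == "lonely"
}

#' Adjusted Rand Index with explicit lonely-sample handling
#'
#' Hubert-Arabie ARI from the pair-counting contingency table. Samples can be
#' marked lonely/unassigned (`NA`, `-1`, or `"lonely"`); three conventions
#' are offered because headline scores are sensitive to them:
#' `"own_cluster"` (default) pools all lonely samples of a labelling into one
#' extra cluster, `"singleton_cluster"` gives each lonely sample its own
#' cluster, `"exclude"` drops samples lonely in either labelling.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @param lonely_mode One of `"own_cluster"`, `"exclude"`,
#'   `"singleton_cluster"`.
#' @return The ARI (1 = identical partitions, about 0 = chance agreement).
#' @export
adjusted_rand_index <- function(labels_a, labels_b,
                                lonely_mode = c("own_cluster", "exclude",
                                                "singleton_cluster")) {
  lonely_mode <- match.arg(lonely_mode)
  stopifnot(length(labels_a) == length(labels_b))
  la <- is_lonely_label(labels_a)
  lb <- is_lonely_label(labels_b)
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  if (lonely_mode == "exclude") {
    keep <- !(la | lb)
    a <- a[keep]
    b <- b[keep]
  } else if (lonely_mode == "own_cluster") {
    a[la] <- ".lonely"
    b[lb] <- ".lonely"
  } else {
    a[la] <- paste0(".lonely", which(la))
    b[lb] <- paste0(".lonely", which(lb))
  }
  if (length(a) < 2L) stop("fewer than 2 samples after lonely handling",
                           call. = FALSE)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(length(a), 2)
  max_index <- (ai + bj) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (nij - expected) / (max_index - expected)
}

# exact max-overlap assignment of found modules to truth modules by
# branch-and-bound over the (small) overlap matrix; returns truth index per
# found module (NA = unmatched)
match_modules <- function(overlap) {
  nf <- nrow(overlap)
  nt <- ncol(overlap)
  best <- list(score = -1, assign = rep(NA_integer_, nf))
  ub_tail <- rev(cumsum(rev(apply(overlap, 1L, max))))  # upper bound
  recurse <- function(i, used, score, assign) {
    if (i > nf) {
      if (score > best$score) best <<- list(score = score, assign = assign)
      return()
    }
    if (score + ub_tail[i] <= best$score) return()
    options <- order(-overlap[i, ])
    for (j in c(options[!(options %in% used)], NA_integer_)) {
      if (is.na(j)) {
        assign[i] <- NA_integer_
        recurse(i + 1L, used, score, assign)
        break
      }
      assign[i] <- j
      recurse(i + 1L, c(used, j), score + overlap[i, j], assign)
    }
  }
  recurse(1L, integer(0), 0, rep(NA_integer_, nf))
  best$assign
}

#' Coverage-matrix recovery accuracy
#'
#' Matches found modules to planted modules by maximal sample overlap (an
#' exact assignment), then scores the fraction of (planted module, omic)
#' cells where the found module's covered-omic indicator equals the planted
#' coverage. Planted modules left unmatched count all their cells as wrong.
#'
#' @param solution A `module_solution` (or `modulomics_fit`).
#' @param truth_labels Integer ground-truth labels (outliers -1), in the
#'   solution's sample order.
#' @param truth_coverage Logical planted-coverage matrix (modules x omics),
#'   with omic ids as column names.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_accuracy <- function(solution, truth_labels, truth_coverage) {
  if (inherits(solution, "modulomics_fit")) solution <- solution$solution
  mods <- solution$modules
  if (length(mods) == 0L) stop("no found modules", call. = FALSE)
  omic_ids <- colnames(truth_coverage)
  nt <- nrow(truth_coverage)
  truth_labels <- align_labels(truth_labels, solution$sample_ids)
  overlap <- vapply(seq_len(nt), function(j) {
    vapply(mods, function(m) sum(truth_labels[m$samples] == j, na.rm = TRUE),
           numeric(1))
  }, numeric(length(mods)))
  overlap <- matrix(overlap, nrow = length(mods), ncol = nt)
  assign <- match_modules(overlap)
  correct <- 0L
  for (j in seq_len(nt)) {
    fi <- match(j, assign)
    if (is.na(fi)) next  # unmatched truth module: all cells wrong
    found_cov <- omic_ids %in% mods[[fi]]$omics
    correct <- correct + sum(found_cov == truth_coverage[j, ])
  }
  correct / (nt * length(omic_ids))
}

align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels)) && all(sample_ids %in% names(labels))) {
    labels <- labels[sample_ids]
  }
  stopifnot(length(labels) == length(sample_ids))
  labels
}

#' Module labels of a solution as a ground-truth-comparable vector
#'
#' @param solution A `module_solution` (or `modulomics_fit`).
#' @return Integer vector over all samples, `NA` for lonely (named by
#'   sample id).
#' @export
solution_labels <- function(solution) {
  if (inherits(solution, "modulomics_fit")) solution <- solution$solution
  module_assignment(solution)
}
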