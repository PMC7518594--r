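#' Construct a module
#'
#' A module is a set of samples together with the non-empty set of omics it
#' covers; its weight is summed only over covered omics.
#'
#' @param samples Integer vector of global sample indices.
#' @param omics Character vector of covered omic ids.
#' @return A `module` list.
#' @export
module <- function(samples, omics) {
  stopifnot(length(omics) >= 1L)
  structure(list(samples = sort(unique(as.integer(samples))),
                 omics = sort(unique(as.character(omics)))),
            class = "module")
}

#' Construct a solution
#'
#' A solution partitions the samples into pairwise-disjoint modules plus a set
#' of lonely (unassigned) samples.
#'
#' @param modules List of [module()] objects.
#' @param lonely Integer vector of lonely sample indices.
#' @param sample_ids Character vector of all sample ids (global order).
#' @return A `module_solution` list.
#' @export
module_solution <- function(modules, lonely, sample_ids) {
  modules <- unname(modules)
  all_mod <- unlist(lapply(modules, `[[`, "samples"))
  lonely <- sort(as.integer(lonely))
  if (anyDuplicated(all_mod)) {
    stop("modules overlap", call. = FALSE)
  }
  covered <- sort(c(all_mod, lonely))
  if (!identical(covered, seq_along(sample_ids))) {
    stop("modules and lonely samples must partition all samples",
         call. = FALSE)
  }
  structure(list(modules = modules, lonely = lonely,
                 sample_ids = sample_ids),
            class = "module_solution")
}

#' @export
print.module_solution <- function(x, ...) {
  cat("<module_solution> ", length(x$modules), " module(s), ",
      length(x$lonely), " lonely of ", length(x$sample_ids), " samples\n",
      sep = "")
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    cat("  M", i, ": ", length(m$samples), " samples, omics {",
        paste(m$omics, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Sample -> module assignment vector of a solution
#'
#' @param solution A `module_solution`.
#' @return Integer vector over all samples; `NA` marks lonely samples.
#' @export
module_assignment <- function(solution) {
  out <- rep(NA_integer_, length(solution$sample_ids))
  for (i in seq_along(solution$modules)) {
    out[solution$modules[[i]]$samples] <- i
  }
  names(out) <- solution$sample_ids
  out
}

# sum of the requested omic weight matrices
omic_weight_sum <- function(graphs, omics) {
  Reduce(`+`, lapply(graphs[omics], `[[`, "weights"))
}

#' Weight of a module
#'
#' `weight(M) = sum over covered omics l of sum over unordered sample pairs
#' {u, v} in M of w_l(u, v)` (each pair counted once). Pairs involving samples
#' unmeasured in an omic contribute zero there.
#'
#' @param module A [module()].
#' @param graphs Named list of `omic_graph` objects.
#' @return The module's total internal edge weight (0 for < 2 samples).
#' @export
module_weight <- function(module, graphs) {
  s <- module$samples
  if (length(s) < 2L) return(0)
  if (!all(module$omics %in% names(graphs))) {
    stop("unknown omic id(s) in module", call. = FALSE)
  }
  sum(vapply(module$omics,
             function(l) sum(graphs[[l]]$weights[s, s]) / 2,
             numeric(1)))
}

#' Objective value of a solution
#'
#' The summed weight of all modules; lonely samples contribute nothing. This
#' is the quantity the greedy search maximises.
#'
#' @param solution A `module_solution`.
#' @param graphs Named list of `omic_graph` objects.
#' @return Numeric objective value.
#' @export
solution_objective <- function(solution, graphs) {
  all_mod <- unlist(lapply(solution$modules, `[[`, "samples"))
  if (anyDuplicated(all_mod)) stop("modules overlap", call. = FALSE)
  if (length(solution$modules) == 0L) return(0)
  sum(vapply(solution$modules, module_weight, numeric(1), graphs = graphs))
}
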