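#' Search parameters for heavy-module detection
#'
#' Defaults follow the standard settings of the method: `S = 15` seeds,
#' seed neighbourhood `k = floor(n/15)`, minimum module size
#' `eta = max(round(n/30), 10)`, at most 10 samples added or moved per action
#' (`n/50` when `n > 1000`), and 15 restarts.
#'
#' @param n Number of samples (drives the size-dependent defaults).
#' @param S Number of seed modules.
#' @param k Seed neighbourhood size.
#' @param eta Minimum module size; actions that would shrink a module below
#'   `eta` are never executed, and no converged module is smaller.
#' @param batch_cap Maximum samples added/moved in a single action.
#' @param restarts Independent runs of seed finding plus optimisation; the
#'   best-objective run is kept (restart `i` uses `rng_seed + i`).
#' @param max_epochs Safety cap on optimisation epochs.
#' @param rng_seed Integer seed making the whole search reproducible.
#' @return A `search_params` list.
#' @export
search_params <- function(n, S = 15L, k = NULL, eta = NULL, batch_cap = NULL,
                          restarts = 15L, max_epochs = 10000L, rng_seed = 1L) {
  k <- k %||% max(1L, floor(n / 15))
  eta <- eta %||% max(round(n / 30), 10L)
  batch_cap <- batch_cap %||% if (n > 1000L) floor(n / 50) else 10L
  stopifnot(eta >= 2L, S >= 1L, restarts >= 1L)
  structure(list(n = as.integer(n), S = as.integer(S), k = as.integer(k),
                 eta = as.integer(eta), batch_cap = as.integer(batch_cap),
                 restarts = as.integer(restarts),
                 max_epochs = as.integer(max_epochs),
                 rng_seed = as.integer(rng_seed)),
            class = "search_params")
}

GAIN_TOL <- 1e-9

ACTION_KINDS <- c("add_samples", "remove_sample", "move_samples", "add_omic",
                  "remove_omic", "merge", "split", "discard", "new_module",
                  "split_by_adding_omic", "split_with_omic")

#' Create an action record
#'
#' Records one candidate local-search action. Fields beyond `kind` and
#' `module` depend on the kind: `samples` (add_samples, new_module, and the
#' retained part `part` for splits), `sample` (remove_sample), `moves`
#' (move_samples: list of `list(sample, from, to)` applied in order), `omic`
#' (omic actions, splits with/by omic, new_module), `other` and `omics`
#' (merge: the partner module and the chosen covered set), `assignment`
#' (discard: target module index per discarded sample, `NA` = lonely).
#'
#' @param kind One of the supported action kinds.
#' @param module Index of the module the action concerns (`NA` for
#'   new_module).
#' @param ... Kind-specific fields.
#' @return An `action_record` list.
#' @export
action_record <- function(kind, module = NA_integer_, ...) {
  kind <- match.arg(kind, ACTION_KINDS)
  fields <- lapply(list(...), function(x) {
    if (is.atomic(x)) unname(x) else x
  })
  structure(c(list(kind = kind, module = module), fields),
            class = "action_record")
}

# sum of weights from sample u to the samples `s` under omic set `omics`
score_to_set <- function(u, s, omics, graphs) {
  if (length(s) == 0L) return(0)
  sum(vapply(omics, function(l) sum(graphs[[l]]$weights[u, s]), numeric(1)))
}

pair_sum <- function(omics, idx, graphs) {
  if (length(idx) < 2L || length(omics) == 0L) return(0)
  sum(vapply(omics, function(l) sum(graphs[[l]]$weights[idx, idx]) / 2,
             numeric(1)))
}

#' Gain of an action
#'
#' The increase in the global objective from applying `action` to `solution`,
#' computed incrementally from the edge weights (tests verify agreement with a
#' full objective recomputation). Structurally invalid actions — e.g. ones
#' that would shrink a module below `eta` — return `-Inf`.
#'
#' @param action An [action_record()].
#' @param solution A `module_solution`.
#' @param graphs Named list of `omic_graph` objects.
#' @param params A [search_params()].
#' @return Numeric gain (`-Inf` when invalid).
#' @export
action_gain <- function(action, solution, graphs, params) {
  eta <- params$eta
  mods <- solution$modules
  m <- if (!is.na(action$module)) mods[[action$module]] else NULL
  switch(action$kind,
    add_samples = {
      g <- 0
      cur <- m$samples
      for (u in action$samples) {
        g <- g + score_to_set(u, cur, m$omics, graphs)
        cur <- c(cur, u)
      }
      g
    },
    remove_sample = {
      if (length(m$samples) - 1L < eta) return(-Inf)
      -score_to_set(action$sample, m$samples, m$omics, graphs)
    },
    move_samples = {
      sets <- lapply(mods, `[[`, "samples")
      g <- 0
      for (mv in action$moves) {
        if (length(sets[[mv$from]]) - 1L < eta) return(-Inf)
        u <- mv$sample
        g <- g - score_to_set(u, setdiff(sets[[mv$from]], u),
                              mods[[mv$from]]$omics, graphs) +
          score_to_set(u, sets[[mv$to]], mods[[mv$to]]$omics, graphs)
        sets[[mv$from]] <- setdiff(sets[[mv$from]], u)
        sets[[mv$to]] <- c(sets[[mv$to]], u)
      }
      g
    },
    add_omic = pair_sum(action$omic, m$samples, graphs),
    remove_omic = {
      if (length(m$omics) < 2L) return(-Inf)
      -pair_sum(action$omic, m$samples, graphs)
    },
    merge = {
      m2 <- mods[[action$other]]
      su <- c(m$samples, m2$samples)
      pair_sum(action$omics, su, graphs) -
        module_weight(m, graphs) - module_weight(m2, graphs)
    },
    split = {
      u <- action$part
      v <- setdiff(m$samples, u)
      if (length(u) < eta || length(v) < eta) return(-Inf)
      pair_sum(m$omics, u, graphs) + pair_sum(m$omics, v, graphs) -
        pair_sum(m$omics, m$samples, graphs)
    },
    discard = {
      g <- -module_weight(m, graphs)
      sets <- lapply(mods, `[[`, "samples")
      for (i in seq_along(m$samples)) {
        tgt <- action$assignment[i]
        if (!is.na(tgt)) {
          u <- m$samples[i]
          g <- g + score_to_set(u, sets[[tgt]], mods[[tgt]]$omics, graphs)
          sets[[tgt]] <- c(sets[[tgt]], u)
        }
      }
      g
    },
    new_module = {
      if (length(action$samples) < eta) return(-Inf)
      pair_sum(action$omic, action$samples, graphs)
    },
    split_by_adding_omic = {
      u <- action$part
      v <- setdiff(m$samples, u)
      if (length(u) == 0L) return(-Inf)
      if (length(u) < eta || (length(v) > 0L && length(v) < eta)) return(-Inf)
      pair_sum(union(m$omics, action$omic), u, graphs) +
        pair_sum(m$omics, v, graphs) - pair_sum(m$omics, m$samples, graphs)
    },
    split_with_omic = {
      u <- action$part
      v <- setdiff(m$samples, u)
      if (length(u) == 0L) return(-Inf)
      if (length(u) < eta || (length(v) > 0L && length(v) < eta)) return(-Inf)
      pair_sum(action$omic, u, graphs) + pair_sum(m$omics, v, graphs) -
        pair_sum(m$omics, m$samples, graphs)
    },
    stop("unknown action kind: ", action$kind, call. = FALSE)
  )
}

#' Apply an action to a solution
#'
#' @inheritParams action_gain
#' @return The updated `module_solution`.
#' @export
apply_action <- function(solution, action, graphs = NULL, params = NULL) {
  mods <- solution$modules
  lonely <- solution$lonely
  mi <- action$module
  switch(action$kind,
    add_samples = {
      mods[[mi]]$samples <- sort(c(mods[[mi]]$samples, action$samples))
      lonely <- setdiff(lonely, action$samples)
    },
    remove_sample = {
      mods[[mi]]$samples <- setdiff(mods[[mi]]$samples, action$sample)
      lonely <- sort(c(lonely, action$sample))
    },
    move_samples = {
      for (mv in action$moves) {
        mods[[mv$from]]$samples <- setdiff(mods[[mv$from]]$samples, mv$sample)
        mods[[mv$to]]$samples <- sort(c(mods[[mv$to]]$samples, mv$sample))
      }
    },
    add_omic = {
      mods[[mi]]$omics <- sort(union(mods[[mi]]$omics, action$omic))
    },
    remove_omic = {
      mods[[mi]]$omics <- setdiff(mods[[mi]]$omics, action$omic)
    },
    merge = {
      mods[[mi]]$samples <- sort(c(mods[[mi]]$samples,
                                   mods[[action$other]]$samples))
      mods[[mi]]$omics <- sort(action$omics)
      mods[[action$other]] <- NULL
    },
    split = {
      rest <- setdiff(mods[[mi]]$samples, action$part)
      newm <- mods[[mi]]
      newm$samples <- sort(action$part)
      mods[[mi]]$samples <- rest
      mods[[length(mods) + 1L]] <- newm
    },
    discard = {
      s <- mods[[mi]]$samples
      for (i in seq_along(s)) {
        tgt <- action$assignment[i]
        if (is.na(tgt)) {
          lonely <- c(lonely, s[i])
        } else {
          mods[[tgt]]$samples <- sort(c(mods[[tgt]]$samples, s[i]))
        }
      }
      lonely <- sort(lonely)
      mods[[mi]] <- NULL
    },
    new_module = {
      mods[[length(mods) + 1L]] <- module(action$samples, action$omic)
      lonely <- setdiff(lonely, action$samples)
    },
    split_by_adding_omic = {
      rest <- setdiff(mods[[mi]]$samples, action$part)
      newm <- module(action$part, union(mods[[mi]]$omics, action$omic))
      if (length(rest) == 0L) {
        mods[[mi]] <- newm
      } else {
        mods[[mi]]$samples <- rest
        mods[[length(mods) + 1L]] <- newm
      }
    },
    split_with_omic = {
      rest <- setdiff(mods[[mi]]$samples, action$part)
      newm <- module(action$part, action$omic)
      if (length(rest) == 0L) {
        mods[[mi]] <- newm
      } else {
        mods[[mi]]$samples <- rest
        mods[[length(mods) + 1L]] <- newm
      }
    },
    stop("unknown action kind: ", action$kind, call. = FALSE)
  )
  module_solution(mods, lonely, solution$sample_ids)
}

#' Find seed modules
#'
#' Builds the omic-summed graph, then repeatedly picks a random remaining
#' sample and forms a module (covering all omics) from it and its up-to-`k`
#' remaining neighbours with the highest strictly positive summed weight;
#' chosen samples are removed before the next seed is sought. Samples left
#' after `S` seeds are lonely. A sample with no positive neighbours forms a
#' singleton seed.
#'
#' @param graphs Named list of `omic_graph` objects.
#' @param params A [search_params()].
#' @return A `module_solution` of seed modules.
#' @export
find_seeds <- function(graphs, params) {
  w_sum <- omic_weight_sum(graphs, names(graphs))
  n <- nrow(w_sum)
  if (n < params$S) {
    warning("fewer samples (", n, ") than seeds (", params$S, ")",
            call. = FALSE)
  }
  withr::with_seed(params$rng_seed, {
    remaining <- seq_len(n)
    mods <- list()
    for (i in seq_len(params$S)) {
      if (length(remaining) == 0L) break
      anchor <- remaining[sample.int(length(remaining), 1L)]
      cand <- setdiff(remaining, anchor)
      wts <- w_sum[anchor, cand]
      pos <- wts > 0
      chosen <- integer(0)
      if (any(pos)) {
        cand <- cand[pos]
        wts <- wts[pos]
        ord <- order(-wts, cand)
        chosen <- cand[ord[seq_len(min(params$k, length(cand)))]]
      }
      mods[[length(mods) + 1L]] <- module(c(anchor, chosen), names(graphs))
      remaining <- setdiff(remaining, c(anchor, chosen))
    }
    module_solution(mods, remaining, rownames(w_sum))
  })
}

# ---- candidate generation -------------------------------------------------

# best candidate of each kind for module `mi`; returns list of action records
# with gains, or NULL when no candidate exists. Ties inside a kind resolve to
# the lowest sample/omic/module index by scan order.
propose_actions <- function(solution, mi, graphs, params) {
  mods <- solution$modules
  m <- mods[[mi]]
  s <- m$samples
  o <- m$omics
  eta <- params$eta
  cap <- params$batch_cap
  wm <- omic_weight_sum(graphs, o)
  out <- list()

  # add_samples: greedy batch over lonely samples
  lon <- solution$lonely
  if (length(lon) > 0L) {
    g <- rowSums(wm[lon, s, drop = FALSE])
    chosen <- integer(0)
    total <- 0
    repeat {
      if (length(chosen) >= cap || length(lon) == 0L) break
      i <- which.max(g)
      if (g[i] <= GAIN_TOL) break
      total <- total + g[i]
      u <- lon[i]
      chosen <- c(chosen, u)
      lon <- lon[-i]
      g <- g[-i]
      if (length(lon) > 0L) g <- g + wm[lon, u]
    }
    if (length(chosen) > 0L) {
      out$add_samples <- action_record("add_samples", mi, samples = chosen,
                                       gain = total)
    }
  }

  # remove_sample
  if (length(s) - 1L >= eta) {
    r <- rowSums(wm[s, s, drop = FALSE])
    i <- which.min(r)
    if (-r[i] > GAIN_TOL) {
      out$remove_sample <- action_record("remove_sample", mi, sample = s[i],
                                         gain = -r[i])
    }
  }

  # move_samples: greedy batch of single-sample switches touching module mi
  others <- setdiff(seq_along(mods), mi)
  if (length(others) > 0L) {
    sets <- lapply(mods, `[[`, "samples")
    wms <- lapply(mods, function(mm) omic_weight_sum(graphs, mm$omics))
    moves <- list()
    total <- 0
    repeat {
      if (length(moves) >= cap) break
      best <- NULL
      best_g <- GAIN_TOL
      for (m2 in others) {
        s1 <- sets[[mi]]
        s2 <- sets[[m2]]
        if (length(s1) - 1L >= eta && length(s1) > 0L) {
          g_out <- rowSums(wms[[m2]][s1, s2, drop = FALSE]) -
            rowSums(wms[[mi]][s1, s1, drop = FALSE])
          i <- which.max(g_out)
          if (g_out[i] > best_g) {
            best_g <- g_out[i]
            best <- list(sample = s1[i], from = mi, to = m2)
          }
        }
        if (length(s2) - 1L >= eta && length(s2) > 0L) {
          g_in <- rowSums(wms[[mi]][s2, s1, drop = FALSE]) -
            rowSums(wms[[m2]][s2, s2, drop = FALSE])
          i <- which.max(g_in)
          if (g_in[i] > best_g) {
            best_g <- g_in[i]
            best <- list(sample = s2[i], from = m2, to = mi)
          }
        }
      }
      if (is.null(best)) break
      moves[[length(moves) + 1L]] <- best
      total <- total + best_g
      sets[[best$from]] <- setdiff(sets[[best$from]], best$sample)
      sets[[best$to]] <- sort(c(sets[[best$to]], best$sample))
    }
    if (length(moves) > 0L) {
      out$move_samples <- action_record("move_samples", mi, moves = moves,
                                        gain = total)
    }
  }

  # add_omic / remove_omic
  spare <- setdiff(names(graphs), o)
  if (length(spare) > 0L) {
    gains <- vapply(spare, pair_sum, numeric(1), idx = s, graphs = graphs)
    i <- which.max(gains)
    if (gains[i] > GAIN_TOL) {
      out$add_omic <- action_record("add_omic", mi, omic = spare[i],
                                    gain = gains[i])
    }
  }
  if (length(o) >= 2L) {
    gains <- -vapply(o, pair_sum, numeric(1), idx = s, graphs = graphs)
    i <- which.max(gains)
    if (gains[i] > GAIN_TOL) {
      out$remove_omic <- action_record("remove_omic", mi, omic = o[i],
                                       gain = gains[i])
    }
  }

  # merge: all partners x four omic-set options
  if (length(others) > 0L) {
    w_m <- pair_sum(o, s, graphs)
    best <- NULL
    for (m2 in others) {
      o2 <- mods[[m2]]$omics
      su <- c(s, mods[[m2]]$samples)
      a <- vapply(names(graphs), pair_sum, numeric(1), idx = su,
                  graphs = graphs)
      w_m2 <- pair_sum(o2, mods[[m2]]$samples, graphs)
      opts <- unique(lapply(list(union(o, o2), intersect(o, o2), o, o2),
                            sort))
      opts <- opts[lengths(opts) > 0L]
      for (oo in opts) {
        gain <- sum(a[oo]) - w_m - w_m2
        if (is.null(best) || gain > best$gain + GAIN_TOL) {
          best <- list(other = m2, omics = oo, gain = gain)
        }
      }
    }
    if (!is.null(best) && best$gain > GAIN_TOL) {
      out$merge <- action_record("merge", mi, other = best$other,
                                 omics = best$omics, gain = best$gain)
    }
  }

  # split (same omics on both parts)
  if (length(s) >= 2L * eta) {
    u_rel <- heavy_subgraph(wm[s, s, drop = FALSE])
    u <- s[u_rel]
    v <- setdiff(s, u)
    if (length(u) >= eta && length(v) >= eta) {
      gain <- pair_sum(o, u, graphs) + pair_sum(o, v, graphs) -
        pair_sum(o, s, graphs)
      if (gain > GAIN_TOL) {
        out$split <- action_record("split", mi, part = u, gain = gain)
      }
    }
  }

  # discard: each sample goes to its best-scoring module, or lonely when all
  # scores are negative (a zero score still assigns)
  {
    sets <- lapply(mods, `[[`, "samples")
    assignment <- rep(NA_integer_, length(s))
    gain <- -pair_sum(o, s, graphs)
    for (i in seq_along(s)) {
      u <- s[i]
      if (length(others) > 0L) {
        scs <- vapply(others, function(m2) {
          score_to_set(u, sets[[m2]], mods[[m2]]$omics, graphs)
        }, numeric(1))
        j <- which.max(scs)
        if (scs[j] >= 0) {
          assignment[i] <- others[j]
          gain <- gain + scs[j]
          sets[[others[j]]] <- c(sets[[others[j]]], u)
        }
      }
    }
    if (gain > GAIN_TOL) {
      out$discard <- action_record("discard", mi, assignment = assignment,
                                   gain = gain)
    }
  }

  # new_module from lonely samples (one omic)
  lon0 <- solution$lonely
  if (length(lon0) >= eta) {
    best <- NULL
    for (l in names(graphs)) {
      u_rel <- heavy_subgraph(graphs[[l]]$weights[lon0, lon0, drop = FALSE])
      wt <- attr(u_rel, "weight")
      if (length(u_rel) >= eta && wt > GAIN_TOL &&
          (is.null(best) || wt > best$gain + GAIN_TOL)) {
        best <- list(samples = lon0[u_rel], omic = l, gain = wt)
      }
    }
    if (!is.null(best)) {
      out$new_module <- action_record("new_module", mi,
                                      samples = best$samples,
                                      omic = best$omic, gain = best$gain)
    }
  }

  # split_by_adding_omic (new part gains omic l not yet covered)
  if (length(spare) > 0L && length(s) >= eta) {
    best <- NULL
    w_m <- pair_sum(o, s, graphs)
    for (l in spare) {
      u_rel <- heavy_subgraph(graphs[[l]]$weights[s, s, drop = FALSE])
      if (length(u_rel) == 0L) next
      u <- s[u_rel]
      v <- setdiff(s, u)
      if (length(u) < eta || (length(v) > 0L && length(v) < eta)) next
      gain <- pair_sum(union(o, l), u, graphs) + pair_sum(o, v, graphs) - w_m
      if (is.null(best) || gain > best$gain + GAIN_TOL) {
        best <- list(part = u, omic = l, gain = gain)
      }
    }
    if (!is.null(best) && best$gain > GAIN_TOL) {
      out$split_by_adding_omic <- action_record(
        "split_by_adding_omic", mi, part = best$part, omic = best$omic,
        gain = best$gain)
    }
  }

  # split_with_omic (split part keeps only omic l, already covered)
  if (length(s) >= eta) {
    best <- NULL
    w_m <- pair_sum(o, s, graphs)
    for (l in o) {
      u_rel <- heavy_subgraph(graphs[[l]]$weights[s, s, drop = FALSE])
      if (length(u_rel) == 0L) next
      u <- s[u_rel]
      v <- setdiff(s, u)
      if (length(u) < eta || (length(v) > 0L && length(v) < eta)) next
      gain <- pair_sum(l, u, graphs) + pair_sum(o, v, graphs) - w_m
      if (is.null(best) || gain > best$gain + GAIN_TOL) {
        best <- list(part = u, omic = l, gain = gain)
      }
    }
    if (!is.null(best) && best$gain > GAIN_TOL) {
      out$split_with_omic <- action_record(
        "split_with_omic", mi, part = best$part, omic = best$omic,
        gain = best$gain)
    }
  }

  out
}

# best action for module mi (fixed kind order breaks gain ties)
best_action <- function(solution, mi, graphs, params) {
  cands <- propose_actions(solution, mi, graphs, params)
  if (length(cands) == 0L) return(NULL)
  gains <- vapply(cands, `[[`, numeric(1), "gain")
  ord <- match(ACTION_KINDS, names(cands))
  ord <- ord[!is.na(ord)]
  best <- ord[which.max(gains[ord])]
  cands[[best]]
}

#' Greedy local-search optimisation of a solution
#'
#' Repeats epochs over a random permutation of the current modules; for each
#' visited module all applicable actions are evaluated and the single best
#' strictly-positive-gain action is applied, so the objective strictly
#' increases at every step. Converges when a full epoch applies no action.
#' Any module still below the minimum size at convergence (a seed that never
#' grew) is dissolved as a final cleanup, its samples reassigned by the
#' discard rule; this cleanup is not gain-driven, so it is excluded from the
#' objective trace.
#'
#' @param start A `module_solution` (typically from [find_seeds()]).
#' @param graphs Named list of `omic_graph` objects.
#' @param params A [search_params()].
#' @return The converged `module_solution`, with attributes
#'   `objective_trace` (objective after every applied action),
#'   `action_counts` (applied actions by kind), `epochs` and
#'   `forced_discards` (undersized seed modules dissolved at the end).
#' @export
optimize_solution <- function(start, graphs, params) {
  sol <- start
  trace <- numeric(0)
  counts <- stats::setNames(integer(length(ACTION_KINDS)), ACTION_KINDS)
  epoch <- 0L
  forced <- 0L
  withr::with_seed(params$rng_seed + 1000003L, {
    {
      converged <- FALSE
      while (epoch < params$max_epochs) {
        epoch <- epoch + 1L
        applied <- FALSE
        nm <- length(sol$modules)
        order_ids <- if (nm > 0L) sample.int(nm) else integer(0)
        for (mi in order_ids) {
          # module list indices shift when structural actions fire; re-scan
          if (mi > length(sol$modules)) next
          act <- best_action(sol, mi, graphs, params)
          if (!is.null(act) && act$gain > GAIN_TOL) {
            sol <- apply_action(sol, act)
            counts[act$kind] <- counts[act$kind] + 1L
            trace <- c(trace, solution_objective(sol, graphs))
            applied <- TRUE
            if (act$kind %in% c("merge", "split", "discard", "new_module",
                                "split_by_adding_omic", "split_with_omic")) {
              break  # structure changed: restart the permutation
            }
          }
        }
        if (nm == 0L) {
          # no modules left: lonely samples can still found a new module
          act <- propose_new_module_only(sol, graphs, params)
          if (!is.null(act)) {
            sol <- apply_action(sol, act)
            counts[act$kind] <- counts[act$kind] + 1L
            trace <- c(trace, solution_objective(sol, graphs))
            applied <- TRUE
          }
        }
        if (!applied) {
          converged <- TRUE
          break
        }
      }
      if (!converged) {
        warning("optimisation hit max_epochs (", params$max_epochs,
                ") before converging", call. = FALSE)
      }
      # final cleanup: seeds that never reached the minimum size are
      # dissolved by the discard rule. This is not a gain-driven action
      # (its gain may be negative), so it stays out of the objective trace.
      repeat {
        small <- which(vapply(sol$modules, function(m) length(m$samples),
                              integer(1)) < params$eta)
        if (length(small) == 0L) break
        sol <- force_discard(sol, small[1L], graphs)
        forced <- forced + 1L
      }
    }
  })
  attr(sol, "objective_trace") <- trace
  attr(sol, "action_counts") <- counts
  attr(sol, "epochs") <- epoch
  attr(sol, "forced_discards") <- forced
  sol
}

propose_new_module_only <- function(solution, graphs, params) {
  lon0 <- solution$lonely
  if (length(lon0) < params$eta) return(NULL)
  best <- NULL
  for (l in names(graphs)) {
    u_rel <- heavy_subgraph(graphs[[l]]$weights[lon0, lon0, drop = FALSE])
    wt <- attr(u_rel, "weight")
    if (length(u_rel) >= params$eta && wt > GAIN_TOL &&
        (is.null(best) || wt > best$gain + GAIN_TOL)) {
      best <- list(samples = lon0[u_rel], omic = l, gain = wt)
    }
  }
  if (is.null(best)) return(NULL)
  action_record("new_module", NA_integer_, samples = best$samples,
                omic = best$omic, gain = best$gain)
}

# discard module mi unconditionally (used for sub-eta seeds at convergence)
force_discard <- function(solution, mi, graphs) {
  mods <- solution$modules
  m <- mods[[mi]]
  others <- setdiff(seq_along(mods), mi)
  sets <- lapply(mods, `[[`, "samples")
  assignment <- rep(NA_integer_, length(m$samples))
  for (i in seq_along(m$samples)) {
    u <- m$samples[i]
    if (length(others) == 0L) next
    scs <- vapply(others, function(m2) {
      score_to_set(u, sets[[m2]], mods[[m2]]$omics, graphs)
    }, numeric(1))
    j <- which.max(scs)
    if (scs[j] >= 0) {
      assignment[i] <- others[j]
      sets[[others[j]]] <- c(sets[[others[j]]], u)
    }
  }
  apply_action(solution, action_record("discard", mi,
                                       assignment = assignment))
}

#' Detect multi-omic sample modules
#'
#' End-to-end module discovery: builds one signed sample graph per omic,
#' runs seed finding plus greedy optimisation with restarts (restart `i` uses
#' `rng_seed + i`), keeps the best-objective solution, and applies the
#' empirical significance filter. The whole run is deterministic given the
#' configuration seeds.
#'
#' @param omics List of [omic_matrix()] objects (or the list returned by
#'   [load_omics()] / [simulate_omics()]).
#' @param registry Optional [sample_registry()]; derived from `omics` when
#'   `NULL`.
#' @param weighting A [weighting_config()].
#' @param search A [search_params()]; sized to the data when `NULL`.
#' @param significance A [null_test_config()], or `NULL` to skip filtering.
#' @return A `modulomics_fit` object; see [tidy.modulomics_fit()],
#'   [glance.modulomics_fit()] and [autoplot.modulomics_fit()].
#' @export
detect_modules <- function(omics, registry = NULL,
                           weighting = weighting_config(),
                           search = NULL,
                           significance = null_test_config()) {
  if (is.list(omics) && !is.null(omics$omics)) {
    registry <- registry %||% omics$registry
    omics <- omics$omics
  }
  registry <- registry %||% sample_registry(omics)
  n <- length(registry$sample_ids)
  search <- search %||% search_params(n, rng_seed = weighting$rng_seed)
  graphs <- build_graphs(omics, registry, weighting)
  best <- NULL
  best_obj <- -Inf
  restart_objs <- numeric(search$restarts)
  for (i in seq_len(search$restarts)) {
    p_i <- search
    p_i$rng_seed <- search$rng_seed + i
    sol <- optimize_solution(find_seeds(graphs, p_i), graphs, p_i)
    obj <- solution_objective(sol, graphs)
    restart_objs[i] <- obj
    if (obj > best_obj) {
      best <- sol
      best_obj <- obj
    }
  }
  filter_report <- NULL
  filtered <- best
  if (!is.null(significance)) {
    significance$eta <- significance$eta %||% search$eta
    filtered <- filter_modules(best, graphs, significance)
    filter_report <- attr(filtered, "filter_report")
  }
  diagnostics <- list(
    restart_objectives = tibble::tibble(restart = seq_len(search$restarts),
                                        objective = restart_objs),
    objective_trace = attr(best, "objective_trace"),
    action_counts = attr(best, "action_counts"),
    epochs = attr(best, "epochs"),
    forced_discards = attr(best, "forced_discards"),
    filter_report = filter_report
  )
  structure(
    list(solution = strip_attrs(filtered), unfiltered = strip_attrs(best),
         graphs = graphs, registry = registry, weighting = weighting,
         search = search, significance = significance,
         objective = solution_objective(filtered, graphs),
         diagnostics = diagnostics),
    class = "modulomics_fit"
  )
}

strip_attrs <- function(sol) {
  attr(sol, "objective_trace") <- NULL
  attr(sol, "action_counts") <- NULL
  attr(sol, "epochs") <- NULL
  attr(sol, "forced_discards") <- NULL
  attr(sol, "filter_report") <- NULL
  sol
}

#' @export
print.modulomics_fit <- function(x, ...) {
  cat("<modulomics_fit> objective ", round(x$objective, 3), " over ",
      x$search$restarts, " restart(s)\n", sep = "")
  print(x$solution)
  invisible(x)
}
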