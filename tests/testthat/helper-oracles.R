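# Independent oracles used to validate the implementation. These are written
# against the definitions, not against the code paths they check.

# exact heaviest-subgraph weight by exhaustive subset enumeration (n <= 20);
# subset weights computed in one matrix product over the 2^n indicator rows
brute_force_heaviest <- function(w) {
  n <- nrow(w)
  stopifnot(n <= 20L)
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wts <- rowSums((m %*% w) * m) / 2
  best <- max(wts)
  list(weight = max(best, 0),
       sizes = rowSums(m)[abs(wts - best) < 1e-12])
}

# ARI by direct pair counting (agreements over all unordered sample pairs)
brute_force_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ta <- a[i] == a[j]
      tb <- b[i] == b[j]
      if (ta && tb) s11 <- s11 + 1
      else if (!ta && !tb) s00 <- s00 + 1
      else if (ta) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 1 else num / den
}

# all set partitions of seq_len(n) as label vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return()
    }
    for (g in seq_len(k + 1L)) rec(c(labels, g), max(k, g))
  }
  rec(integer(0), 0L)
  out
}

# naive re-implementation of the consensus weighting formula from an explicit
# run history (list of (sampled index set, label vector))
naive_consensus <- function(runs, m, C, shift = 0) {
  w <- matrix(0, m, m)
  for (u in seq_len(m - 1L)) {
    for (v in (u + 1L):m) {
      vals <- c()
      for (r in runs) {
        iu <- match(u, r$sub)
        iv <- match(v, r$sub)
        if (is.na(iu) || is.na(iv)) next
        cl <- outer(r$labels, r$labels, `==`) * 1
        ns <- length(r$labels)
        avg <- (sum(cl) - ns) / (ns * (ns - 1))
        vals <- c(vals, cl[iu, iv] - avg)
      }
      if (length(vals) > 0) w[u, v] <- w[v, u] <- mean(vals) - C + shift
    }
  }
  w
}

# random symmetric signed weight matrix with zero diagonal
random_signed_graph <- function(n, sd = 1, shift = 0) {
  w <- matrix(stats::rnorm(n * n, shift, sd), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# wrap plain weight matrices as omic graphs over synthetic sample ids
graphs_from_matrices <- function(mats) {
  n <- nrow(mats[[1L]])
  ids <- sprintf("s%03d", seq_len(n))
  out <- purrr::imap(mats, function(w, nm) {
    dimnames(w) <- list(ids, ids)
    structure(list(omic_id = nm, weights = w,
                   measured = rep(TRUE, n), model = NULL),
              class = "omic_graph")
  })
  names(out) <- names(mats)
  out
}

# random valid solution over n samples: n_mod disjoint modules of size >= 2
random_solution <- function(n, n_mod, omic_ids, min_size = 3L) {
  idx <- sample.int(n)
  sizes <- min_size + stats::rpois(n_mod, 2)
  while (sum(sizes) > n - 1L) sizes <- pmax(min_size, sizes - 1L)
  mods <- list()
  at <- 1L
  for (i in seq_len(n_mod)) {
    mods[[i]] <- module(idx[at:(at + sizes[i] - 1L)],
                        sample(omic_ids, sample(length(omic_ids), 1L)))
    at <- at + sizes[i]
  }
  module_solution(mods, idx[at:n], sprintf("s%03d", seq_len(n)))
}
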