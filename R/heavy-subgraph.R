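#' Heavy subgraph by min-degree peeling
#'
#' Greedy heuristic for the heaviest-subgraph problem on a signed,
#' edge-weighted graph (a relative of Charikar's densest-subgraph
#' 2-approximation): repeatedly remove the node with the smallest weighted
#' degree (ties broken towards the lowest index), and return the heaviest of
#' the nested subgraphs visited along the way — including the full node set
#' and the empty set, so an all-negative graph yields the empty set. Weight
#' ties are broken towards the larger node set.
#'
#' @param w Symmetric numeric matrix with zero diagonal (edge weights over the
#'   node subset of interest).
#' @return Integer vector of retained node indices (possibly empty), with the
#'   subgraph's total edge weight in attribute `"weight"`.
#' @export
heavy_subgraph <- function(w) {
  n <- nrow(w)
  stopifnot(n >= 1L, ncol(w) == n)
  if (n == 1L) {
    res <- integer(0)
    attr(res, "weight") <- 0
    return(res)
  }
  deg <- rowSums(w)
  alive <- rep(TRUE, n)
  removal <- integer(n)
  weights_seq <- numeric(n + 1L)       # weights_seq[i]: after i - 1 removals
  weights_seq[1L] <- sum(w) / 2
  total <- weights_seq[1L]
  for (i in seq_len(n)) {
    d <- deg
    d[!alive] <- Inf
    v <- which.min(d)                  # first minimum = lowest index
    total <- total - deg[v]
    weights_seq[i + 1L] <- total
    alive[v] <- FALSE
    removal[i] <- v
    deg <- deg - w[, v]
  }
  weights_seq[n + 1L] <- 0             # empty set, exact
  best <- which.max(weights_seq)       # first max = largest surviving set
  if (weights_seq[best] <= 0) {
    res <- integer(0)
    attr(res, "weight") <- 0
    return(res)
  }
  res <- sort(setdiff(seq_len(n), removal[seq_len(best - 1L)]))
  attr(res, "weight") <- weights_seq[best]
  res
}
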