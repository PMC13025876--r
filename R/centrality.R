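# Node centralities: degree, Brandes betweenness, per-component closeness.
# All shortest paths are unweighted, matching CytoNCA's defaults; BC is
# unnormalised (each unordered pair counted once) while CC is normalised
# within its connected component — the mixed convention under which the
# published screening thresholds (BC on the hundreds scale, CC in [0, 1])
# are mutually consistent.

#' Degree centrality
#'
#' @param net A [ppi_network()].
#' @return Named numeric vector: number of incident edges per node.
#' @export
degree_centrality <- function(net) {
  deg <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.numeric(tab)
  }
  deg
}

#' Betweenness centrality (Brandes)
#'
#' Unnormalised betweenness on unweighted undirected graphs:
#' `BC(v) = sum over pairs s < t (both != v) of sigma_st(v) / sigma_st`,
#' where `sigma_st` counts shortest s-t paths. Computed with Brandes'
#' dependency accumulation, one BFS per source; endpoints are excluded.
#'
#' @param net A [ppi_network()].
#' @return Named numeric vector of betweenness scores (>= 0).
#' @export
betweenness_centrality <- function(net) {
  adj <- net_adjacency(net)
  n <- length(adj)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L
    sigma[s] <- 1
    order <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order <- c(order, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- nxt
    }
    delta <- numeric(n)
    for (w in rev(order)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  stats::setNames(bc / 2, net$nodes)
}

#' Closeness centrality (per component)
#'
#' `CC(v) = (n_c - 1) / sum_u d(v, u)` with the sum and size `n_c` taken
#' over `v`'s connected component, so values lie in (0, 1] for nodes with
#' at least one neighbour. Isolated nodes score 0.
#'
#' @param net A [ppi_network()].
#' @return Named numeric vector of closeness scores in `[0, 1]`.
#' @export
closeness_centrality <- function(net) {
  adj <- net_adjacency(net)
  n <- length(adj)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    dist[s] <- 0L
    frontier <- s
    d <- 0L
    while (length(frontier)) {
      d <- d + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[dist[nxt] < 0L]
      dist[nxt] <- d
      frontier <- nxt
    }
    reach <- which(dist > 0L)
    cc[s] <- if (length(reach)) length(reach) / sum(dist[reach]) else 0
  }
  stats::setNames(cc, net$nodes)
}

#' Centrality table
#'
#' Convenience wrapper computing all three screening metrics.
#'
#' @param net A [ppi_network()].
#' @return Data frame with columns `node`, `DC`, `BC`, `CC`, one row per
#'   node in `net$nodes` order.
#' @export
centrality_table <- function(net) {
  data.frame(node = net$nodes,
             DC = unname(degree_centrality(net)),
             BC = unname(betweenness_centrality(net)),
             CC = unname(closeness_centrality(net)),
             stringsAsFactors = FALSE)
}
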