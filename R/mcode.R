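# MCODE-style dense-module detection: vertex weighting by the
# core-clustering coefficient (highest k-core of the closed neighbourhood
# times that core's density), greedy complex prediction from high-weight
# seeds, and 2-core haircut post-processing.

# k-core numbers of an adjacency-list graph via iterative pruning
core_numbers <- function(adj) {
  n <- length(adj)
  deg <- vapply(adj, length, integer(1))
  core <- integer(n)
  alive <- rep.int(TRUE, n)
  k <- 0L
  remaining <- n
  while (remaining > 0L) {
    repeat {
      drop <- which(alive & deg <= k)
      if (!length(drop)) break
      core[drop] <- k
      alive[drop] <- FALSE
      remaining <- remaining - length(drop)
      for (v in drop) {
        nb <- adj[[v]]
        nb <- nb[alive[nb]]
        deg[nb] <- deg[nb] - 1L
      }
    }
    k <- k + 1L
  }
  core
}

# density without self-loops: 2E / (V (V - 1)); 0 for V < 2
graph_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2L) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' MCODE vertex weights
#'
#' Weights each node by the core-clustering coefficient of its closed
#' neighbourhood: find the highest k-core of the subgraph induced by the
#' node and its neighbours, and multiply that `k` by the density of the
#' k-core subgraph. Nodes with fewer than `degree_cutoff` neighbours (and
#' isolated nodes) weigh 0.
#'
#' @param net A [ppi_network()].
#' @param degree_cutoff Minimum degree for a node to receive a non-zero
#'   weight (default 2, the Cytoscape plugin default).
#' @return Named numeric vector of weights (>= 0).
#' @export
mcode_vertex_weights <- function(net, degree_cutoff = 2L) {
  adj <- net_adjacency(net)
  n <- length(adj)
  w <- numeric(n)
  for (v in seq_len(n)) {
    if (length(adj[[v]]) < degree_cutoff) next
    nb <- c(v, adj[[v]])
    # local adjacency restricted to the closed neighbourhood
    local <- lapply(nb, function(u) match(intersect(adj[[u]], nb), nb))
    core <- core_numbers(local)
    k_max <- max(core)
    if (k_max == 0L) next
    members <- which(core >= k_max)
    n_edges <- sum(vapply(members, function(i)
      sum(local[[i]] %in% members), numeric(1))) / 2
    w[v] <- k_max * graph_density(length(members), n_edges)
  }
  stats::setNames(w, net$nodes)
}

#' MCODE complex prediction
#'
#' Greedy outward expansion from the highest-weight unvisited seed:
#' starting from the seed, neighbours whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)` are admitted (each node joins
#' at most one complex). With `haircut`, the complex is trimmed to its
#' 2-core, iteratively removing members with fewer than two in-complex
#' neighbours; with `fluff`, unassigned neighbours whose closed
#' neighbourhood is denser than `fluff_density` are appended after the
#' haircut. Complexes are scored `density x node count` and returned in
#' descending score order. Equal-weight seed ties break lexicographically
#' by symbol.
#'
#' @param net A [ppi_network()].
#' @param node_score_cutoff Admission slack as a fraction of the seed
#'   weight (default 0.2).
#' @param degree_cutoff Passed to [mcode_vertex_weights()] (default 2).
#' @param haircut Trim each complex to its 2-core (default `TRUE`).
#' @param fluff Append dense unassigned neighbours (default `FALSE`).
#' @param fluff_density Density threshold for fluffing (default 0.1).
#' @return List of `mcode_cluster` objects, each with `members`
#'   ([gene_set()]), `seed`, `node_count`, `edge_count`, `density`,
#'   `score` and `rank`.
#' @export
mcode_find_complexes <- function(net, node_score_cutoff = 0.2,
                                 degree_cutoff = 2L, haircut = TRUE,
                                 fluff = FALSE, fluff_density = 0.1) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff < 1)
  adj <- net_adjacency(net)
  n <- length(adj)
  w <- unname(mcode_vertex_weights(net, degree_cutoff = degree_cutoff))
  seed_order <- order(-w, net$nodes, method = "radix")
  assigned <- rep.int(FALSE, n)
  clusters <- list()
  for (seed in seed_order) {
    if (assigned[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      cand <- unique(unlist(adj[frontier], use.names = FALSE))
      cand <- cand[!assigned[cand] & w[cand] >= threshold]
      assigned[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    if (haircut) members <- two_core(members, adj)
    if (fluff && length(members)) {
      extra <- unique(unlist(adj[members], use.names = FALSE))
      extra <- extra[!assigned[extra] & !(extra %in% members)]
      keep <- vapply(extra, function(v) {
        nb <- c(v, adj[[v]])
        ne <- sum(vapply(nb, function(u)
          sum(adj[[u]] %in% nb), numeric(1))) / 2
        graph_density(length(nb), ne) > fluff_density
      }, logical(1))
      members <- c(members, extra[keep])
    }
    if (length(members) < 3L) next
    ne <- sum(vapply(members, function(u)
      sum(adj[[u]] %in% members), numeric(1))) / 2
    dens <- graph_density(length(members), ne)
    clusters[[length(clusters) + 1L]] <- list(
      members = gene_set(net$nodes[members], label = "mcode cluster"),
      seed = net$nodes[seed], node_count = length(members),
      edge_count = as.integer(ne), density = dens,
      score = dens * length(members))
  }
  if (!length(clusters)) return(list())
  ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
               -vapply(clusters, `[[`, numeric(1), "node_count"),
               vapply(clusters, `[[`, character(1), "seed"),
               method = "radix")
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$rank <- i
    class(clusters[[i]]) <- "mcode_cluster"
  }
  clusters
}

# iteratively remove members with < 2 neighbours inside the member set
two_core <- function(members, adj) {
  repeat {
    if (!length(members)) return(members)
    deg <- vapply(members, function(u) sum(adj[[u]] %in% members),
                  numeric(1))
    if (all(deg >= 2)) return(members)
    members <- members[deg >= 2]
  }
}

#' @export
print.mcode_cluster <- function(x, ...) {
  cat(sprintf(
    "<mcode_cluster> rank %d: %d nodes, %d edges, score %.3f (seed %s)\n",
    x$rank, x$node_count, x$edge_count, x$score, x$seed))
  invisible(x)
}

#' Summarise MCODE clusters as a data frame
#'
#' @param clusters Result of [mcode_find_complexes()].
#' @return Data frame with one row per cluster.
#' @export
mcode_summary <- function(clusters) {
  if (!length(clusters))
    return(data.frame(rank = integer(), seed = character(),
                      nodes = integer(), edges = integer(),
                      score = numeric(), members = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    rank = vapply(clusters, `[[`, integer(1), "rank"),
    seed = vapply(clusters, `[[`, character(1), "seed"),
    nodes = vapply(clusters, `[[`, integer(1), "node_count"),
    edges = vapply(clusters, `[[`, integer(1), "edge_count"),
    score = vapply(clusters, `[[`, numeric(1), "score"),
    members = vapply(clusters, function(cl)
      paste(cl$members$symbols, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
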