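# Graph construction helpers used across tests.

node_names <- function(n) sprintf("N%02d", seq_len(n))

# Erdos-Renyi G(n, p) as a ppi_network; isolated nodes retained
er_net <- function(n, p, seed) {
  nm <- node_names(n)
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2L))
    keep <- stats::runif(nrow(pairs)) < p
    edges <- pairs[keep, , drop = FALSE]
  })
  ppi_network(data.frame(from = nm[edges[, 1L]], to = nm[edges[, 2L]],
                         stringsAsFactors = FALSE), nodes = nm)
}

# the graph on n nodes whose edge set is encoded by `bits` over the
# C(n, 2) vertex pairs in utils::combn order (for exhaustive enumeration)
graph_from_bits <- function(n, bits) {
  nm <- node_names(n)
  pairs <- t(utils::combn(n, 2L))
  keep <- bitwAnd(bits, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) != 0L
  ppi_network(data.frame(from = nm[pairs[keep, 1L]],
                         to = nm[pairs[keep, 2L]],
                         stringsAsFactors = FALSE), nodes = nm)
}

complete_net <- function(n, prefix = "K") {
  nm <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- t(utils::combn(nm, 2L))
  ppi_network(data.frame(from = pairs[, 1L], to = pairs[, 2L],
                         stringsAsFactors = FALSE))
}

path_net <- function(nodes) {
  ppi_network(data.frame(from = nodes[-length(nodes)], to = nodes[-1L],
                         stringsAsFactors = FALSE))
}

cycle_net <- function(n) {
  nm <- node_names(n)
  ppi_network(data.frame(from = nm, to = nm[c(2:n, 1L)],
                         stringsAsFactors = FALSE))
}

star_net <- function(leaves = 4L) {
  ppi_network(data.frame(from = "HUB", to = sprintf("LEAF%d", seq_len(leaves)),
                         stringsAsFactors = FALSE))
}

net_adj_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    A[cbind(net$edges$from, net$edges$to)] <- TRUE
    A[cbind(net$edges$to, net$edges$from)] <- TRUE
  }
  A
}

net_to_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

# relabel nodes with a random permutation of fresh names
relabel_net <- function(net, seed) {
  new <- withr::with_seed(seed,
    sample(sprintf("Z%03d", seq_along(net$nodes))))
  map <- stats::setNames(new, net$nodes)
  list(net = ppi_network(data.frame(from = unname(map[net$edges$from]),
                                    to = unname(map[net$edges$to]),
                                    score = net$edges$score,
                                    stringsAsFactors = FALSE),
                         nodes = unname(map)),
       map = map)
}
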