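# Maximal clique centrality: Bron-Kerbosch enumeration with pivoting and
# MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!.
# Scores are accumulated in exact arbitrary-precision integers so that
# large cliques cannot overflow or lose ranking resolution.

#' Enumerate maximal cliques (Bron-Kerbosch with pivoting)
#'
#' Every maximal clique is returned exactly once; isolated nodes appear as
#' singleton cliques (a node with no neighbours is itself maximal).
#'
#' @param net A [ppi_network()].
#' @return List of character vectors, each a maximal clique (symbols in
#'   lexicographic order); the list is ordered deterministically.
#' @export
maximal_cliques <- function(net) {
  adj <- net_adjacency(net)
  n <- length(adj)
  out <- vector("list", 0L)
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    px <- c(P, X)
    gain <- vapply(px, function(u) sum(P %in% adj[[u]]), integer(1))
    u <- px[which.max(gain)]
    for (v in P[!(P %in% adj[[u]])]) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- P[P != v]
      X <- c(X, v)
    }
  }
  if (n > 0L) bk(integer(0), seq_len(n), integer(0))
  cliques <- lapply(out, function(ix) sort(net$nodes[ix], method = "radix"))
  key <- vapply(cliques, paste, character(1), collapse = "\r")
  cliques[order(key, method = "radix")]
}

#' Maximal clique centrality scores
#'
#' `MCC(v) = sum over maximal cliques C with v in C of (|C| - 1)!`. An
#' isolated node therefore scores `0! = 1` via its singleton clique.
#' Factorials are evaluated in arbitrary-precision integers; the table
#' reports both a double approximation (`MCC`) and the exact decimal
#' string (`MCC_exact`), which [mcc_top()] uses to break ordering ties
#' beyond double resolution.
#'
#' @param net A [ppi_network()].
#' @return Data frame with columns `node`, `MCC` (numeric), `MCC_exact`
#'   (character) and `clique_count`, rows in `net$nodes` order. The exact
#'   bignum scores are attached as attribute `"exact"`.
#' @export
mcc_scores <- function(net) {
  cliques <- maximal_cliques(net)
  n <- length(net$nodes)
  exact <- replicate(n, bi(0), simplify = FALSE)
  count <- integer(n)
  for (cl in cliques) {
    contrib <- bi_factorial(length(cl) - 1L)
    ix <- match(cl, net$nodes)
    for (i in ix) {
      exact[[i]] <- bi_add(exact[[i]], contrib)
      count[i] <- count[i] + 1L
    }
  }
  out <- data.frame(node = net$nodes,
                    MCC = vapply(exact, bi_to_double, numeric(1)),
                    MCC_exact = vapply(exact, bi_format, character(1)),
                    clique_count = count,
                    stringsAsFactors = FALSE)
  attr(out, "exact") <- exact
  out
}

#' Top-k nodes by MCC
#'
#' Selects the `k` highest-scoring nodes. When scores tie at the k-th
#' boundary the default policy includes every tied node (so the result may
#' exceed `k`); `"truncate"` instead cuts to exactly `k` after a
#' lexicographic tie-break, for bit-exact list lengths.
#'
#' @param table Result of [mcc_scores()].
#' @param k Number of nodes requested (default 10).
#' @param ties `"include"` (default) or `"truncate"`.
#' @return A [gene_set()] of the selected nodes. If `k` exceeds the node
#'   count all nodes are returned with a warning.
#' @export
mcc_top <- function(table, k = 10L, ties = c("include", "truncate")) {
  ties <- match.arg(ties)
  stopifnot(k >= 1L)
  n <- nrow(table)
  if (k >= n) {
    if (k > n) warning("k = ", k, " exceeds node count ", n,
                       "; returning all nodes")
    return(gene_set(table$node, label = "MCC top"))
  }
  # zero-pad the exact decimal scores to equal width so that plain string
  # comparison orders them numerically, with no double rounding involved
  width <- max(nchar(table$MCC_exact))
  score_key <- sprintf("%s%s",
                       strrep("0", width - nchar(table$MCC_exact)),
                       table$MCC_exact)
  ord <- order(score_key, table$node, method = "radix",
               decreasing = c(TRUE, FALSE))
  kth <- score_key[ord[k]]
  if (ties == "include") {
    sel <- ord[score_key[ord] >= kth]
  } else {
    sel <- ord[seq_len(k)]
  }
  gene_set(table$node[sel], label = "MCC top")
}
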