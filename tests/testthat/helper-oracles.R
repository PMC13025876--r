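# Independent brute-force oracles. These deliberately avoid the
# algorithms used by the package (Brandes accumulation, Bron-Kerbosch,
# core pruning, cumulative-sum ES): centralities come from explicit
# enumeration of all shortest paths, cliques from subset enumeration,
# and exact hypergeometric tails from Python's rational arithmetic.

# all simple paths from s to t as lists of vertex indices
enumerate_paths <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ])) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

# DC / BC / CC by exhaustive shortest-path enumeration
oracle_centralities <- function(net) {
  A <- net_adj_matrix(net)
  n <- nrow(A)
  dc <- rowSums(A)
  bc <- numeric(n)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  if (n >= 2) {
    for (s in seq_len(n - 1L)) {
      for (t in seq.int(s + 1L, n)) {
        paths <- enumerate_paths(A, s, t)
        if (!length(paths)) next
        lens <- vapply(paths, length, integer(1)) - 1L
        L <- min(lens)
        dist[s, t] <- dist[t, s] <- L
        sp <- paths[lens == L]
        sigma <- length(sp)
        inner <- unlist(lapply(sp, function(p) p[-c(1L, length(p))]))
        if (length(inner)) {
          tab <- table(inner)
          idx <- as.integer(names(tab))
          bc[idx] <- bc[idx] + as.numeric(tab) / sigma
        }
      }
    }
  }
  cc <- vapply(seq_len(n), function(v) {
    reach <- which(is.finite(dist[v, ]) & seq_len(n) != v)
    if (!length(reach)) 0 else length(reach) / sum(dist[v, reach])
  }, numeric(1))
  data.frame(node = net$nodes, DC = unname(dc), BC = bc, CC = cc,
             stringsAsFactors = FALSE)
}

# maximal cliques and MCC by enumeration over all vertex subsets (n <= ~15)
oracle_max_cliques <- function(net) {
  A <- net_adj_matrix(net)
  n <- nrow(A)
  cliques <- list()
  for (bits in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(bits, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (!length(S)) next
    k <- length(S)
    if (k > 1L && sum(A[S, S]) != k * (k - 1L)) next
    outside <- setdiff(seq_len(n), S)
    if (any(vapply(outside, function(v) all(A[v, S]), logical(1)))) next
    cliques[[length(cliques) + 1L]] <- sort(net$nodes[S])
  }
  key <- vapply(cliques, paste, character(1), collapse = "\r")
  cliques[order(key, method = "radix")]
}

oracle_mcc <- function(net) {
  cliques <- oracle_max_cliques(net)
  mcc <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  cnt <- stats::setNames(integer(length(net$nodes)), net$nodes)
  for (cl in cliques) {
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
    cnt[cl] <- cnt[cl] + 1L
  }
  list(MCC = mcc, clique_count = cnt, cliques = cliques)
}

# MCODE vertex weight by subset enumeration: the highest k for which some
# subset of the closed neighbourhood has minimum internal degree >= k,
# and the density of the union of all subsets attaining it
oracle_mcode_weight <- function(net, v, degree_cutoff = 2L) {
  A <- net_adj_matrix(net)
  vi <- match(v, net$nodes)
  nb <- c(vi, which(A[vi, ]))
  if (length(nb) - 1L < degree_cutoff) return(0)
  B <- A[nb, nb, drop = FALSE]
  m <- length(nb)
  best_k <- 0L
  core_members <- integer(0)
  for (bits in seq_len(2^m) - 1L) {
    S <- which(bitwAnd(bits, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    if (length(S) < 2L) next
    mindeg <- min(rowSums(B[S, S, drop = FALSE]))
    if (mindeg > best_k) {
      best_k <- mindeg
      core_members <- S
    } else if (mindeg == best_k && best_k > 0L) {
      core_members <- union(core_members, S)
    }
  }
  if (best_k == 0L) return(0)
  V <- length(core_members)
  E <- sum(B[core_members, core_members]) / 2
  best_k * 2 * E / (V * (V - 1))
}

# step-up Benjamini-Hochberg from its definition, in input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  # literal step-up: q_(i) = min_{j >= i} m p_(j) / j
  q <- vapply(seq_len(m), function(i)
    min(m * sorted[i:m] / seq.int(i, m)), numeric(1))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# weighted-KS enrichment score by an explicit position-by-position walk
oracle_es <- function(ranked, members, weight = 1) {
  genes <- names(ranked)
  hit <- toupper(trimws(genes)) %in% toupper(trimws(members))
  N <- length(genes)
  NH <- sum(hit)
  NR <- sum(abs(ranked[hit])^weight)
  cur <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      cur <- cur + (if (NR > 0) abs(ranked[i])^weight / NR else 1 / NH)
    } else {
      cur <- cur - 1 / (N - NH)
    }
    if (abs(cur) > abs(best)) best <- cur
  }
  unname(best)
}

# exact hypergeometric upper tails via Python fractions; rows is a data
# frame with columns N, K, n, k
py_hyper_tail <- function(rows) {
  script <- paste(
    "import sys",
    "from fractions import Fraction",
    "from math import comb",
    "for line in sys.stdin:",
    "    N, K, n, k = map(int, line.split())",
    "    p = sum(Fraction(comb(K, i) * comb(N - K, n - i), comb(N, n))",
    "            for i in range(k, min(K, n) + 1))",
    "    print(repr(float(p)))",
    sep = "\n")
  inp <- sprintf("%d %d %d %d", rows$N, rows$K, rows$n, rows$k)
  out <- system2("python", c("-c", shQuote(script)), input = inp,
                 stdout = TRUE)
  as.numeric(out)
}

binom_bounds99 <- function(n_trials, p = 0.05) {
  stats::qbinom(c(0.005, 0.995), n_trials, p) / n_trials
}
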