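# Seeded synthetic-data generators with recorded ground truth. Every
# emitted file is plain text, round-trips through the package readers,
# and is verified against the recorded truth at generation time.

synthetic_symbols <- function(n, prefix = "G") {
  sprintf("%s%06d", prefix, seq_len(n))
}

#' Generate two gene lists with exact controlled overlap
#'
#' Draws two lists from a synthetic universe (`G000001`, ... to avoid
#' collisions with real symbols) such that `|A| = size_a`,
#' `|B| = size_b` and `|A intersect B| = overlap` hold exactly. With the
#' published list sizes (327/1668/198) this produces a fixture shaped
#' like a compound-target/disease-gene pair.
#'
#' @param universe_size Size of the symbol universe.
#' @param size_a,size_b Sizes of the two lists.
#' @param overlap Exact intersection size.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, `targets_a.tsv` and
#'   `targets_b.tsv` are written there and verified by re-reading.
#' @return List with `a`, `b` ([gene_set()]s), `paths` (or `NULL`) and
#'   `truth` (overlap symbols, parameters, seed).
#' @export
make_target_lists <- function(universe_size, size_a, size_b, overlap,
                              seed = 1L, dir = NULL) {
  if (overlap > min(size_a, size_b))
    stop("overlap exceeds the smaller list size")
  if (size_a + size_b - overlap > universe_size)
    stop("universe too small for the requested sizes")
  universe <- synthetic_symbols(universe_size)
  picks <- local_seed(seed,
                      sample(universe, size_a + size_b - overlap))
  shared <- picks[seq_len(overlap)]
  a_only <- picks[seq_len(size_a - overlap) + overlap]
  b_only <- picks[seq_len(size_b - overlap) + size_a]
  a <- gene_set(c(shared, a_only), label = "compound targets")
  b <- gene_set(c(shared, b_only), label = "disease targets")
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(a = file.path(dir, "targets_a.tsv"),
               b = file.path(dir, "targets_b.tsv"))
    write_gene_set(a, paths[["a"]])
    write_gene_set(b, paths[["b"]])
    stopifnot(identical(read_gene_list(paths[["a"]])$symbols, a$symbols),
              identical(read_gene_list(paths[["b"]])$symbols, b$symbols))
  }
  truth <- list(overlap = sort(shared, method = "radix"),
                params = list(universe_size = universe_size,
                              size_a = size_a, size_b = size_b,
                              overlap = overlap, seed = seed))
  stopifnot(identical(gs_intersect(a, b)$symbols, truth$overlap))
  list(a = a, b = b, paths = paths, truth = truth)
}

# preferential-attachment backbone: node i > m attaches to `m` distinct
# existing nodes sampled proportional to degree + 1
pa_edges <- function(n, m) {
  stopifnot(n > m)
  deg <- numeric(n)
  from <- integer(0)
  to <- integer(0)
  for (v in seq.int(2L, n)) {
    k <- min(m, v - 1L)
    prev <- seq_len(v - 1L)
    targets <- if (length(prev) == 1L) prev
               else sample(prev, k, prob = deg[prev] + 1)
    from <- c(from, rep.int(v, k))
    to <- c(to, targets)
    deg[v] <- deg[v] + k
    deg[targets] <- deg[targets] + 1
  }
  cbind(from, to)
}

#' Generate a synthetic interaction network with planted structure
#'
#' Scale-free-like backbone (preferential attachment), one designated hub
#' additionally wired to a fraction of all nodes, and one planted clique.
#' The hub is a member of the planted clique, so the planted structure is
#' simultaneously recoverable by centrality screening, dense-module
#' detection and clique-based ranking. Edges are emitted in STRING
#' dialect with confidences drawn uniformly from [900, 1000], so the
#' default cutoff retains them all (cutoff behaviour is exercised
#' separately with sub-900 rows).
#'
#' @param n Number of nodes.
#' @param attachment Edges added per node in the backbone (default 2).
#' @param hub_fraction Fraction of nodes the hub is wired to
#'   (default 0.3).
#' @param clique_size Size of the planted clique (default 8; the hub
#'   counts as one member).
#' @param seed Integer seed.
#' @param symbols Optional character vector of `n` node names (default
#'   synthetic `G...` symbols).
#' @param path Optional output file for the STRING-dialect edge list;
#'   written deterministically (same seed, byte-identical file) and
#'   verified by re-reading.
#' @return List with `net` ([ppi_network()]), `path` (or `NULL`) and
#'   `truth` (hub symbol, clique members, parameters, seed).
#' @export
make_ppi <- function(n, attachment = 2L, hub_fraction = 0.3,
                     clique_size = 8L, seed = 1L, symbols = NULL,
                     path = NULL) {
  stopifnot(clique_size <= n, clique_size >= 2L, n > attachment)
  symbols <- symbols %||% synthetic_symbols(n)
  stopifnot(length(symbols) == n)
  symbols <- normalize_symbols(symbols)
  stopifnot(length(symbols) == n)
  res <- local_seed(seed, {
    backbone <- pa_edges(n, attachment)
    hub <- sample.int(n, 1L)
    others <- setdiff(seq_len(n), hub)
    clique <- c(hub, sample(others, clique_size - 1L))
    n_wire <- ceiling(hub_fraction * n)
    wired <- sample(others, min(n_wire, length(others)))
    hub_edges <- cbind(rep.int(hub, length(wired)), wired)
    cl_pairs <- t(utils::combn(clique, 2L))
    edges <- rbind(backbone, hub_edges, cl_pairs)
    scores <- sample(900:1000, nrow(edges), replace = TRUE)
    list(edges = edges, hub = hub, clique = clique, scores = scores)
  })
  net <- ppi_network(data.frame(from = symbols[res$edges[, 1L]],
                                to = symbols[res$edges[, 2L]],
                                score = res$scores,
                                stringsAsFactors = FALSE))
  truth <- list(hub = symbols[res$hub],
                clique = sort(symbols[res$clique], method = "radix"),
                params = list(n = n, attachment = attachment,
                              hub_fraction = hub_fraction,
                              clique_size = clique_size, seed = seed))
  if (!is.null(path)) {
    write_string_edges(net, path)
    reread <- read_string_edges(path, min_score = 900L)
    stopifnot(identical(reread$edges, net$edges))
  }
  # planted clique must be present as a complete subgraph
  sub <- induced_subgraph(net, truth$clique)
  stopifnot(nrow(sub$edges) == choose(clique_size, 2))
  list(net = net, path = path, truth = truth)
}

#' Generate a sparse random graph with one planted clique
#'
#' Erdos-Renyi background `G(n, p)` plus a clique on `clique_size` random
#' nodes — the classic planted-clique recovery benchmark for dense-module
#' detection.
#'
#' @param n Number of nodes.
#' @param p Background edge probability.
#' @param clique_size Planted clique size.
#' @param seed Integer seed.
#' @return List with `net` ([ppi_network()]; isolated background nodes
#'   are retained as nodes) and `truth` (clique members).
#' @export
make_planted_clique_graph <- function(n, p, clique_size, seed = 1L) {
  stopifnot(clique_size <= n)
  symbols <- synthetic_symbols(n)
  res <- local_seed(seed, {
    pairs <- t(utils::combn(n, 2L))
    keep <- stats::runif(nrow(pairs)) < p
    clique <- sort(sample.int(n, clique_size))
    list(bg = pairs[keep, , drop = FALSE], clique = clique)
  })
  cl_pairs <- t(utils::combn(res$clique, 2L))
  edges <- rbind(res$bg, cl_pairs)
  net <- ppi_network(data.frame(from = symbols[edges[, 1L]],
                                to = symbols[edges[, 2L]],
                                score = 1000L, stringsAsFactors = FALSE),
                     nodes = symbols)
  list(net = net,
       truth = list(clique = symbols[res$clique],
                    params = list(n = n, p = p,
                                  clique_size = clique_size, seed = seed)))
}

#' Generate a two-group expression matrix with planted DE genes
#'
#' Baseline expression is log-normal: on the log2 scale each gene has a
#' Normal(5, 1.5) mean and Normal(0, `sigma`) per-sample noise. A chosen
#' set of genes is shifted upward by `effect_log2` (on the log2 scale) in
#' group A. Values are emitted as `2^z - 1`, so the analysis transform
#' `log2(x + 1)` recovers the simulated log2 scale exactly. A GMT
#' collection containing the true DE set plus size-matched decoy sets is
#' generated alongside.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group.
#' @param de_set_size Number of planted DE genes.
#' @param effect_log2 Log2-scale shift of the planted genes in group A
#'   (default 2).
#' @param sigma Log2-scale noise standard deviation (default 0.5).
#' @param seed Integer seed.
#' @param n_decoys Number of decoy gene sets in the GMT (default 10).
#' @param dir Optional directory; when given, writes
#'   `expression.tsv`, `groups.tsv` and `sets.gmt` (verified by
#'   re-reading).
#' @return List with `mat` (genes x samples), `groups` (named vector),
#'   `collection` (named list of gene sets, first element
#'   `"PLANTED_DE"`), `paths` (or `NULL`) and `truth` (DE gene symbols,
#'   parameters, seed).
#' @export
make_expression <- function(n_genes, n_per_group, de_set_size,
                            effect_log2 = 2, sigma = 0.5, seed = 1L,
                            n_decoys = 10L, dir = NULL) {
  stopifnot(de_set_size <= n_genes)
  genes <- synthetic_symbols(n_genes)
  samples <- c(sprintf("A%03d", seq_len(n_per_group)),
               sprintf("B%03d", seq_len(n_per_group)))
  groups <- stats::setNames(rep(c("A", "B"), each = n_per_group), samples)
  res <- local_seed(seed, {
    mu <- stats::rnorm(n_genes, mean = 5, sd = 1.5)
    de <- sort(sample.int(n_genes, de_set_size))
    z <- matrix(stats::rnorm(n_genes * 2L * n_per_group, sd = sigma),
                nrow = n_genes) + mu
    z[de, seq_len(n_per_group)] <- z[de, seq_len(n_per_group)] + effect_log2
    decoys <- lapply(seq_len(n_decoys), function(i)
      sample(genes, de_set_size))
    list(z = z, de = de, decoys = decoys)
  })
  mat <- pmax(2^res$z - 1, 0)
  dimnames(mat) <- list(genes, samples)
  collection <- c(list(PLANTED_DE = genes[res$de]),
                  stats::setNames(res$decoys,
                                  sprintf("DECOY_%02d", seq_len(n_decoys))))
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(matrix = file.path(dir, "expression.tsv"),
               groups = file.path(dir, "groups.tsv"),
               gmt = file.path(dir, "sets.gmt"))
    write_tsv(data.frame(gene = genes, as.data.frame(mat),
                         check.names = FALSE), paths[["matrix"]])
    write_tsv(data.frame(sample = samples, group = unname(groups)),
              paths[["groups"]])
    write_gmt(collection, paths[["gmt"]])
    reread <- read_expression(paths[["matrix"]])
    stopifnot(identical(rownames(reread), genes),
              max(abs(reread - mat)) < 1e-6,
              identical(read_groups(paths[["groups"]]), groups),
              identical(sort(read_gmt(paths[["gmt"]])$terms$
                               PLANTED_DE$members),
                        sort(genes[res$de])))
  }
  list(mat = mat, groups = groups, collection = collection, paths = paths,
       truth = list(de_genes = genes[res$de],
                    params = list(n_genes = n_genes,
                                  n_per_group = n_per_group,
                                  de_set_size = de_set_size,
                                  effect_log2 = effect_log2,
                                  sigma = sigma, seed = seed)))
}
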