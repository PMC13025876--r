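# Protein-protein interaction networks: STRING-dialect IO, confidence
# filtering, induced subgraphs. The container is a plain node vector plus a
# canonical undirected edge table; all topology downstream is unweighted.

#' Construct an interaction network
#'
#' Builds a simple undirected graph from an edge table. Self-loops are
#' dropped (with a warning), reversed duplicates are collapsed keeping the
#' maximum confidence, and edges are stored canonically with
#' `from < to` lexicographically.
#'
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `score` (integer confidence on the STRING 0-1000 scale; defaults to
#'   1000).
#' @param nodes Optional character vector of additional (possibly
#'   isolated) nodes.
#' @return An object of class `ppi_network` with elements `nodes`
#'   (character) and `edges` (data frame `from`, `to`, `score`).
#' @export
ppi_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        score = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (!"score" %in% names(edges)) edges$score <- rep(1000L, nrow(edges))
  edges$from <- normalize_symbols_keep(edges$from)
  edges$to <- normalize_symbols_keep(edges$to)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  lo <- pmin(edges$from, edges$to)
  hi <- pmax(edges$from, edges$to)
  edges$from <- lo
  edges$to <- hi
  if (nrow(edges) > 0L) {
    key <- paste(edges$from, edges$to, sep = "\r")
    score <- tapply(edges$score, key, max)
    keys <- sort(names(score), method = "radix")
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[[`, "", 1L),
                        to = vapply(parts, `[[`, "", 2L),
                        score = as.integer(unname(score[keys])),
                        stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$from, edges$to,
                         normalize_symbols(nodes %||% character()))),
                method = "radix")
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

# like normalize_symbols() but errors on empties instead of dropping them,
# so malformed edge rows cannot silently vanish
normalize_symbols_keep <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(is.na(x) | !nzchar(x))) stop("empty node name in edge list")
  x
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

# adjacency as a list of sorted integer vectors indexed like net$nodes
net_adjacency <- function(net) {
  n <- length(net$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(net$edges) > 0L) {
    fi <- match(net$edges$from, net$nodes)
    ti <- match(net$edges$to, net$nodes)
    adj <- unname(split(c(ti, fi), factor(c(fi, ti), levels = seq_len(n))))
    adj <- lapply(adj, function(v) sort(unname(v)))
  }
  adj
}

#' Read a STRING-dialect edge list
#'
#' Parses a tab- or comma-separated file with columns `protein1`,
#' `protein2`, `combined_score` and keeps edges at or above the confidence
#' cutoff (the STRING "minimum required score" convention, so the
#' highest-confidence 0.9 setting is `min_score = 900`). Scores supplied
#' as 0-1 fractions are auto-detected and scaled by 1000. Reversed
#' duplicate rows collapse to one edge keeping the maximum score;
#' self-loops are dropped with a warning.
#'
#' @param path Edge-list file.
#' @param min_score Inclusive confidence cutoff on the 0-1000 scale
#'   (default 900).
#' @param id_map Optional headerless two-column file mapping protein IDs
#'   to gene symbols; unmapped rows are dropped with a warning.
#' @return A [ppi_network()] whose every edge has `score >= min_score`.
#' @export
read_string_edges <- function(path, min_score = 900L, id_map = NULL) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  if (min_score < 0 || min_score > 1000) stop("min_score must be in [0, 1000]")
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE) &&
             !grepl("\t", first, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(df)))
    stop("edge list must have columns protein1, protein2, combined_score; ",
         "found: ", paste(names(df), collapse = ", "))
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(score))) {
    bad <- which(is.na(score))[1L]
    stop("malformed combined_score '", df$combined_score[bad],
         "' at data line ", bad, " of ", path)
  }
  # 0-1 dialect: every score within [0, 1]
  if (nrow(df) > 0L && all(score >= 0 & score <= 1)) score <- score * 1000
  if (any(score < 0 | score > 1000))
    stop("combined_score outside [0, 1000] in ", path)
  if (!is.null(id_map)) {
    map <- utils::read.table(id_map, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    lut <- stats::setNames(map[[2L]], toupper(trimws(map[[1L]])))
    p1 <- lut[toupper(trimws(df$protein1))]
    p2 <- lut[toupper(trimws(df$protein2))]
    miss <- is.na(p1) | is.na(p2)
    if (any(miss))
      warning(sum(miss), " edge(s) dropped: endpoint without symbol mapping")
    df <- df[!miss, , drop = FALSE]
    score <- score[!miss]
    df$protein1 <- p1[!miss]
    df$protein2 <- p2[!miss]
  }
  keep <- score >= min_score
  ppi_network(data.frame(from = df$protein1[keep], to = df$protein2[keep],
                         score = as.integer(round(score[keep])),
                         stringsAsFactors = FALSE))
}

#' Write a network as a STRING-dialect edge list
#'
#' Round-trips through [read_string_edges()] bit-identically (canonical
#' edge order, integer scores). Isolated nodes are not representable in an
#' edge list and are omitted.
#'
#' @param net A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(net, path) {
  write_tsv(data.frame(protein1 = net$edges$from, protein2 = net$edges$to,
                       combined_score = net$edges$score), path)
}

#' Drop isolated nodes
#'
#' Removes nodes of degree zero ("disconnected nodes were hidden"). The
#' removed symbols are attached as attribute `"removed"`.
#'
#' @param net A `ppi_network`.
#' @return A `ppi_network` in which every node has degree >= 1.
#' @export
drop_isolated <- function(net) {
  connected <- unique(c(net$edges$from, net$edges$to))
  removed <- setdiff(net$nodes, connected)
  out <- ppi_network(net$edges)
  attr(out, "removed") <- sort(removed, method = "radix")
  out
}

#' Induced subgraph on a node subset
#'
#' Keeps `net$nodes` intersected with `keep` and every edge whose two
#' endpoints are both kept.
#'
#' @param net A `ppi_network`.
#' @param keep A [gene_set()] or character vector of symbols to retain.
#' @return A `ppi_network`.
#' @export
induced_subgraph <- function(net, keep) {
  keep <- as_gene_set(keep)$symbols
  nodes <- intersect(net$nodes, keep)
  e <- net$edges[net$edges$from %in% nodes & net$edges$to %in% nodes, ,
                 drop = FALSE]
  ppi_network(e, nodes = nodes)
}

# connected-component labels by BFS; returns integer vector along net$nodes
net_components <- function(net) {
  adj <- net_adjacency(net)
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- unlist(adj[frontier], use.names = FALSE)
      nxt <- nxt[comp[nxt] == 0L]
      nxt <- unique(nxt)
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}
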