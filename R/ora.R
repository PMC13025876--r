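# Over-representation analysis: GMT collections, exact hypergeometric
# upper-tail tests, Benjamini-Hochberg adjustment.

#' Read a GMT gene-set collection
#'
#' GMT dialect: one term per line, tab-separated as
#' `term <TAB> description <TAB> member1 <TAB> member2 ...`. Member
#' symbols are normalised (uppercase, trimmed) and deduplicated with a
#' warning.
#'
#' @param path GMT file path.
#' @return An object of class `gene_set_collection`: list with `terms`
#'   (named list of `list(description, members)`) and `universe` (a
#'   [gene_set()] of all member symbols).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    members <- normalize_symbols(fields[-(1:2)])
    if (anyDuplicated(members)) {
      warning("duplicated member(s) in term '", fields[1L],
              "' (line ", i, "); deduplicated")
      members <- unique(members)
    }
    if (!length(members)) stop("GMT line ", i, " defines an empty term")
    terms[[fields[1L]]] <- list(description = fields[2L], members = members)
  }
  structure(list(
    terms = terms,
    universe = gene_set(unlist(lapply(terms, `[[`, "members"),
                               use.names = FALSE), label = "GMT universe")),
    class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$terms, function(t) length(t$members), integer(1))
  cat(sprintf(
    "<gene_set_collection> %d terms (sizes %d-%d), universe %d genes\n",
    length(x$terms), if (length(sizes)) min(sizes) else 0L,
    if (length(sizes)) max(sizes) else 0L, length(x$universe)))
  invisible(x)
}

#' Write a collection in GMT format
#'
#' @param collection A `gene_set_collection` (or named list of character
#'   vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "gene_set_collection")) {
    lines <- vapply(names(collection$terms), function(nm) {
      t <- collection$terms[[nm]]
      paste(c(nm, t$description, t$members), collapse = "\t")
    }, character(1))
  } else {
    lines <- vapply(names(collection), function(nm)
      paste(c(nm, "synthetic", collection[[nm]]), collapse = "\t"),
      character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR q-values in input order (`stats::p.adjust(method = "BH")`
#' with input validation).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query set overlaps the term more than
#' expected when drawing `n` genes from an `N`-gene universe containing
#' `K` term members: `p = P(X >= k)`, `X ~ Hypergeometric(N, K, n)`,
#' computed exactly with `stats::phyper`. The query and all terms are
#' restricted to the universe before testing. By default only terms with
#' at least one query hit enter the result (and the BH family), mirroring
#' common enrichment servers; `include_empty = TRUE` reports `k = 0`
#' terms with `p = 1`.
#'
#' @param query A [gene_set()] or character vector.
#' @param collection A [read_gmt()] collection (or named list of
#'   character vectors).
#' @param universe Universe [gene_set()]; defaults to all genes in the
#'   collection. A PPI node set can be supplied to restrict the
#'   background.
#' @param include_empty Also report terms with no query overlap
#'   (default `FALSE`).
#' @return Data frame sorted by ascending `p` with columns `term`,
#'   `description`, `k`, `K`, `n`, `N`, `fold`, `p`, `q`.
#' @export
ora <- function(query, collection, universe = NULL, include_empty = FALSE) {
  if (!inherits(collection, "gene_set_collection")) {
    stopifnot(is.list(collection), !is.null(names(collection)))
    collection <- structure(list(
      terms = lapply(collection, function(m)
        list(description = "", members = normalize_symbols(m))),
      universe = gene_set(unlist(collection, use.names = FALSE))),
      class = "gene_set_collection")
  }
  universe <- as_gene_set(universe %||% collection$universe)$symbols
  if (!length(universe)) stop("empty universe")
  query <- intersect(as_gene_set(query)$symbols, universe)
  N <- length(universe)
  n <- length(query)
  if (n == 0L) {
    warning("query has no genes in the universe; empty result")
    return(data.frame(term = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), fold = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(collection$terms), function(nm) {
    members <- intersect(collection$terms[[nm]]$members, universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    data.frame(term = nm,
               description = collection$terms[[nm]]$description,
               k = k, K = K, n = n, N = N,
               fold = (k / n) / (K / N),
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no testable terms after universe restriction")
  if (!include_empty) out <- out[out$k >= 1L, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no term overlaps the query; empty result")
    out$q <- numeric(0)
    return(out)
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
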