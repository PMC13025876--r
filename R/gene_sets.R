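# Gene-symbol sets: normalisation, file IO, union and Venn intersection.

#' Normalise gene symbols
#'
#' Uppercases, strips surrounding whitespace, and drops empty strings and
#' `NA`s. No alias or HGNC re-mapping is attempted: normalisation is purely
#' lexical so that results are deterministic and database-free.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of cleaned symbols (possibly shorter than `x`).
#' @export
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!is.na(x) & nzchar(x)]
}

#' Construct a gene set
#'
#' A `gene_set` is an ordered collection of unique, normalised gene symbols
#' with an optional provenance map recording which source(s) contributed
#' each symbol. Duplicates keep their first occurrence; default ordering is
#' lexicographic for reproducibility, with insertion order available on
#' request.
#'
#' @param symbols Character vector of gene symbols (normalised internally).
#' @param label Free-text label, e.g. `"TN targets"`.
#' @param sources Optional named list mapping symbol to a character vector
#'   of source tags.
#' @param order `"lexicographic"` (default) or `"insertion"`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(symbols = character(), label = "",
                     sources = NULL, order = c("lexicographic", "insertion")) {
  order <- match.arg(order)
  symbols <- normalize_symbols(symbols)
  symbols <- symbols[!duplicated(symbols)]
  if (order == "lexicographic") symbols <- sort(symbols, method = "radix")
  if (!is.null(sources)) {
    stopifnot(is.list(sources))
    names(sources) <- normalize_symbols(names(sources))
    sources <- sources[names(sources) %in% symbols]
  }
  structure(list(symbols = symbols, label = label, sources = sources),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$symbols)))
  show <- utils::head(x$symbols, 10L)
  cat(" ", paste(show, collapse = ", "),
      if (length(x$symbols) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' @export
as.character.gene_set <- function(x, ...) x$symbols

as_gene_set <- function(x, label = "") {
  if (inherits(x, "gene_set")) x else gene_set(x, label = label)
}

#' Read a gene list from a delimited file
#'
#' Reads a headered TSV/CSV, extracts one column of gene symbols,
#' normalises and deduplicates them. Stands in for database exports of
#' predicted compound targets or disease gene lists. An optional two-column
#' identifier-to-symbol mapping file (e.g. UniProt accession to symbol)
#' converts non-symbol columns; rows without a mapping are dropped with a
#' warning.
#'
#' @param path File path. `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @param column Column name or 1-based index holding the symbols.
#' @param label Label for the resulting set (defaults to the file name).
#' @param id_map Optional path to a headerless two-column file mapping
#'   identifiers in `column` to gene symbols.
#' @param order Passed to [gene_set()].
#' @return A [gene_set()]. The number of duplicates dropped is reported
#'   via `message()`.
#' @export
read_gene_list <- function(path, column = 1L, label = basename(path),
                           id_map = NULL,
                           order = c("lexicographic", "insertion")) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fill = TRUE,
                          quote = "\"", comment.char = "")
  if (is.character(column)) {
    if (!column %in% names(df))
      stop("column '", column, "' not present in ", path,
           " (found: ", paste(names(df), collapse = ", "), ")")
    raw <- df[[column]]
  } else {
    if (column < 1L || column > ncol(df))
      stop("column index ", column, " out of range for ", path)
    raw <- df[[column]]
  }
  if (nrow(df) == 0L) {
    warning("empty gene list file: ", path)
    return(gene_set(character(), label = label, order = order))
  }
  if (!is.null(id_map)) {
    map <- utils::read.table(id_map, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    lut <- stats::setNames(map[[2L]], toupper(trimws(map[[1L]])))
    hit <- lut[toupper(trimws(raw))]
    n_miss <- sum(is.na(hit) & nzchar(trimws(raw)))
    if (n_miss > 0L)
      warning(n_miss, " row(s) in ", path, " had no symbol mapping; dropped")
    raw <- hit[!is.na(hit)]
  }
  norm <- normalize_symbols(raw)
  n_dup <- sum(duplicated(norm))
  if (n_dup > 0L)
    message(n_dup, " duplicate symbol(s) dropped from ", path)
  gene_set(norm, label = label, order = order)
}

#' Union of gene sets with provenance
#'
#' Removes duplicates across sets while recording, for every symbol, which
#' input set(s) contributed it — the "merge three disease databases and
#' drop duplicates" step.
#'
#' @param ... `gene_set` objects (or character vectors), or a single list
#'   of them.
#' @param label Label for the union.
#' @return A [gene_set()] whose `sources` maps each symbol to the labels of
#'   the contributing sets.
#' @export
gs_union <- function(..., label = "union") {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) &&
      !inherits(sets[[1L]], "gene_set")) sets <- sets[[1L]]
  if (length(sets) < 1L) stop("gs_union() needs at least one set")
  sets <- lapply(sets, as_gene_set)
  labels <- vapply(seq_along(sets), function(i) {
    if (nzchar(sets[[i]]$label)) sets[[i]]$label else paste0("set", i)
  }, character(1))
  sources <- list()
  for (i in seq_along(sets)) {
    for (s in sets[[i]]$symbols)
      sources[[s]] <- c(sources[[s]], labels[[i]])
  }
  gene_set(unlist(lapply(sets, `[[`, "symbols"), use.names = FALSE),
           label = label, sources = sources)
}

#' Venn counts for two gene sets
#'
#' @param a,b `gene_set` objects or character vectors.
#' @return Named integer vector `c(a_only, b_only, both)`.
#' @export
venn_counts <- function(a, b) {
  a <- as_gene_set(a)$symbols
  b <- as_gene_set(b)$symbols
  both <- sum(a %in% b)
  c(a_only = length(a) - both, b_only = length(b) - both, both = both)
}

#' Intersect two gene sets
#'
#' The compound-target x disease-gene Venn step: symbols present in both
#' sets. Venn counts are attached as the `"venn"` attribute.
#'
#' @param a,b `gene_set` objects or character vectors.
#' @param label Label for the intersection.
#' @return A [gene_set()] with attribute `venn` (see [venn_counts()]).
#' @export
gs_intersect <- function(a, b, label = "overlap") {
  a <- as_gene_set(a); b <- as_gene_set(b)
  out <- gene_set(intersect(a$symbols, b$symbols), label = label)
  attr(out, "venn") <- venn_counts(a, b)
  out
}

#' Write a gene set as one symbol per line
#'
#' Emits a headered single-column TSV readable back by [read_gene_list()].
#'
#' @param gs A `gene_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  write_tsv(data.frame(symbol = as_gene_set(gs)$symbols), path)
}

#' Serialise a gene set (with provenance) to JSON
#'
#' @param gs A `gene_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set_json <- function(gs, path) {
  gs <- as_gene_set(gs)
  jsonlite::write_json(
    list(label = gs$label, n = length(gs$symbols),
         symbols = gs$symbols, sources = gs$sources),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}
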