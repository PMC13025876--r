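# Consensus hub genes: three-way intersection of the centrality
# survivors, a dense-module member list, and the MCC top-k list.

#' Consensus hub genes from three candidate lists
#'
#' Intersects the three topological candidate lists (centrality-screen
#' survivors, module members, MCC top-k) and reports the pairwise overlap
#' counts needed for a Venn figure. When a [centrality_table()] is
#' supplied, hubs are ordered by descending degree in it (the convention
#' of degree-ranked hub tables); otherwise lexicographically.
#'
#' @param a,b,c [gene_set()] objects or character vectors.
#' @param centrality Optional data frame with columns `node` and `DC`
#'   used to order the hubs.
#' @return An object of class `consensus_report` with elements `hubs`
#'   ([gene_set()]), `sizes` (named input sizes), and `overlaps` (named
#'   counts `ab`, `ac`, `bc`, `abc`).
#' @export
consensus_hubs <- function(a, b, c, centrality = NULL) {
  a <- as_gene_set(a, "centrality"); b <- as_gene_set(b, "module")
  c <- as_gene_set(c, "mcc")
  hubs <- intersect(intersect(a$symbols, b$symbols), c$symbols)
  if (!is.null(centrality)) {
    stopifnot(all(c("node", "DC") %in% names(centrality)))
    dc <- centrality$DC[match(hubs, centrality$node)]
    dc[is.na(dc)] <- -Inf
    hubs <- hubs[order(-dc, hubs, method = "radix")]
    hubs <- gene_set(hubs, label = "consensus hubs", order = "insertion")
  } else {
    hubs <- gene_set(hubs, label = "consensus hubs")
  }
  structure(list(
    hubs = hubs,
    sizes = c(a = length(a$symbols), b = length(b$symbols),
              c = length(c$symbols)),
    overlaps = c(ab = length(intersect(a$symbols, b$symbols)),
                 ac = length(intersect(a$symbols, c$symbols)),
                 bc = length(intersect(b$symbols, c$symbols)),
                 abc = length(hubs$symbols))),
    class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf(
    "<consensus_report> inputs %d/%d/%d -> %d consensus hub(s)\n",
    x$sizes[["a"]], x$sizes[["b"]], x$sizes[["c"]],
    length(x$hubs)))
  if (length(x$hubs))
    cat("  ", paste(x$hubs$symbols, collapse = ", "), "\n", sep = "")
  invisible(x)
}
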