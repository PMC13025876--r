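# Iterative median-threshold screening of network nodes on DC/BC/CC.

#' Median-threshold centrality screening
#'
#' Implements the two-round hub screening used in Cytoscape/CytoNCA
#' workflows: in each round, compute degree, betweenness and closeness on
#' the current (induced) network, take each metric's median over the
#' current nodes, and keep only nodes strictly above all three medians.
#' Survivors induce the next round's subgraph, on which the centralities
#' are recomputed. Ties at a median are dropped (strict `>`). Screening
#' stops early with a warning if a round would leave no survivors.
#'
#' @param net A [ppi_network()]; isolated nodes are removed first and the
#'   starting population logged in the trace.
#' @param rounds Number of screening rounds (default 2).
#' @return An object of class `screening_trace`: a list with
#'   \describe{
#'     \item{rounds}{list, one element per executed round, each holding
#'       `population` (size), `median_DC`/`median_BC`/`median_CC` (the
#'       thresholds actually applied) and `survivors` (a [gene_set()]).}
#'     \item{final}{[gene_set()] of final survivors.}
#'     \item{tables}{list of per-round [centrality_table()] data frames.}
#'   }
#' @export
median_screen <- function(net, rounds = 2L) {
  stopifnot(rounds >= 1L)
  cur <- drop_isolated(net)
  if (length(cur$nodes) < 2L)
    stop("median_screen() needs a network with at least 2 connected nodes")
  trace <- list()
  tables <- list()
  for (r in seq_len(rounds)) {
    tab <- centrality_table(cur)
    med <- c(DC = stats::median(tab$DC), BC = stats::median(tab$BC),
             CC = stats::median(tab$CC))
    keep <- tab$DC > med[["DC"]] & tab$BC > med[["BC"]] & tab$CC > med[["CC"]]
    survivors <- gene_set(tab$node[keep],
                          label = sprintf("round %d survivors", r))
    trace[[r]] <- list(population = nrow(tab),
                       median_DC = med[["DC"]], median_BC = med[["BC"]],
                       median_CC = med[["CC"]], survivors = survivors)
    tables[[r]] <- tab
    if (length(survivors) == 0L) {
      warning("median screening round ", r,
              " left no survivors; stopping early")
      break
    }
    cur <- induced_subgraph(cur, survivors)
  }
  final <- trace[[length(trace)]]$survivors
  structure(list(rounds = trace, final = final, tables = tables),
            class = "screening_trace")
}

#' @export
print.screening_trace <- function(x, ...) {
  cat("<screening_trace>\n")
  for (r in seq_along(x$rounds)) {
    ri <- x$rounds[[r]]
    cat(sprintf(
      "  round %d: n=%d, medians DC=%.4g BC=%.4g CC=%.4g -> %d survivors\n",
      r, ri$population, ri$median_DC, ri$median_BC, ri$median_CC,
      length(ri$survivors)))
  }
  invisible(x)
}

#' Serialise a screening trace to JSON
#'
#' @param trace A `screening_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screening_trace <- function(trace, path) {
  out <- list(
    rounds = lapply(trace$rounds, function(r) {
      list(population = r$population, median_DC = r$median_DC,
           median_BC = r$median_BC, median_CC = r$median_CC,
           n_survivors = length(r$survivors),
           survivors = r$survivors$symbols)
    }),
    final = trace$final$symbols)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
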